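#' End-to-end replication report on a synthetic population
#'
#' Chains the whole pipeline on a generated two-cohort population: simulate,
#' assign CSF amyloid status per cohort rule, fit the model on cohort A,
#' externally validate on cohort B, evaluate the combined population at the
#' Youden cutoff, derive dual cutoffs at the target predictive value, run
#' the prevalence-fixed bootstrap, the measurement-noise Monte Carlo and the
#' bootstrap calibration, and write every table as CSV/JSON plus a Markdown
#' summary. Every stochastic stage is seeded from the single master seed, so
#' a run is reproducible end to end.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed.
#' @param spec Synthetic population specification.
#' @param target_pv Target predictive value for the dual cutoffs.
#' @param prevalences Prevalence grid for the bootstrap stage.
#' @param B Bootstrap populations per prevalence.
#' @param n_iter Noise Monte Carlo iterations per level.
#' @param n_boot Calibration bootstrap cycles.
#' @param calibration_prevalence Prevalence fixed in calibration resamples.
#' @return Invisibly, a list with every intermediate result.
#' @export
replication_report <- function(out_dir, seed = 1L,
                               spec = default_synthetic_spec(),
                               target_pv = 0.875,
                               prevalences = c(0.4, 0.5, 0.6),
                               B = 200L, n_iter = 200L, n_boot = 200L,
                               calibration_prevalence = 0.6) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)

  cohort <- generate_cohort(spec, seed = child_seed(seed, 1L))
  cohort <- assign_amyloid_status(cohort, rule = spec$rules)
  write_cohort(cohort, path("cohort.csv"))

  coh_a <- cohort[cohort$cohort == "A", ]
  coh_b <- cohort[cohort$cohort == "B", ]

  baseline <- compare_groups(cohort)
  utils::write.csv(baseline, path("baseline_characteristics.csv"), row.names = FALSE)

  fit <- fit_amyloid_model(coh_a)
  jsonlite::write_json(
    list(covariate_names = fit$covariate_names, beta = as.list(fit$beta),
         loglik = fit$loglik, aic = fit$aic, aic_ratio_only = fit$aic_ratio_only,
         n = fit$n, training_prevalence = fit$training_prevalence,
         package_version = as.character(utils::packageVersion("amyloidrisk"))),
    path("model.json"), auto_unbox = TRUE, digits = NA)

  ext <- external_validate(fit, coh_b)

  # performance rows in the usual metrics-table layout
  eval_row <- function(label, p, y) {
    roc <- auc_rank(p, y)
    yj <- youden_cutoff(p, y)
    m <- yj$metrics
    data.frame(cohort = label, sensitivity = m$sensitivity,
               specificity = m$specificity, ppv = m$ppv, npv = m$npv,
               auc = roc$auc, ci_low = roc$ci_low, ci_high = roc$ci_high,
               accuracy_pct = 100 * m$accuracy, prevalence_pct = 100 * mean(y),
               n = length(y), youden_threshold = yj$threshold)
  }
  y_a <- status_binary(coh_a); y_b <- status_binary(coh_b)
  y_all <- status_binary(cohort)
  p_a <- predict(fit, coh_a)
  fit_b <- fit_amyloid_model(coh_b)
  fit_all <- fit_amyloid_model(cohort)
  p_all <- predict(fit_all, cohort)
  perf <- rbind(eval_row("A (training)", p_a, y_a),
                eval_row("B (refit)", predict(fit_b, coh_b), y_b),
                eval_row("External validation", ext$p_hat, y_b),
                eval_row("Combined", p_all, y_all))
  utils::write.csv(perf, path("performance_metrics.csv"), row.names = FALSE)

  curve <- pv_curves(p_all, y_all)
  utils::write.csv(curve$curve, path("pv_curve.csv"), row.names = FALSE)
  pair <- find_dual_cutoffs(curve, target_pv)
  jsonlite::write_json(
    list(target_pv = pair$target_pv, p_neg = pair$p_neg, p_pos = pair$p_pos,
         grey_fraction = pair$grey_fraction, crossed = pair$crossed,
         post_exclusion = pair$post_exclusion),
    path("dual_cutoffs.json"), auto_unbox = TRUE, digits = NA)

  boot <- bootstrap_cutoff_table(cohort, fit_all, prevalences = prevalences,
                                 B = B, target_pv = target_pv,
                                 seed = child_seed(seed, 2L))
  utils::write.csv(boot$summary, path("bootstrap_cutoffs.csv"), row.names = FALSE)

  noise <- noise_study(cohort, n_iter = n_iter, seed = child_seed(seed, 3L))
  utils::write.csv(noise$summary, path("noise_study.csv"), row.names = FALSE)

  calib <- bootstrap_calibration(p_all, y_all, n_boot = n_boot,
                                 seed = child_seed(seed, 4L),
                                 prevalence_target = calibration_prevalence)
  utils::write.csv(calib$curve, path("calibration_curve.csv"), row.names = FALSE)

  assoc <- plasma_csf_association(cohort)
  jsonlite::write_json(unclass(assoc), path("association.json"),
                       auto_unbox = TRUE, digits = NA)

  md <- c(
    "# Synthetic replication report",
    sprintf("master seed: %d; package amyloidrisk %s", seed,
            as.character(utils::packageVersion("amyloidrisk"))),
    "",
    "## Model (trained on cohort A)",
    sprintf("- coefficients: %s",
            paste(sprintf("%s = %.4g", names(fit$beta), fit$beta), collapse = ", ")),
    sprintf("- AIC %.1f (ratio-only %.1f)", fit$aic, fit$aic_ratio_only),
    "",
    "## Discrimination",
    sprintf("- external validation AUC %.3f (%.3f-%.3f)",
            ext$roc$auc, ext$roc$ci_low, ext$roc$ci_high),
    sprintf("- combined AUC %.3f, accuracy %.1f%% at Youden threshold %.3f",
            perf$auc[4], perf$accuracy_pct[4], perf$youden_threshold[4]),
    "",
    "## Dual cutoffs (combined population)",
    sprintf("- target PV %.3f: p_neg = %.3f, p_pos = %.3f, grey zone %.1f%%",
            pair$target_pv, pair$p_neg, pair$p_pos, 100 * pair$grey_fraction),
    sprintf("- post-exclusion sensitivity %.1f%%, specificity %.1f%%",
            100 * pair$post_exclusion$sensitivity,
            100 * pair$post_exclusion$specificity),
    "",
    "## Calibration",
    sprintf("- mean slope %.3f, mean intercept %.3f over %d cycles",
            calib$slope, calib$intercept, calib$n_boot),
    "",
    "## Plasma-CSF agreement",
    sprintf("- Spearman rho %.3f; Deming slope %.3f",
            assoc$spearman_rho, assoc$deming_slope)
  )
  writeLines(md, path("report.md"))

  invisible(list(cohort = cohort, fit = fit, external = ext, performance = perf,
                 pv_curve = curve, cutoffs = pair, bootstrap = boot,
                 noise = noise, calibration = calib, association = assoc))
}
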