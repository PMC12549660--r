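# deterministic child seed for (master, counter); keeps seeds < 2^31
child_seed <- function(master, counter) {
  as.integer((as.double(master) * 48271 + as.double(counter) * 16807) %%
               2147483629) + 1L
}

#' Resample a cohort at an exactly fixed prevalence
#'
#' Stratified bootstrap: draws `round(prevalence * n_out)` records with
#' replacement from the amyloid-positive stratum and the remainder from the
#' negative stratum, so the realised prevalence of every resampled
#' population is exact by construction.
#'
#' @param cohort An `amyloid_cohort` with resolved statuses.
#' @param prevalence Target prevalence in (0, 1).
#' @param n_out Output population size (default: size of `cohort`).
#' @param seed Integer seed.
#' @return An `amyloid_cohort` of exactly `n_out` records.
#' @export
resample_fixed_prevalence <- function(cohort, prevalence, n_out = nrow(cohort),
                                      seed = 1L) {
  stopifnot(prevalence > 0, prevalence < 1, n_out >= 2)
  y <- status_binary(cohort)
  idx_p <- which(y == 1L); idx_n <- which(y == 0L)
  if (!length(idx_p) || !length(idx_n)) stop("both status strata must be non-empty")
  set.seed(as.integer(seed))
  n_pos <- as.integer(round(prevalence * n_out))
  # index into the stratum vectors (safe for single-record strata)
  take <- c(idx_p[sample.int(length(idx_p), n_pos, replace = TRUE)],
            idx_n[sample.int(length(idx_n), n_out - n_pos, replace = TRUE)])
  out <- cohort[take, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dual-cutoff bootstrap across prevalence scenarios
#'
#' For each target prevalence, generates `B` prevalence-fixed bootstrap
#' populations from the cohort, applies the model with frozen coefficients
#' (no refitting), derives dual cutoffs at `target_pv` in each population,
#' and records the negativity/positivity cutoffs, grey-zone fraction and
#' post-exclusion sensitivity/specificity. Populations where the cutoffs
#' cross or the target is unreachable are counted as degenerate and excluded
#' from the mean/SD summaries; a prevalence with more than 50% degenerate
#' populations is flagged unreliable.
#'
#' Per-population seeds derive from the master seed by a counter scheme, so
#' any subset of the (prevalence, replicate) grid reproduces in isolation.
#'
#' @param cohort An `amyloid_cohort` with resolved statuses.
#' @param model An `amyloid_fit` (frozen; refitting per resample available
#'   via `refit = TRUE` for sensitivity analysis).
#' @param prevalences Target prevalences (default `c(0.4, 0.5, 0.6)`).
#' @param B Populations per prevalence (default 1000).
#' @param target_pv Target predictive value (default 0.875).
#' @param seed Master seed.
#' @param n_out Population size (default: cohort size).
#' @param refit Refit the model in each population instead of freezing it.
#' @param grid_step Grid for the predictive-value curves.
#' @return An object of class `bootstrap_cutoff_table`: per-prevalence
#'   summaries (mean, sd of each quantity over non-degenerate populations),
#'   the per-population records, and degenerate counts.
#' @export
bootstrap_cutoff_table <- function(cohort, model, prevalences = c(0.4, 0.5, 0.6),
                                   B = 1000L, target_pv = 0.875, seed = 1L,
                                   n_out = nrow(cohort), refit = FALSE,
                                   grid_step = 0.001) {
  stopifnot(inherits(model, "amyloid_fit"))
  counter <- 0L
  per_prev <- lapply(prevalences, function(prev) {
    rec <- vector("list", B)
    for (b in seq_len(B)) {
      counter <<- counter + 1L
      pop <- resample_fixed_prevalence(cohort, prev, n_out,
                                       seed = child_seed(seed, counter))
      m <- if (refit) fit_amyloid_model(pop, model$covariate_names) else model
      p <- predict(m, pop)
      y <- status_binary(pop)
      pair <- tryCatch(find_dual_cutoffs(pv_curves(p, y, grid_step), target_pv),
                       amyloidrisk_unreachable_target = function(e) NULL)
      rec[[b]] <- if (is.null(pair) || pair$crossed) {
        data.frame(replicate = b, p_neg = NA_real_, p_pos = NA_real_,
                   grey_fraction = NA_real_, sensitivity = NA_real_,
                   specificity = NA_real_, degenerate = TRUE)
      } else {
        data.frame(replicate = b, p_neg = pair$p_neg, p_pos = pair$p_pos,
                   grey_fraction = pair$grey_fraction,
                   sensitivity = pair$post_exclusion$sensitivity,
                   specificity = pair$post_exclusion$specificity,
                   degenerate = FALSE)
      }
    }
    do.call(rbind, rec)
  })
  names(per_prev) <- sprintf("%g", prevalences)

  summ <- do.call(rbind, lapply(seq_along(prevalences), function(i) {
    d <- per_prev[[i]]
    ok <- d[!d$degenerate, , drop = FALSE]
    data.frame(prevalence = prevalences[i],
               n_populations = nrow(d), n_degenerate = sum(d$degenerate),
               unreliable = sum(d$degenerate) > 0.5 * nrow(d),
               p_neg_mean = mean(ok$p_neg), p_neg_sd = stats::sd(ok$p_neg),
               p_pos_mean = mean(ok$p_pos), p_pos_sd = stats::sd(ok$p_pos),
               grey_pct_mean = 100 * mean(ok$grey_fraction),
               grey_pct_sd = 100 * stats::sd(ok$grey_fraction),
               sens_pct_mean = 100 * mean(ok$sensitivity),
               sens_pct_sd = 100 * stats::sd(ok$sensitivity),
               spec_pct_mean = 100 * mean(ok$specificity),
               spec_pct_sd = 100 * stats::sd(ok$specificity))
  }))
  if (any(summ$unreliable))
    warning("more than 50% degenerate populations at prevalence(s): ",
            paste(summ$prevalence[summ$unreliable], collapse = ", "))
  structure(list(summary = summ, populations = per_prev, target_pv = target_pv,
                 B = B, seed = seed, refit = refit),
            class = "bootstrap_cutoff_table")
}

#' @export
print.bootstrap_cutoff_table <- function(x, ...) {
  cat(sprintf("Prevalence-fixed bootstrap (%d populations per prevalence, target PV %.3f)\n",
              x$B, x$target_pv))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  prevalence %.0f%%: lower %.3f (%.2f), upper %.3f (%.2f), grey %.1f%% (%.1f), sens %.1f%% (%.1f), spec %.1f%% (%.1f)%s\n",
                100 * s$prevalence[i], s$p_neg_mean[i], s$p_neg_sd[i],
                s$p_pos_mean[i], s$p_pos_sd[i], s$grey_pct_mean[i], s$grey_pct_sd[i],
                s$sens_pct_mean[i], s$sens_pct_sd[i],
                s$spec_pct_mean[i], s$spec_pct_sd[i],
                if (s$n_degenerate[i] > 0)
                  sprintf(" [%d degenerate]", s$n_degenerate[i]) else ""))
  }
  invisible(x)
}

#' Percentile bootstrap confidence interval for an arbitrary statistic
#'
#' @param statistic Function of a data set (vector or data frame rows).
#' @param data Vector or data frame to resample.
#' @param B Number of resamples.
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return A list: `point` (statistic on the original data), `low`, `high`,
#'   `level`, `B`.
#' @export
bootstrap_ci <- function(statistic, data, B = 2000L, seed = 1L, level = 0.95) {
  stopifnot(is.function(statistic), level > 0, level < 1)
  set.seed(as.integer(seed))
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  draw <- function() {
    idx <- sample.int(n, n, replace = TRUE)
    if (is.data.frame(data)) data[idx, , drop = FALSE] else data[idx]
  }
  reps <- vapply(seq_len(B), function(b) {
    v <- tryCatch(statistic(draw()), error = function(e) NA_real_)
    if (length(v) != 1L) NA_real_ else as.numeric(v)
  }, numeric(1))
  n_bad <- sum(is.na(reps))
  if (n_bad > 0.1 * B)
    stop("statistic undefined on ", n_bad, " of ", B, " resamples")
  qs <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE)
  list(point = as.numeric(statistic(data)), low = unname(qs[1]),
       high = unname(qs[2]), level = level, B = B, n_failed = n_bad)
}
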