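#' Rank-based AUC with DeLong confidence interval
#'
#' Computes the area under the ROC curve as the Mann–Whitney concordance
#' probability (ties between a positive and a negative score count 1/2), with
#' a 95% confidence interval from DeLong's placement-value variance by
#' default, or a seeded percentile bootstrap.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels 0/1 outcome vector (1 = positive).
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param boot_reps,boot_seed Bootstrap replicates and seed (bootstrap CI only).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `roc_result`: `auc`, `ci_low`, `ci_high`,
#'   `n_pos`, `n_neg`, and `curve`, a data frame of (fpr, tpr) points from
#'   (0,0) to (1,1).
#' @export
auc_rank <- function(scores, labels, ci_method = c("delong", "bootstrap"),
                     boot_reps = 2000L, boot_seed = 1L, conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  y <- as.integer(labels)
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both outcome classes must be present")

  r <- rank(scores)  # average ranks handle ties as 1/2
  auc <- (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  degenerate <- length(unique(scores)) == 1L
  if (degenerate) warning("constant scores: AUC = 0.5 with degenerate CI")

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (ci_method == "delong") {
    sp <- scores[y == 1L]; sn <- scores[y == 0L]
    # placement values: for each positive, fraction of negatives it beats
    v10 <- vapply(sp, function(s) (sum(sn < s) + 0.5 * sum(sn == s)) / n_neg,
                  numeric(1))
    v01 <- vapply(sn, function(s) (sum(sp > s) + 0.5 * sum(sp == s)) / n_pos,
                  numeric(1))
    se <- sqrt(stats::var(v10) / n_pos + stats::var(v01) / n_neg)
    if (!is.finite(se)) se <- 0
    ci <- c(auc - z * se, auc + z * se)
  } else {
    set.seed(as.integer(boot_seed))
    idx_p <- which(y == 1L); idx_n <- which(y == 0L)
    reps <- vapply(seq_len(boot_reps), function(b) {
      ip <- idx_p[sample.int(n_pos, n_pos, replace = TRUE)]
      iin <- idx_n[sample.int(n_neg, n_neg, replace = TRUE)]
      s <- c(scores[ip], scores[iin]); yy <- rep(1:0, c(n_pos, n_neg))
      rr <- rank(s)
      (sum(rr[yy == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
    }, numeric(1))
    ci <- unname(stats::quantile(reps, c((1 - conf_level) / 2,
                                         1 - (1 - conf_level) / 2)))
  }
  ci <- pmin(pmax(ci, 0), 1)

  # ROC curve: sweep thresholds downward over distinct scores
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1L) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0L) / n_neg, numeric(1))
  curve <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))

  structure(list(auc = auc, ci_low = min(ci[1], auc), ci_high = max(ci[2], auc),
                 n_pos = n_pos, n_neg = n_neg, curve = curve,
                 ci_method = ci_method, degenerate = degenerate),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.4f (95%% CI %.4f-%.4f, %s), n+ = %d, n- = %d\n",
              x$auc, x$ci_low, x$ci_high, x$ci_method, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$curve$fpr, x$curve$tpr, type = "l", lwd = 2,
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 main = sprintf("ROC curve (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Confusion-table metrics at a probability threshold
#'
#' Package-wide classification convention: predicted positive iff
#' `score >= threshold`. Predictive values whose denominator is empty are
#' returned `NA` with the corresponding `undefined` flag set, never silently
#' propagated.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 outcomes (1 = positive).
#' @param threshold Finite classification threshold.
#' @return A list of class `threshold_metrics`: confusion counts `tp, fp,
#'   tn, fn`, `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`,
#'   `youden_j`, `prevalence`, `threshold`, `undefined` (character vector of
#'   undefined metrics).
#' @export
metrics_at <- function(scores, labels, threshold) {
  stopifnot(is.finite(threshold), length(scores) == length(labels),
            all(labels %in% c(0, 1)))
  y <- as.integer(labels)
  pred <- scores >= threshold
  tp <- sum(pred & y == 1L); fp <- sum(pred & y == 0L)
  fn <- sum(!pred & y == 1L); tn <- sum(!pred & y == 0L)
  undef <- character(0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else { undef <- c(undef, "sensitivity"); NA_real_ }
  spec <- if (tn + fp > 0) tn / (tn + fp) else { undef <- c(undef, "specificity"); NA_real_ }
  ppv <- if (tp + fp > 0) tp / (tp + fp) else { undef <- c(undef, "ppv"); NA_real_ }
  npv <- if (tn + fn > 0) tn / (tn + fn) else { undef <- c(undef, "npv"); NA_real_ }
  n <- tp + fp + tn + fn
  structure(list(threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
                 accuracy = (tp + tn) / n,
                 youden_j = sens + spec - 1,
                 prevalence = (tp + fn) / n,
                 undefined = undef),
            class = "threshold_metrics")
}

#' @export
print.threshold_metrics <- function(x, ...) {
  cat(sprintf("threshold %.4g: sens %.3f, spec %.3f, PPV %.3f, NPV %.3f, accuracy %.3f, J %.3f\n",
              x$threshold, x$sensitivity, x$specificity, x$ppv, x$npv,
              x$accuracy, x$youden_j))
  cat(sprintf("  counts: TP %d, FP %d, TN %d, FN %d (prevalence %.3f)\n",
              x$tp, x$fp, x$tn, x$fn, x$prevalence))
  if (length(x$undefined)) cat("  undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Youden-optimal threshold
#'
#' Scans the finite candidate set of midpoints between adjacent distinct
#' scores, plus one candidate below the minimum and one above the maximum,
#' and returns the threshold maximising Youden's J = sensitivity +
#' specificity - 1. Ties are broken toward the larger threshold (higher
#' specificity).
#'
#' @inheritParams metrics_at
#' @return A list: `threshold`, `metrics` (a [metrics_at()] record).
#' @export
youden_cutoff <- function(scores, labels) {
  y <- as.integer(labels)
  if (sum(y == 1L) == 0L || sum(y == 0L) == 0L)
    stop("both outcome classes must be present")
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, s[length(s)] + 1)
  j <- vapply(cand, function(t) {
    m <- metrics_at(scores, y, t)
    m$sensitivity + m$specificity - 1
  }, numeric(1))
  best <- max(j)
  thr <- max(cand[j >= best - 1e-12])  # tie-break: larger threshold
  list(threshold = thr, metrics = metrics_at(scores, y, thr))
}

#' Predictive values from sensitivity, specificity and prevalence
#'
#' Bayes' identities:
#' `PPV = sens * prev / (sens * prev + (1 - spec) * (1 - prev))` and
#' `NPV = spec * (1 - prev) / (spec * (1 - prev) + (1 - sens) * prev)`.
#'
#' @param sens,spec,prev Rates in \[0, 1\] (vectorised).
#' @return Predictive value(s); `NA` with a warning where the denominator is
#'   zero (e.g. degenerate prevalence).
#' @export
ppv_from_rates <- function(sens, spec, prev) {
  stopifnot(all(sens >= 0 & sens <= 1), all(spec >= 0 & spec <= 1),
            all(prev >= 0 & prev <= 1))
  den <- sens * prev + (1 - spec) * (1 - prev)
  out <- ifelse(den > 0, sens * prev / den, NA_real_)
  if (anyNA(out)) warning("PPV undefined where no subject tests positive")
  out
}

#' @rdname ppv_from_rates
#' @export
npv_from_rates <- function(sens, spec, prev) {
  stopifnot(all(sens >= 0 & sens <= 1), all(spec >= 0 & spec <= 1),
            all(prev >= 0 & prev <= 1))
  den <- spec * (1 - prev) + (1 - sens) * prev
  out <- ifelse(den > 0, spec * (1 - prev) / den, NA_real_)
  if (anyNA(out)) warning("NPV undefined where no subject tests negative")
  out
}

#' Derive the p-tau181/Abeta42 fallback cutoff
#'
#' Among subjects with both the CSF Abeta42/Abeta40 ratio (which defines
#' status) and CSF p-tau181, finds the Youden-maximising cutoff on
#' p-tau181/Abeta42 under the ">= is positive" orientation, and reports the
#' marker's AUC. This is the procedure that motivates the shipped fallback
#' default of 0.0815.
#'
#' @param cohort An `amyloid_cohort`; records lacking either measurement are
#'   ignored. Statuses are (re)derived from the ratio rule.
#' @param rule [positivity_rule()] defining status from the CSF ratio.
#' @return A list: `cutoff`, `auc`, `n`, `metrics` at the cutoff.
#' @export
derive_fallback_cutoff <- function(cohort, rule = default_positivity_rule("A")) {
  ok <- !is.na(cohort$csf_ab42) & !is.na(cohort$csf_ab40) & !is.na(cohort$csf_ptau181)
  d <- cohort[ok, , drop = FALSE]
  if (nrow(d) < 4L) stop("too few subjects with both CSF measurements")
  y <- as.integer(d$csf_ab42 / d$csf_ab40 <= rule$ratio_cutoff)
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  marker <- d$csf_ptau181 / d$csf_ab42
  yc <- youden_cutoff(marker, y)
  roc <- auc_rank(marker, y)
  list(cutoff = yc$threshold, auc = roc$auc, n = nrow(d), metrics = yc$metrics)
}

#' Group comparison table by amyloid status
#'
#' Reproduces the usual baseline-characteristics layout: per-group median
#' \[IQR\] with two-sided Mann–Whitney U p-values for continuous variables,
#' and counts (%) with Chi-square p-values for categorical ones.
#'
#' @param cohort An `amyloid_cohort` with resolved statuses.
#' @param continuous,categorical Variable names to compare.
#' @return A data frame with one row per variable: group summaries, test
#'   used, p-value.
#' @export
compare_groups <- function(cohort,
                           continuous = c("age", "mmse", "storage_years",
                                          "plasma_ab40", "plasma_ab42", "plasma_ratio",
                                          "csf_ptau181", "csf_ab40", "csf_ab42"),
                           categorical = c("sex", "apoe_carrier")) {
  y <- status_binary(cohort)
  if (all(y == 1L) || all(y == 0L)) stop("both status groups must be non-empty")
  g_pos <- cohort[y == 1L, , drop = FALSE]
  g_neg <- cohort[y == 0L, , drop = FALSE]
  fmt_med <- function(v) {
    q <- stats::quantile(v, c(0.5, 0.25, 0.75), na.rm = TRUE)
    sprintf("%.3g [%.3g-%.3g]", q[1], q[2], q[3])
  }
  rows <- list()
  for (v in intersect(continuous, names(cohort))) {
    a <- g_pos[[v]]; b <- g_neg[[v]]
    if (all(is.na(a)) || all(is.na(b))) next
    p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
    rows[[v]] <- data.frame(variable = v, positive = fmt_med(a),
                            negative = fmt_med(b), test = "Mann-Whitney U",
                            p_value = p, stringsAsFactors = FALSE)
  }
  fmt_cnt <- function(v) {
    tbl <- table(v)
    paste(sprintf("%s: %d (%.1f%%)", names(tbl), as.integer(tbl),
                  100 * as.integer(tbl) / sum(tbl)), collapse = "; ")
  }
  for (v in intersect(categorical, names(cohort))) {
    tab <- table(cohort[[v]], y)
    if (nrow(tab) < 2L) next
    p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    rows[[v]] <- data.frame(variable = v, positive = fmt_cnt(g_pos[[v]]),
                            negative = fmt_cnt(g_neg[[v]]), test = "Chi-square",
                            p_value = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
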