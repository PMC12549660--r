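#' Predictive-value curves over the probability range
#'
#' For every threshold `t` on a regular grid over \[0, 1\], computes the
#' positive predictive value of the rule "positive iff p >= t" and the
#' negative predictive value of the rule "negative iff p <= t". Grid points
#' where the corresponding predicted set is empty are flagged undefined
#' (`NA`), never extrapolated.
#'
#' @param p_hat Predicted probabilities in \[0, 1\].
#' @param labels 0/1 outcomes (1 = positive).
#' @param grid_step Grid resolution (default 0.001).
#' @return An object of class `pv_curve`: data frame `curve` with columns
#'   `threshold`, `ppv`, `npv`, `n_pos_pred`, `n_neg_pred`, plus the inputs
#'   (`p_hat`, `labels`) for downstream cutoff search.
#' @export
pv_curves <- function(p_hat, labels, grid_step = 0.001) {
  stopifnot(all(p_hat >= 0 & p_hat <= 1), length(p_hat) == length(labels),
            all(labels %in% c(0, 1)), grid_step > 0, grid_step <= 0.5)
  y <- as.integer(labels)
  if (sum(y) == 0L || sum(y) == length(y)) stop("both outcome classes must be present")
  # snap accumulated floating-point error back onto the nominal grid values
  grid <- round(seq(0, 1, by = grid_step), ceiling(-log10(grid_step)) + 1)
  n <- length(p_hat)
  ord <- order(p_hat)
  sp <- p_hat[ord]
  cpos <- cumsum(y[ord])
  n_pos <- sum(y)

  n_le <- findInterval(grid, sp)                    # count p <= t
  n_lt <- findInterval(grid, sp, left.open = TRUE)  # count p <  t
  pos_le <- c(0, cpos)[n_le + 1L]
  pos_lt <- c(0, cpos)[n_lt + 1L]

  n_ge <- n - n_lt
  pos_ge <- n_pos - pos_lt
  neg_le <- n_le - pos_le

  ppv <- ifelse(n_ge > 0, pos_ge / n_ge, NA_real_)
  npv <- ifelse(n_le > 0, neg_le / n_le, NA_real_)

  structure(list(
    curve = data.frame(threshold = grid, ppv = ppv, npv = npv,
                       n_pos_pred = n_ge, n_neg_pred = n_le),
    p_hat = p_hat, labels = y, grid_step = grid_step
  ), class = "pv_curve")
}

#' @export
print.pv_curve <- function(x, ...) {
  cat(sprintf("Predictive-value curve: %d grid points (step %g), n = %d (prevalence %.3f)\n",
              nrow(x$curve), x$grid_step, length(x$p_hat), mean(x$labels)))
  invisible(x)
}

#' @export
plot.pv_curve <- function(x, target_pv = NULL, ...) {
  graphics::plot(x$curve$threshold, x$curve$ppv, type = "l", col = "firebrick",
                 lwd = 2, ylim = c(0, 1), xlab = "Probability threshold",
                 ylab = "Predictive value", main = "PPV and NPV along the probability range", ...)
  graphics::lines(x$curve$threshold, x$curve$npv, col = "steelblue", lwd = 2)
  if (!is.null(target_pv)) graphics::abline(h = target_pv, lty = 2)
  graphics::legend("bottom", col = c("firebrick", "steelblue"), lwd = 2,
                   legend = c("PPV of {p >= t}", "NPV of {p <= t}"), bty = "n")
  invisible(x)
}

#' Dual cutoffs at a target predictive value
#'
#' Solves for the cutoff pair: the positivity cutoff `p_pos` is the smallest
#' grid threshold whose (defined) PPV reaches `target_pv`, the negativity
#' cutoff `p_neg` the largest grid threshold whose (defined) NPV reaches it.
#' Probabilities strictly between the two cutoffs form the indeterminate
#' "grey zone". If the two cutoffs cross (`p_neg >= p_pos`) both are
#' reported unmodified with `crossed = TRUE` and a zero grey zone; a target
#' unreachable on one side raises an error (condition class
#' `amyloidrisk_unreachable_target`) naming the failed side.
#'
#' @param curve A [pv_curves()] result.
#' @param target_pv Target PPV and NPV (e.g. 0.875, or the secondary choice
#'   0.85).
#' @return An object of class `cutoff_pair`: `target_pv`, `p_neg`, `p_pos`,
#'   `grey_fraction`, `crossed`, and (when not crossed) `post_exclusion`
#'   with sensitivity/specificity/accuracy among classified subjects.
#' @export
find_dual_cutoffs <- function(curve, target_pv) {
  stopifnot(inherits(curve, "pv_curve"), target_pv >= 0, target_pv <= 1)
  cv <- curve$curve
  ok_ppv <- which(!is.na(cv$ppv) & cv$ppv >= target_pv)
  ok_npv <- which(!is.na(cv$npv) & cv$npv >= target_pv)
  fail <- c(if (!length(ok_ppv)) "positivity (PPV)",
            if (!length(ok_npv)) "negativity (NPV)")
  if (length(fail))
    stop(structure(class = c("amyloidrisk_unreachable_target", "error", "condition"),
                   list(message = paste0("target predictive value ", target_pv,
                                         " unreachable on the ",
                                         paste(fail, collapse = " and "), " side"),
                        call = sys.call())))
  p_pos <- cv$threshold[min(ok_ppv)]
  p_neg <- cv$threshold[max(ok_npv)]
  crossed <- p_neg >= p_pos
  p <- curve$p_hat; y <- curve$labels
  grey <- if (crossed) 0 else mean(p > p_neg & p < p_pos)
  post <- if (crossed) NULL else
    post_exclusion_metrics(p, y, list(p_neg = p_neg, p_pos = p_pos, crossed = FALSE))
  structure(list(target_pv = target_pv, p_neg = p_neg, p_pos = p_pos,
                 grey_fraction = grey, crossed = crossed, post_exclusion = post,
                 n = length(p)),
            class = "cutoff_pair")
}

#' @export
print.cutoff_pair <- function(x, ...) {
  cat(sprintf("Dual cutoffs at target PPV = NPV = %.3f\n", x$target_pv))
  if (x$crossed) {
    cat(sprintf("  CROSSED: p_neg = %.3f >= p_pos = %.3f; use a single cutoff instead\n",
                x$p_neg, x$p_pos))
  } else {
    cat(sprintf("  negativity cutoff p <= %.3f, positivity cutoff p >= %.3f\n",
                x$p_neg, x$p_pos))
    cat(sprintf("  grey zone (%.3f, %.3f): %.1f%% of subjects\n",
                x$p_neg, x$p_pos, 100 * x$grey_fraction))
    pe <- x$post_exclusion
    cat(sprintf("  after exclusion: sens %.1f%%, spec %.1f%%, accuracy %.1f%%\n",
                100 * pe$sensitivity, 100 * pe$specificity, 100 * pe$accuracy))
  }
  invisible(x)
}

#' Tri-state classification with a grey zone
#'
#' Applies a dual-cutoff rule: `"negative"` iff `p <= p_neg`, `"positive"`
#' iff `p >= p_pos` (both boundaries classified), `"indeterminate"` in the
#' open interval between them.
#'
#' @param p_hat Predicted probabilities.
#' @param pair A [find_dual_cutoffs()] result (not crossed).
#' @return Character vector in `{negative, indeterminate, positive}`.
#' @export
classify_with_greyzone <- function(p_hat, pair) {
  if (isTRUE(pair$crossed))
    stop("crossed cutoff pair: dual-cutoff classification undefined; ",
         "use a single Youden cutoff instead")
  out <- rep("indeterminate", length(p_hat))
  out[p_hat <= pair$p_neg] <- "negative"
  out[p_hat >= pair$p_pos] <- "positive"
  out
}

#' Sensitivity/specificity after grey-zone exclusion
#'
#' Computes sensitivity, specificity and accuracy among subjects classified
#' by the dual-cutoff rule; indeterminate subjects are excluded from all
#' denominators. A class that is entirely indeterminate yields `NA` for its
#' rate with an `undefined` flag.
#'
#' @param p_hat Predicted probabilities.
#' @param labels 0/1 outcomes.
#' @param pair A `cutoff_pair` (or list with `p_neg`, `p_pos`, `crossed`).
#' @return A list: `sensitivity`, `specificity`, `accuracy`,
#'   `n_classified`, `n_excluded`, `undefined`.
#' @export
post_exclusion_metrics <- function(p_hat, labels, pair) {
  if (isTRUE(pair$crossed)) stop("crossed cutoff pair: no grey zone to exclude")
  y <- as.integer(labels)
  cls <- classify_with_greyzone(p_hat, pair)
  keep <- cls != "indeterminate"
  if (!any(keep)) stop("all subjects fall in the grey zone; no classified subjects")
  pred_pos <- cls[keep] == "positive"
  yk <- y[keep]
  undef <- character(0)
  sens <- if (sum(yk == 1L) > 0) sum(pred_pos & yk == 1L) / sum(yk == 1L) else {
    undef <- c(undef, "sensitivity"); NA_real_ }
  spec <- if (sum(yk == 0L) > 0) sum(!pred_pos & yk == 0L) / sum(yk == 0L) else {
    undef <- c(undef, "specificity"); NA_real_ }
  list(sensitivity = sens, specificity = spec,
       accuracy = mean((pred_pos & yk == 1L) | (!pred_pos & yk == 0L)),
       n_classified = sum(keep), n_excluded = sum(!keep), undefined = undef)
}
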