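#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the p-value uses the exact
#' permutation distribution for n <= 10 (no ties) and the t-approximation
#' otherwise, via [stats::cor.test()].
#'
#' @param x,y Numeric vectors (n >= 3).
#' @return A list: `rho`, `p`, `n`; `rho` is `NA` with a warning for a
#'   constant input.
#' @export
spearman_assoc <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  }
  exact <- length(x) <= 10
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = exact))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Deming (errors-in-variables) regression
#'
#' Closed-form Deming fit of `y` on `x` when both variables carry
#' measurement error. `lambda` is the ratio of error variances
#' `var(error in y) / var(error in x)`; `lambda = 1` gives orthogonal
#' regression and `lambda -> Inf` recovers ordinary least squares of `y` on
#' `x`. The slope is
#' `(syy - lambda*sxx + sqrt((syy - lambda*sxx)^2 + 4*lambda*sxy^2)) / (2*sxy)`
#' and the intercept `mean(y) - slope * mean(x)`.
#'
#' @param x,y Numeric vectors (n >= 3).
#' @param lambda Error-variance ratio (default 1).
#' @return A list: `slope`, `intercept`, `lambda`, `n`.
#' @export
deming_fit <- function(x, y, lambda = 1) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  stopifnot(is.numeric(lambda), lambda > 0)
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  if (sxx == 0 && syy == 0) stop("zero variance in both variables: fit undefined")
  if (sxy == 0) stop("zero covariance: Deming slope undefined")
  slope <- (syy - lambda * sxx + sqrt((syy - lambda * sxx)^2 + 4 * lambda * sxy^2)) /
    (2 * sxy)
  list(slope = slope, intercept = mean(y) - slope * mean(x),
       lambda = lambda, n = length(x))
}

#' Plasma–CSF agreement statistics for a cohort
#'
#' Spearman correlation and Deming regression between the plasma and CSF
#' Abeta42/Abeta40 ratios of a cohort (records with both available).
#'
#' @param cohort An `amyloid_cohort`.
#' @param lambda Error-variance ratio for the Deming fit.
#' @return A list of class `association_result`: `spearman_rho`,
#'   `spearman_p`, `deming_slope`, `deming_intercept`, `lambda`, `n`.
#' @export
plasma_csf_association <- function(cohort, lambda = 1) {
  csf_ratio <- cohort$csf_ab42 / cohort$csf_ab40
  ok <- !is.na(csf_ratio) & !is.na(cohort$plasma_ratio)
  sp <- spearman_assoc(cohort$plasma_ratio[ok], csf_ratio[ok])
  dm <- deming_fit(cohort$plasma_ratio[ok], csf_ratio[ok], lambda = lambda)
  structure(list(spearman_rho = sp$rho, spearman_p = sp$p,
                 deming_slope = dm$slope, deming_intercept = dm$intercept,
                 lambda = lambda, n = sp$n),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("Plasma-CSF Abeta42/Abeta40 agreement (n = %d)\n", x$n))
  cat(sprintf("  Spearman rho = %.3f (p = %.3g)\n", x$spearman_rho, x$spearman_p))
  cat(sprintf("  Deming slope = %.3f, intercept = %.4f (lambda = %g)\n",
              x$deming_slope, x$deming_intercept, x$lambda))
  invisible(x)
}
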