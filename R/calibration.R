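#' Logistic recalibration slope and intercept
#'
#' Two-step recalibration in the validation-literature convention: the
#' calibration slope is the coefficient of `logit(p_hat)` in a logistic
#' regression of the outcome on `logit(p_hat)`; the calibration intercept is
#' the intercept of a logistic regression with `logit(p_hat)` entered as a
#' fixed offset (slope held at 1). Ideal values are 1 and 0.
#'
#' @param p_hat Predicted probabilities; values outside
#'   `[1e-10, 1 - 1e-10]` are clipped for logit stability (counted and
#'   warned about).
#' @param labels 0/1 outcomes (1 = positive).
#' @return A list: `slope`, `intercept`, `n_clipped`, `separation` flag.
#' @export
recalibration_coefficients <- function(p_hat, labels) {
  y <- as.integer(labels)
  stopifnot(length(p_hat) == length(y), all(y %in% c(0, 1)))
  if (all(y == 1L) || all(y == 0L)) stop("both outcome classes must be present")
  eps <- 1e-10
  n_clipped <- sum(p_hat < eps | p_hat > 1 - eps)
  if (n_clipped > 0)
    warning(n_clipped, " probability value(s) clipped to [1e-10, 1-1e-10] for logit")
  lp <- stats::qlogis(pmin(pmax(p_hat, eps), 1 - eps))

  f_slope <- suppressWarnings(stats::glm(y ~ lp, family = stats::binomial()))
  f_int <- suppressWarnings(stats::glm(y ~ 1 + offset(lp), family = stats::binomial()))
  sep <- any(f_slope$fitted.values > 1 - 1e-8) || any(f_slope$fitted.values < 1e-8)
  if (sep) warning("possible separation on the logit scale; coefficients unstable")
  list(slope = unname(stats::coef(f_slope)[2]),
       intercept = unname(stats::coef(f_int)[1]),
       n_clipped = n_clipped, separation = sep)
}

#' Flexible (LOESS) calibration curve
#'
#' Local linear regression of the 0/1 outcome on the predicted probability
#' with tricube weights ([stats::loess()], degree 1, direct surface),
#' evaluated on a probability grid. Grid points outside the observed range
#' of `p_hat` are flagged `NA` rather than extrapolated; smoothed values
#' outside \[0, 1\] are reported as-is (count returned), never silently
#' clamped.
#'
#' @inheritParams recalibration_coefficients
#' @param span LOESS span in (0, 1\] (default 0.75).
#' @param grid Evaluation grid (default `seq(0, 1, by = 0.01)`).
#' @return A data frame `(predicted, observed)` with attribute
#'   `"n_out_of_range"`, the number of smoothed values outside \[0, 1\].
#' @export
loess_curve <- function(p_hat, labels, span = 0.75, grid = seq(0, 1, by = 0.01)) {
  y <- as.integer(labels)
  stopifnot(length(p_hat) >= 20, span > 0, span <= 1)
  fit <- stats::loess(y ~ p, data = data.frame(p = p_hat, y = y),
                      span = span, degree = 1, family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  inside <- grid >= min(p_hat) & grid <= max(p_hat)
  obs <- rep(NA_real_, length(grid))
  obs[inside] <- stats::predict(fit, newdata = data.frame(p = grid[inside]))
  out <- data.frame(predicted = grid, observed = obs)
  attr(out, "n_out_of_range") <- sum(obs < 0 | obs > 1, na.rm = TRUE)
  out
}

#' Bootstrap-averaged model calibration
#'
#' Runs `n_boot` bootstrap cycles; in each, the data are resampled (at an
#' exactly fixed prevalence when `prevalence_target` is given, ordinary
#' bootstrap otherwise), recalibration coefficients are estimated and a
#' LOESS calibration curve computed. Reports the mean slope and intercept
#' over cycles and the point-wise mean curve with its min/max envelope.
#'
#' @inheritParams recalibration_coefficients
#' @param n_boot Bootstrap cycles (default 1000).
#' @param seed Master seed (per-cycle seeds derived by counter).
#' @param prevalence_target Optional prevalence fixed in every resample.
#' @param span,grid Passed to [loess_curve()].
#' @return An object of class `calibration_result`: `slope`, `intercept`
#'   (cycle means), `per_cycle` (slopes/intercepts), `curve`
#'   (grid, mean, envelope_low, envelope_high), `n_boot`, `n_failed`.
#' @export
bootstrap_calibration <- function(p_hat, labels, n_boot = 1000L, seed = 1L,
                                  prevalence_target = NULL, span = 0.75,
                                  grid = seq(0, 1, by = 0.01)) {
  y <- as.integer(labels)
  stopifnot(length(p_hat) == length(y))
  n <- length(y)
  idx_p <- which(y == 1L); idx_n <- which(y == 0L)
  slopes <- intercepts <- rep(NA_real_, n_boot)
  curves <- matrix(NA_real_, nrow = n_boot, ncol = length(grid))
  for (b in seq_len(n_boot)) {
    set.seed(child_seed(seed, b))
    if (is.null(prevalence_target)) {
      take <- sample.int(n, n, replace = TRUE)
    } else {
      n_pos <- as.integer(round(prevalence_target * n))
      take <- c(idx_p[sample.int(length(idx_p), n_pos, replace = TRUE)],
                idx_n[sample.int(length(idx_n), n - n_pos, replace = TRUE)])
    }
    ok <- tryCatch({
      rc <- suppressWarnings(recalibration_coefficients(p_hat[take], y[take]))
      cv <- loess_curve(p_hat[take], y[take], span = span, grid = grid)
      slopes[b] <- rc$slope; intercepts[b] <- rc$intercept
      curves[b, ] <- cv$observed
      TRUE
    }, error = function(e) FALSE)
  }
  n_failed <- sum(is.na(slopes))
  if (n_failed > 0.05 * n_boot)
    warning("more than 5% of bootstrap cycles failed (", n_failed, "/", n_boot, ")")
  curve <- data.frame(
    predicted = grid,
    observed_mean = colMeans(curves, na.rm = TRUE),
    envelope_low = suppressWarnings(apply(curves, 2, min, na.rm = TRUE)),
    envelope_high = suppressWarnings(apply(curves, 2, max, na.rm = TRUE))
  )
  curve$observed_mean[!is.finite(curve$observed_mean)] <- NA_real_
  curve$envelope_low[!is.finite(curve$envelope_low)] <- NA_real_
  curve$envelope_high[!is.finite(curve$envelope_high)] <- NA_real_
  structure(list(slope = mean(slopes, na.rm = TRUE),
                 intercept = mean(intercepts, na.rm = TRUE),
                 per_cycle = data.frame(slope = slopes, intercept = intercepts),
                 curve = curve, n_boot = n_boot, n_failed = n_failed,
                 span = span, seed = seed,
                 prevalence_target = prevalence_target),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Bootstrap calibration (%d cycles%s)\n", x$n_boot,
              if (!is.null(x$prevalence_target))
                sprintf(", prevalence fixed at %.0f%%", 100 * x$prevalence_target)
              else ""))
  cat(sprintf("  mean slope = %.3f (ideal 1), mean intercept = %.3f (ideal 0)\n",
              x$slope, x$intercept))
  if (x$n_failed > 0) cat(sprintf("  %d cycle(s) failed\n", x$n_failed))
  invisible(x)
}

#' @export
plot.calibration_result <- function(x, ...) {
  cv <- x$curve[!is.na(x$curve$observed_mean), ]
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "Predicted probability", ylab = "Observed proportion",
                 main = sprintf("Flexible calibration (slope %.2f, intercept %.2f)",
                                x$slope, x$intercept), ...)
  graphics::polygon(c(cv$predicted, rev(cv$predicted)),
                    c(cv$envelope_low, rev(cv$envelope_high)),
                    col = grDevices::adjustcolor("steelblue", 0.2), border = NA)
  graphics::lines(cv$predicted, cv$observed_mean, col = "steelblue", lwd = 2)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
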