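#' Fit the plasma amyloid risk model
#'
#' Maximum-likelihood logistic regression of CSF amyloid status on the plasma
#' Abeta42/Abeta40 ratio, age (years, untransformed) and APOE epsilon-4
#' carriage (dichotomised). Fitting is iteratively reweighted least squares
#' via [stats::glm()]; quasi-complete separation is detected (fitted
#' probabilities numerically 0 or 1) and flagged with a warning rather than
#' silently diverging. Covariates with zero variance are dropped from the
#' design with a warning and their coefficients reported as 0.
#'
#' A ratio-only reference model is fitted alongside so the improvement in
#' Akaike Information Criterion from adding age and APOE can always be read
#' off the fit (`$aic_ratio_only`).
#'
#' @param cohort An `amyloid_cohort` with `amyloid_status` resolved for every
#'   record (`"positive"`/`"negative"`); at least 2 records per class.
#' @param covariates Character vector of covariate columns; default
#'   `c("plasma_ratio", "age", "apoe_carrier")`.
#' @return An object of class `amyloid_fit` with components `beta` (named,
#'   intercept first), `se`, `vcov`, `loglik`, `aic`, `aic_ratio_only`, `n`,
#'   `covariate_names`, `training_prevalence`, `converged`, `separation`.
#' @examples
#' cohort <- generate_cohort(default_synthetic_spec(), seed = 1)
#' fit <- fit_amyloid_model(cohort[cohort$cohort == "A", ])
#' fit
#' @export
fit_amyloid_model <- function(cohort,
                              covariates = c("plasma_ratio", "age", "apoe_carrier")) {
  y <- status_binary(cohort)
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L)
    stop("need at least 2 records in each outcome class (have ",
         sum(y == 1L), " positive, ", sum(y == 0L), " negative)")
  X <- as.data.frame(lapply(cohort[covariates], as.numeric))
  if (anyNA(X)) stop("missing covariate values; complete cases required for fitting")

  keep <- vapply(X, function(v) stats::var(v) > 0, logical(1))
  if (!all(keep))
    warning("zero-variance covariate(s) dropped from design: ",
            paste(covariates[!keep], collapse = ", "))
  dat <- cbind(y = y, X[, keep, drop = FALSE])

  fit <- stats::glm(y ~ ., data = dat, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  sep <- any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)
  if (sep) warning("possible complete separation: fitted probabilities numerically 0 or 1")

  beta <- stats::setNames(numeric(length(covariates) + 1L),
                          c("(Intercept)", covariates))
  se <- vc <- NULL
  cf <- stats::coef(fit)
  beta[c("(Intercept)", covariates[keep])] <- cf
  se <- stats::setNames(numeric(length(beta)), names(beta))
  se[c("(Intercept)", covariates[keep])] <- sqrt(diag(stats::vcov(fit)))
  vc <- stats::vcov(fit)

  ll <- as.numeric(stats::logLik(fit))
  aic_ratio <- NA_real_
  if ("plasma_ratio" %in% covariates && stats::var(X$plasma_ratio) > 0) {
    fr <- stats::glm(y ~ plasma_ratio, data = dat, family = stats::binomial())
    aic_ratio <- stats::AIC(fr)
  }

  structure(list(
    beta = beta, se = se, vcov = vc,
    loglik = ll, aic = -2 * ll + 2 * length(cf),
    aic_ratio_only = aic_ratio,
    n = length(y), covariate_names = covariates,
    training_prevalence = mean(y),
    converged = fit$converged, separation = sep,
    fitted = as.numeric(fit$fitted.values),
    y = y, ids = cohort$id
  ), class = "amyloid_fit")
}

#' Construct an `amyloid_fit` from frozen coefficients
#'
#' Builds a model object from externally supplied coefficients (for example
#' coefficients published for a training cohort) so it can be applied to new
#' cohorts without refitting.
#'
#' @param beta Named or unnamed length `k+1` coefficient vector, intercept
#'   first, covariates in the order of `covariates`.
#' @param covariates Covariate column names the coefficients refer to.
#' @return An `amyloid_fit` (without likelihood information).
#' @export
amyloid_model_from_coefficients <- function(beta,
                                            covariates = c("plasma_ratio", "age", "apoe_carrier")) {
  stopifnot(length(beta) == length(covariates) + 1L)
  structure(list(
    beta = stats::setNames(as.numeric(beta), c("(Intercept)", covariates)),
    se = NULL, vcov = NULL, loglik = NA_real_, aic = NA_real_,
    aic_ratio_only = NA_real_, n = NA_integer_, covariate_names = covariates,
    training_prevalence = NA_real_, converged = NA, separation = NA,
    fitted = NULL, y = NULL, ids = NULL
  ), class = "amyloid_fit")
}

#' @export
coef.amyloid_fit <- function(object, ...) object$beta

#' @export
print.amyloid_fit <- function(x, digits = 4, ...) {
  cat("Plasma amyloid-positivity logistic model\n")
  cat("  covariates:", paste(x$covariate_names, collapse = ", "), "\n")
  print(round(x$beta, digits))
  if (!is.na(x$aic))
    cat(sprintf("  n = %d, logLik = %.3f, AIC = %.2f (ratio-only AIC = %.2f)\n",
                x$n, x$loglik, x$aic, x$aic_ratio_only))
  if (!is.na(x$training_prevalence))
    cat(sprintf("  training prevalence = %.3f\n", x$training_prevalence))
  if (isTRUE(x$separation)) cat("  WARNING: possible complete separation\n")
  invisible(x)
}

#' @export
summary.amyloid_fit <- function(object, ...) {
  tab <- cbind(estimate = object$beta, se = object$se,
               z = object$beta / object$se,
               p = 2 * stats::pnorm(-abs(object$beta / object$se)))
  structure(list(coefficients = tab, loglik = object$loglik, aic = object$aic,
                 aic_ratio_only = object$aic_ratio_only, n = object$n,
                 training_prevalence = object$training_prevalence),
            class = "summary.amyloid_fit")
}

#' @export
print.summary.amyloid_fit <- function(x, ...) {
  cat("Plasma amyloid-positivity logistic model\n\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nn = %d, logLik = %.3f, AIC = %.2f (ratio-only AIC = %.2f)\n",
              x$n, x$loglik, x$aic, x$aic_ratio_only))
  invisible(x)
}

# design matrix (with intercept) for a cohort under a model's covariates
model_design <- function(object, cohort) {
  miss_col <- setdiff(object$covariate_names, names(cohort))
  if (length(miss_col)) stop("cohort lacks covariate column(s): ",
                             paste(miss_col, collapse = ", "))
  X <- vapply(object$covariate_names, function(cv) as.numeric(cohort[[cv]]),
              numeric(nrow(cohort)))
  X <- matrix(X, nrow = nrow(cohort),
              dimnames = list(NULL, object$covariate_names))
  if (anyNA(X) || any(!is.finite(X))) {
    bad <- which(apply(X, 1, function(r) any(is.na(r) | !is.finite(r))))
    flds <- vapply(bad, function(i)
      paste(object$covariate_names[is.na(X[i, ]) | !is.finite(X[i, ])],
            collapse = ","), character(1))
    stop("missing/non-finite covariates in record(s) ",
         paste(sprintf("%s[%s]", bad, flds), collapse = "; "))
  }
  cbind(`(Intercept)` = 1, X)
}

#' Predicted probability of CSF amyloid positivity
#'
#' @param object An `amyloid_fit`.
#' @param newdata An `amyloid_cohort` (or data frame with the model's
#'   covariate columns). Omitted: returns fitted training probabilities.
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1), in input row order.
#' @export
predict.amyloid_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(object$fitted)) stop("no training data stored; supply newdata")
    return(object$fitted)
  }
  eta <- drop(model_design(object, newdata) %*% object$beta)
  stats::plogis(eta)
}

#' Simulate amyloid-status outcomes from a fitted model
#'
#' Draws Bernoulli outcomes at the model's predicted probabilities — useful
#' for calibration recovery experiments and parametric checks.
#'
#' @param object An `amyloid_fit`.
#' @param nsim Number of simulated outcome vectors.
#' @param seed Optional seed.
#' @param newdata Cohort to simulate for (default: training data).
#' @param ... Unused.
#' @return A data frame with `nsim` columns of 0/1 outcomes.
#' @export
simulate.amyloid_fit <- function(object, nsim = 1, seed = NULL, newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict(object, newdata = newdata)
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1L, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
residuals.amyloid_fit <- function(object, type = c("deviance", "response"), ...) {
  type <- match.arg(type)
  if (is.null(object$fitted)) stop("no training data stored")
  p <- object$fitted; y <- object$y
  if (type == "response") return(y - p)
  sign(y - p) * sqrt(-2 * (y * log(p) + (1 - y) * log(1 - p)))
}

#' Plot the distribution of predicted probabilities by amyloid status
#'
#' @param x An `amyloid_fit`.
#' @param newdata Optional cohort (with statuses) to plot instead of the
#'   training data.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.amyloid_fit <- function(x, newdata = NULL, ...) {
  if (is.null(newdata)) {
    p <- x$fitted; y <- x$y
  } else {
    p <- predict(x, newdata); y <- status_binary(newdata)
  }
  br <- seq(0, 1, by = 0.05)
  h1 <- graphics::hist(p[y == 1], breaks = br, plot = FALSE)
  h0 <- graphics::hist(p[y == 0], breaks = br, plot = FALSE)
  ylim <- c(0, max(h1$counts, h0$counts))
  graphics::plot(h0, col = grDevices::adjustcolor("steelblue", 0.6), ylim = ylim,
                 xlab = "Predicted probability of amyloid positivity",
                 main = "Predicted probabilities by CSF amyloid status", ...)
  graphics::plot(h1, col = grDevices::adjustcolor("firebrick", 0.6), add = TRUE)
  graphics::legend("top", fill = grDevices::adjustcolor(c("steelblue", "firebrick"), 0.6),
                   legend = c("CSF-amyloid negative", "CSF-amyloid positive"), bty = "n")
  invisible(x)
}

#' Externally validate a fitted model on an independent cohort
#'
#' Applies a model with frozen coefficients (no refitting) to a validation
#' cohort and evaluates discrimination: predicted probabilities, ROC/AUC
#' with confidence interval, and threshold metrics at the maximum Youden
#' index. Overlapping participant ids between training and validation data
#' trigger a leakage warning.
#'
#' @param model An `amyloid_fit` fitted on a disjoint cohort.
#' @param cohort Validation `amyloid_cohort` with resolved statuses.
#' @return A list of class `external_validation`: `p_hat`, `roc`
#'   (see [auc_rank()]), `youden` (threshold + [metrics_at()] record).
#' @export
external_validate <- function(model, cohort) {
  if (!is.null(model$ids)) {
    overlap <- intersect(model$ids, cohort$id)
    if (length(overlap))
      warning("training/validation overlap for ", length(overlap),
              " id(s); external validation assumes disjoint cohorts")
  }
  p <- predict(model, cohort)
  y <- status_binary(cohort)
  roc <- auc_rank(p, y)
  yj <- youden_cutoff(p, y)
  structure(list(p_hat = p, roc = roc, youden = yj, n = length(y),
                 prevalence = mean(y)), class = "external_validation")
}

#' @export
print.external_validation <- function(x, ...) {
  cat("External validation (frozen coefficients)\n")
  cat(sprintf("  n = %d, prevalence = %.1f%%\n", x$n, 100 * x$prevalence))
  cat(sprintf("  AUC = %.3f (95%% CI %.3f-%.3f)\n",
              x$roc$auc, x$roc$ci_low, x$roc$ci_high))
  m <- x$youden$metrics
  cat(sprintf("  at Youden threshold %.3f: sens %.3f, spec %.3f, PPV %.3f, NPV %.3f, accuracy %.1f%%\n",
              x$youden$threshold, m$sensitivity, m$specificity, m$ppv, m$npv,
              100 * m$accuracy))
  invisible(x)
}
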