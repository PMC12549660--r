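test_that("fitting recovers generating coefficients at large n", {
  beta_true <- c(14, -70, -0.02, 1.2)
  co <- generate_from_true_model(beta_true, n = 5000, seed = 7)
  fit <- fit_amyloid_model(co)
  z <- (fit$beta - beta_true) / fit$se
  expect_true(all(abs(z) < 3),
              label = paste("standardised errors:", paste(round(z, 2), collapse = " ")))
})

test_that("intercept-only likelihood on a balanced 2+2 cohort is closed form", {
  df <- toy_cohort_df()[c(1, 1, 2, 2), ]
  df$id <- paste0("r", 1:4)
  df$amyloid_status <- c("positive", "positive", "negative", "negative")
  df$age <- 70; df$apoe_e4_count <- 1
  df$plasma_ab40 <- 200; df$plasma_ab42 <- 40  # all covariates constant
  co <- as_cohort(df)
  expect_warning(fit <- fit_amyloid_model(co), "zero-variance")
  expect_equal(unname(fit$beta["(Intercept)"]), 0, tolerance = 1e-6)
  expect_equal(unname(fit$beta[c("plasma_ratio", "age", "apoe_carrier")]),
               c(0, 0, 0))
  expect_equal(fit$loglik, 4 * log(0.5), tolerance = 1e-8)
})

test_that("fewer than two records per class is an error", {
  df <- toy_cohort_df()
  df$amyloid_status <- c("positive", "negative", "negative")
  expect_error(fit_amyloid_model(as_cohort(df)), "at least 2 records")
})

test_that("complete separation is flagged, not silently divergent", {
  co <- default_cohort_cached()
  d <- co[order(co$plasma_ratio), ][1:40, ]
  d$amyloid_status <- rep(c("positive", "negative"), each = 20)
  d$sep <- as.numeric(d$amyloid_status == "positive")  # perfect separator
  w <- capture_warnings(fit <- fit_amyloid_model(d, covariates = c("sep")))
  expect_true(any(grepl("separation", w)))
  expect_true(fit$separation)
})

test_that("predicted probabilities follow the logistic form and input order", {
  fit <- amyloid_model_from_coefficients(c(0, 1, 0, 0))
  d <- data.frame(plasma_ratio = c(0, 50, -50), age = 70, apoe_carrier = 0)
  p <- predict(fit, d)
  expect_equal(p[1], 0.5)
  expect_gte(p[2], 1 - 1e-20)
  expect_lte(p[3], 1e-20)

  co <- default_cohort_cached()
  f <- fit_amyloid_model(co)
  p_all <- predict(f, co)
  expect_true(all(p_all > 0 & p_all < 1))
  perm <- rev(seq_len(nrow(co)))
  expect_equal(predict(f, co[perm, ]), p_all[perm])
})

test_that("missing covariates in prediction are reported per record", {
  fit <- amyloid_model_from_coefficients(c(0, 1, 0, 0))
  d <- data.frame(plasma_ratio = c(0.2, NA), age = c(70, 71), apoe_carrier = 0)
  expect_error(predict(fit, d), "plasma_ratio")
  expect_error(predict(fit, d[, c("age", "apoe_carrier")]), "lacks covariate")
})

test_that("AIC identity holds and the full model beats ratio-only on synthetic data", {
  co <- default_cohort_cached()
  fit <- fit_amyloid_model(co)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * 4, tolerance = 1e-9)
  expect_lt(fit$aic, fit$aic_ratio_only)  # age + APOE add real signal here
})

test_that("mean fitted probability equals sample prevalence (score equation)", {
  co <- default_cohort_cached()
  fit <- fit_amyloid_model(co)
  expect_equal(mean(fit$fitted), mean(status_binary(co)), tolerance = 1e-6)
})

test_that("affine covariate rescaling rescales the coefficient, not the fit", {
  co <- default_cohort_cached()
  fit <- fit_amyloid_model(co)
  co2 <- co
  co2$age <- co2$age / 10
  fit2 <- fit_amyloid_model(co2)
  expect_equal(unname(fit2$beta["age"]), unname(fit$beta["age"] * 10),
               tolerance = 1e-4)
  expect_equal(predict(fit2, co2), predict(fit, co), tolerance = 1e-8)
})

test_that("external validation freezes coefficients and flags id overlap", {
  co <- default_cohort_cached()
  coh_a <- co[co$cohort == "A", ]
  coh_b <- co[co$cohort == "B", ]
  fit <- fit_amyloid_model(coh_a)
  ev <- external_validate(fit, coh_b)
  expect_equal(ev$p_hat, predict(fit, coh_b))
  # applied to its own training set: identical to predict
  expect_warning(ev_self <- external_validate(fit, coh_a), "overlap")
  expect_equal(ev_self$p_hat, predict(fit, coh_a))
  # validation AUC within sampling error of training AUC (same process)
  auc_train <- auc_rank(predict(fit, coh_a), status_binary(coh_a))$auc
  expect_lt(abs(ev$roc$auc - auc_train), 0.1)
})

test_that("flipping validation labels mirrors the AUC", {
  co <- default_cohort_cached()
  coh_b <- co[co$cohort == "B", ]
  fit <- fit_amyloid_model(co[co$cohort == "A", ])
  flipped <- coh_b
  flipped$amyloid_status <- ifelse(coh_b$amyloid_status == "positive",
                                   "negative", "positive")
  ev <- external_validate(fit, coh_b)
  ev_flip <- external_validate(fit, flipped)
  expect_equal(ev_flip$roc$auc, 1 - ev$roc$auc, tolerance = 1e-12)
})

test_that("simulate() draws outcomes at the fitted probabilities", {
  co <- default_cohort_cached()
  fit <- fit_amyloid_model(co)
  sims <- simulate(fit, nsim = 50, seed = 5)
  expect_equal(dim(sims), c(450L, 50L))
  expect_lt(abs(mean(as.matrix(sims)) - mean(fit$fitted)), 0.02)
  expect_identical(simulate(fit, nsim = 2, seed = 8), simulate(fit, nsim = 2, seed = 8))
})
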