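test_that("rank AUC matches exhaustive pair counting and symmetry", {
  scores <- c(0.9, 0.8, 0.85, 0.7)
  labels <- c(1, 1, 0, 0)
  # pairs: (0.9,0.85)+ (0.9,0.7)+ (0.8,0.85)- (0.8,0.7)+ -> 3/4
  r <- auc_rank(scores, labels)
  expect_equal(r$auc, 0.75)

  expect_equal(auc_rank(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(auc_rank(scores, 1 - labels)$auc, 1 - 0.75)

  # ties between classes count one half
  expect_equal(suppressWarnings(auc_rank(c(1, 1), c(0, 1))$auc), 0.5)

  expect_error(auc_rank(scores, c(1, 1, 1, 1)), "both outcome classes")
  expect_warning(r0 <- auc_rank(c(2, 2, 2), c(1, 0, 1)), "constant scores")
  expect_equal(r0$auc, 0.5)
})

test_that("AUC equals the trapezoidal area under its own ROC curve", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(10:80, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), sample(c(1, 2, 7), 1))  # induce ties sometimes
    r <- auc_rank(s, y)
    cv <- r$curve
    trap <- sum(diff(cv$fpr) * (head(cv$tpr, -1) + tail(cv$tpr, -1)) / 2)
    expect_equal(r$auc, trap, tolerance = 1e-12)
    expect_true(all(diff(cv$fpr) >= 0) && all(diff(cv$tpr) >= 0))
    expect_equal(unlist(cv[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(cv[nrow(cv), ]), c(fpr = 1, tpr = 1))
    expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  }
})

test_that("DeLong and bootstrap intervals agree with pROC on a fixture", {
  skip_if_not_installed("pROC")
  set.seed(8)
  y <- rbinom(120, 1, 0.5)
  s <- y * 0.8 + rnorm(120)
  r <- auc_rank(s, y)
  pr <- pROC::roc(y, s, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(r$ci_low, ci[1], tolerance = 1e-6)
  expect_equal(r$ci_high, ci[3], tolerance = 1e-6)

  rb <- auc_rank(s, y, ci_method = "bootstrap", boot_reps = 500, boot_seed = 2)
  expect_lt(abs(rb$ci_low - ci[1]), 0.05)
  expect_lt(abs(rb$ci_high - ci[3]), 0.05)
})

test_that("threshold metrics count the confusion table exactly", {
  ts <- toy_scores()
  m <- metrics_at(ts$p, ts$y, 0.5)
  expect_equal(c(m$tp, m$fp, m$tn, m$fn), c(3, 1, 3, 1))
  expect_equal(m$sensitivity, 3 / 4)
  expect_equal(m$specificity, 3 / 4)
  expect_equal(m$youden_j, m$sensitivity + m$specificity - 1)
  expect_equal(m$prevalence, 0.5)

  lo <- metrics_at(ts$p, ts$y, min(ts$p) - 1)
  expect_equal(c(lo$sensitivity, lo$specificity), c(1, 0))
  hi <- metrics_at(ts$p, ts$y, max(ts$p) + 1)
  expect_equal(c(hi$sensitivity, hi$specificity), c(0, 1))
  expect_true("ppv" %in% hi$undefined)
  expect_true(is.na(hi$ppv))
})

test_that("threshold-count PPV matches the rate-based identity exactly", {
  ts <- toy_scores()
  for (t in c(0.25, 0.45, 0.65)) {
    m <- metrics_at(ts$p, ts$y, t)
    expect_equal(m$ppv,
                 ppv_from_rates(m$sensitivity, m$specificity, m$prevalence),
                 tolerance = 1e-12)
    expect_equal(m$npv,
                 npv_from_rates(m$sensitivity, m$specificity, m$prevalence),
                 tolerance = 1e-12)
  }
})

test_that("Youden search equals a brute-force scan and breaks ties upward", {
  ts <- toy_scores()
  yc <- youden_cutoff(ts$p, ts$y)
  expect_equal(yc$metrics$youden_j, brute_youden_j(ts$p, ts$y), tolerance = 1e-12)

  # separated classes: any threshold in (0.2, 0.8) attains J = 1; midpoint rule -> 0.5
  yc2 <- youden_cutoff(c(0.8, 0.9, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(yc2$threshold, 0.5)
  expect_equal(yc2$metrics$youden_j, 1)

  # tie in J: the larger threshold (higher specificity) is returned
  p3 <- c(0.1, 0.4, 0.6, 0.9); y3 <- c(0, 1, 0, 1)
  yc3 <- youden_cutoff(p3, y3)
  cand_j <- vapply(c(0.25, 0.75), function(t) {
    m <- metrics_at(p3, y3, t); m$youden_j
  }, numeric(1))
  expect_equal(cand_j[1], cand_j[2])  # genuinely tied
  expect_equal(yc3$threshold, 0.75)

  set.seed(17)
  for (i in 1:30) {
    n <- sample(6:60, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    s <- round(runif(n), 2)
    expect_equal(youden_cutoff(s, y)$metrics$youden_j, brute_youden_j(s, y),
                 tolerance = 1e-12)
  }
})

test_that("predictive values follow Bayes identities and prevalence monotonicity", {
  expect_equal(round(ppv_from_rates(0.82, 0.80, 0.62), 2), 0.87)
  expect_equal(round(ppv_from_rates(0.81, 0.85, 0.70), 2), 0.93)
  expect_equal(ppv_from_rates(1, 1, 0.5), 1)
  expect_equal(npv_from_rates(1, 1, 0.5), 1)
  expect_warning(v <- ppv_from_rates(0, 1, 0), "undefined")
  expect_true(is.na(v))

  set.seed(5)
  for (i in 1:50) {
    sens <- runif(1, 0.05, 0.99); spec <- runif(1, 0.05, 0.99)
    prev <- sort(runif(5, 0.01, 0.99))
    expect_true(all(diff(ppv_from_rates(sens, spec, prev)) >= -1e-12))
    expect_true(all(diff(npv_from_rates(sens, spec, prev)) <= 1e-12))
  }
})

test_that("fallback cutoff derivation is Youden-optimal and orientation-consistent", {
  co <- default_cohort_cached()
  res <- derive_fallback_cutoff(co, default_positivity_rule("pooled"))
  expect_gt(res$auc, 0.9)  # p-tau181/Abeta42 separates the groups strongly
  expect_gt(res$cutoff, 0)

  # degenerate marker equal to the status indicator
  both <- !is.na(co$csf_ab42) & !is.na(co$csf_ab40) & !is.na(co$csf_ptau181)
  d <- co[both, ][1:50, ]
  y <- as.integer(d$csf_ab42 / d$csf_ab40 <= 0.0685)
  expect_equal(auc_rank(y, y)$auc, 1.0)

  # negated marker under flipped labels selects the mirrored cutoff
  marker <- d$csf_ptau181 / d$csf_ab42
  yc <- youden_cutoff(marker, y)
  yc_neg <- youden_cutoff(-marker, 1 - y)
  expect_equal(yc_neg$threshold, -yc$threshold, tolerance = 1e-9)
  expect_equal(yc_neg$metrics$youden_j, yc$metrics$youden_j, tolerance = 1e-12)
})

test_that("group comparison table uses the right tests and reproduces shifts", {
  co <- default_cohort_cached()
  tab <- compare_groups(co)
  expect_true(all(c("plasma_ratio", "apoe_carrier") %in% tab$variable))
  expect_lt(tab$p_value[tab$variable == "plasma_ratio"], 1e-10)
  expect_lt(tab$p_value[tab$variable == "apoe_carrier"], 1e-6)
  expect_equal(tab$test[tab$variable == "age"], "Mann-Whitney U")
  expect_equal(tab$test[tab$variable == "sex"], "Chi-square")

  # identical groups: Mann-Whitney p approximately 1
  df <- co[1:40, ]
  df$amyloid_status <- rep(c("positive", "negative"), 20)
  df$age <- rep(1:20, each = 2)  # same values in both groups
  t2 <- compare_groups(df, continuous = "age", categorical = character(0))
  expect_gt(t2$p_value, 0.9)

  # fully shifted groups, n = 20/20
  df$age <- ifelse(df$amyloid_status == "positive", 80, 50) + runif(40)
  t3 <- compare_groups(df, continuous = "age", categorical = character(0))
  expect_lt(t3$p_value, 0.001)

  # 2x2 chi-square closed form: (50,10 / 10,50) -> X2 = 53.3 on 1 df
  x2 <- suppressWarnings(chisq.test(matrix(c(50, 10, 10, 50), 2), correct = FALSE))
  expect_equal(unname(x2$statistic), 160 / 3, tolerance = 1e-9)
  expect_lt(x2$p.value, 1e-10)
})
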