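test_that("predictive-value curves match exhaustive threshold scans", {
  ts <- toy_scores()
  cv <- pv_curves(ts$p, ts$y)
  expect_equal(cv$curve$threshold, seq(0, 1, by = 0.001))

  # ppv at t = 0.401: {0.6+, 0.7-, 0.8+, 0.9+} -> 3/4
  at <- function(t, col) cv$curve[[col]][which.min(abs(cv$curve$threshold - t))]
  expect_equal(at(0.401, "ppv"), 0.75)
  expect_equal(at(0.401, "n_pos_pred"), 4)
  # npv at t = 0.599: {0.1-, 0.2-, 0.3+, 0.4-} -> 3/4
  expect_equal(at(0.599, "npv"), 0.75)

  # t = 0: {p <= 0} is empty (no zero probabilities) -> flagged undefined
  expect_true(is.na(cv$curve$npv[1]))
  expect_equal(cv$curve$n_neg_pred[1], 0)

  # perfect probabilities: PPV/NPV = 1 at every interior threshold (at t = 0
  # the predicted-positive set also contains the true negatives, and
  # symmetrically at t = 1)
  cv2 <- pv_curves(c(0, 0, 1, 1), c(0, 0, 1, 1))
  interior <- cv2$curve$threshold > 0 & cv2$curve$threshold < 1
  expect_true(all(cv2$curve$ppv[interior] == 1))
  expect_true(all(cv2$curve$npv[interior] == 1))
})

test_that("dual cutoffs solve the toy configurations exactly", {
  ts <- toy_scores()
  cv <- pv_curves(ts$p, ts$y)

  pair1 <- find_dual_cutoffs(cv, 1.0)
  expect_equal(pair1$p_neg, 0.299)
  expect_equal(pair1$p_pos, 0.701)
  expect_false(pair1$crossed)
  expect_equal(pair1$grey_fraction, 0.5)

  pair2 <- find_dual_cutoffs(cv, 0.75)
  expect_true(pair2$crossed)
  expect_equal(pair2$p_neg, 0.599)
  expect_equal(pair2$p_pos, 0.401)
  expect_equal(pair2$grey_fraction, 0)

  pair0 <- find_dual_cutoffs(cv, 0)
  expect_true(pair0$crossed)
  expect_equal(pair0$p_neg, 1)
  expect_equal(pair0$p_pos, 0)

  # unreachable side names itself
  cvu <- pv_curves(c(0.2, 0.4, 0.6, 0.8), c(1, 0, 1, 0))
  err <- tryCatch(find_dual_cutoffs(cvu, 0.999), error = function(e) e)
  expect_s3_class(err, "amyloidrisk_unreachable_target")
})

test_that("grey-zone classification respects inclusive boundaries", {
  pair <- list(p_neg = 0.30, p_pos = 0.67, crossed = FALSE)
  expect_equal(classify_with_greyzone(c(0.30, 0.50, 0.67, 0.299, 0.671), pair),
               c("negative", "indeterminate", "positive", "negative", "positive"))
  expect_error(classify_with_greyzone(0.5, list(crossed = TRUE)), "crossed")
})

test_that("post-exclusion metrics drop indeterminate subjects from denominators", {
  ts <- toy_scores()
  pe <- post_exclusion_metrics(ts$p, ts$y, list(p_neg = 0.299, p_pos = 0.701,
                                                crossed = FALSE))
  expect_equal(pe$sensitivity, 1)
  expect_equal(pe$specificity, 1)
  expect_equal(pe$n_classified, 4)
  expect_equal(pe$n_excluded, 4)

  expect_error(post_exclusion_metrics(ts$p, ts$y,
                                      list(p_neg = 0.05, p_pos = 0.95,
                                           crossed = FALSE)),
               "grey zone")

  # one class entirely indeterminate -> its rate undefined, flagged
  pe2 <- post_exclusion_metrics(c(0.1, 0.5, 0.9), c(0, 1, 0),
                                list(p_neg = 0.2, p_pos = 0.8, crossed = FALSE))
  expect_true(is.na(pe2$sensitivity))
  expect_equal(pe2$undefined, "sensitivity")
  expect_equal(pe2$specificity, 0.5)  # one of the two negatives is called positive
})

test_that("grid search agrees with an independent brute-force scan", {
  set.seed(23)
  for (i in 1:40) {
    n <- sample(20:100, 1)
    y <- c(0, 1, rbinom(n - 2, 1, runif(1, 0.3, 0.7)))
    p <- round(plogis(rnorm(n, 2 * y - 1, 1.2)), 3)  # on-grid probabilities
    target <- sample(c(0.7, 0.8, 0.875), 1)
    cv <- pv_curves(p, y)
    got <- tryCatch(find_dual_cutoffs(cv, target), error = function(e) NULL)
    want <- brute_dual_cutoffs(p, y, target)
    if (is.null(want)) {
      expect_null(got)
    } else {
      # same attained sets: grid cutoffs classify every point identically
      expect_equal(p >= got$p_pos, p >= want$p_pos)
      expect_equal(p <= got$p_neg, p <= want$p_neg)
    }
  }
})

test_that("uncrossed cutoffs guarantee the target empirically; grey zone grows with target", {
  spec <- default_synthetic_spec()
  for (s in 1:10) {
    co <- generate_cohort(spec, seed = 100 + s)
    fit <- fit_amyloid_model(co)
    p <- fit$fitted; y <- status_binary(co)
    cv <- pv_curves(p, y)
    greys <- c()
    for (target in c(0.8, 0.875, 0.925)) {
      pair <- tryCatch(find_dual_cutoffs(cv, target), error = function(e) NULL)
      if (is.null(pair) || pair$crossed) next
      pos_set <- p >= pair$p_pos
      neg_set <- p <= pair$p_neg
      expect_gte(sum(y[pos_set] == 1) / sum(pos_set), target)
      expect_gte(sum(y[neg_set] == 0) / sum(neg_set), target)
      greys <- c(greys, pair$grey_fraction)
    }
    expect_true(all(diff(greys) >= 0))  # widening the target never shrinks the grey zone
  }
})
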