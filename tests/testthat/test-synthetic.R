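test_that("log-normal quartile fit matches the closed form and round-trips", {
  p <- fit_lognormal_from_quartiles(0.195, 0.180, 0.212)
  expect_equal(p$mu, log(0.195))
  expect_equal(p$sigma, 0.121, tolerance = 0.005)

  z <- qnorm(0.75)
  p2 <- fit_lognormal_from_quartiles(1, exp(-z), exp(z))
  expect_equal(p2$mu, 0)
  expect_equal(p2$sigma, 1, tolerance = 1e-12)

  # implied quartiles reproduce the inputs when data are log-normal-compatible
  q <- qlnorm(c(0.25, 0.75), p$mu, p$sigma)
  expect_lt(abs(q[1] / 0.180 - 1), 0.10)
  expect_lt(abs(q[2] / 0.212 - 1), 0.10)

  expect_error(fit_lognormal_from_quartiles(10, 10, 11), "q25 < median")
  expect_error(fit_lognormal_from_quartiles(1, -1, 2), "q25 < median")
})

test_that("generated cohorts have exact stratified counts and prevalence", {
  co <- default_cohort_cached()
  expect_equal(nrow(co), 450L)
  expect_equal(sum(co$cohort == "A"), 190L)
  expect_equal(sum(co$cohort == "B"), 260L)
  # floor(prevalence * n) positives per cohort
  expect_equal(sum(co$cohort == "A" & co$amyloid_status == "positive"), 96L)
  expect_equal(sum(co$cohort == "B" & co$amyloid_status == "positive"), 182L)
  expect_equal(mean(co$amyloid_status == "positive"), 278 / 450)

  spec10 <- default_synthetic_spec(n_a = 10, n_b = 10,
                                   prevalence_a = 0.6, prevalence_b = 0.6,
                                   fraction_missing_csf_ratio = 0)
  co10 <- generate_cohort(spec10, seed = 2)
  expect_equal(sum(co10$cohort == "A" & co10$amyloid_status == "positive"), 6L)
})

test_that("generation is deterministic under a seed, distinct across seeds", {
  spec <- default_synthetic_spec()
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(generate_cohort(spec, seed = 42), f1)
  write_cohort(generate_cohort(spec, seed = 42), f2)
  expect_identical(readLines(f1), readLines(f2))
  co_b <- generate_cohort(spec, seed = 43)
  expect_false(identical(generate_cohort(spec, seed = 42)$plasma_ratio,
                         co_b$plasma_ratio))
})

test_that("group-wise sample medians track the specification targets", {
  co <- default_cohort_cached()
  spec <- default_synthetic_spec()
  for (cc in c("A", "B")) {
    for (st in c("positive", "negative")) {
      d <- co[co$cohort == cc & co$amyloid_status == st, ]
      tgt <- spec$groups[[cc]][[st]]$plasma_ratio[1]
      expect_lt(abs(median(d$plasma_ratio) / tgt - 1), 0.15,
                label = sprintf("plasma ratio median, cohort %s %s", cc, st))
    }
  }
  # pooled positives vs pooled target, tighter band at n = 450
  med_pos <- median(co$plasma_ratio[co$amyloid_status == "positive"])
  med_neg <- median(co$plasma_ratio[co$amyloid_status == "negative"])
  expect_lt(med_pos, med_neg)  # amyloid-positive plasma ratio is lower
})

test_that("re-deriving status from CSF reproduces the generating labels", {
  spec <- default_synthetic_spec()
  co <- generate_cohort(spec, seed = 7)
  rederived <- assign_amyloid_status(co, rule = spec$rules)
  evaluable <- rederived$amyloid_status != "unknown"
  expect_true(all(evaluable))  # fallback path covers blanked-ratio records
  expect_equal(rederived$amyloid_status, co$amyloid_status)
  expect_equal(sum(is.na(co$csf_ab40)), 30L)
})

test_that("plasma-CSF rank correlation is near the cohort-level target", {
  co <- default_cohort_cached()
  spec <- default_synthetic_spec()
  for (cc in c("A", "B")) {
    d <- co[co$cohort == cc, ]
    cr <- d$csf_ab42 / d$csf_ab40
    ok <- !is.na(cr)
    rho <- cor(d$plasma_ratio[ok], cr[ok], method = "spearman")
    expect_lt(abs(rho - spec$rho_target[[cc]]), 0.1,
              label = sprintf("Spearman rho, cohort %s", cc))
  }
})

test_that("infeasible status-conditional distributions fail fast", {
  spec <- default_synthetic_spec(n_a = 20, n_b = 20)
  # positive-group CSF ratio far above the positivity cutoff: impossible side
  spec$groups$A$positive$csf_ratio <- c(0.30, 0.28, 0.32)
  expect_error(generate_cohort(spec, seed = 1), "could not generate")
})

test_that("true-model generator recovers null prevalence and effect signs", {
  co0 <- generate_from_true_model(c(0, 0, 0, 0), n = 10000, seed = 3)
  expect_lt(abs(mean(co0$amyloid_status == "positive") - 0.5), 0.02)

  co_neg <- generate_from_true_model(c(12, -60, 0, 0), n = 4000, seed = 4)
  y <- as.integer(co_neg$amyloid_status == "positive")
  expect_lt(cor(co_neg$plasma_ratio, y), 0)  # large negative ratio coefficient

  a <- generate_from_true_model(c(0.5, -30, 0.05, 1), n = 500, seed = 9)
  b <- generate_from_true_model(c(0.5, -30, 0.05, 1), n = 500, seed = 9)
  expect_identical(a$amyloid_status, b$amyloid_status)
  expect_equal(attr(a, "true_beta"), c(0.5, -30, 0.05, 1))
})

test_that("synthetic spec JSON round-trip reproduces identical draws", {
  spec <- default_synthetic_spec()
  path <- withr::local_tempfile(fileext = ".json")
  write_synthetic_spec(spec, path)
  spec2 <- read_synthetic_spec(path)
  expect_identical(generate_cohort(spec, seed = 11)$plasma_ratio,
                   generate_cohort(spec2, seed = 11)$plasma_ratio)

  shipped <- system.file("extdata", "default_synthetic_spec.json",
                         package = "amyloidrisk")
  expect_true(nzchar(shipped))
  spec3 <- read_synthetic_spec(shipped)
  expect_identical(generate_cohort(spec, seed = 11)$plasma_ratio,
                   generate_cohort(spec3, seed = 11)$plasma_ratio)
})
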