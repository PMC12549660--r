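# in-memory toy cohort: 3 well-formed participants
toy_cohort_df <- function() {
  data.frame(
    id = c("p1", "p2", "p3"),
    cohort = c("A", "A", "B"),
    age = c(71, 66, 74),
    sex = c("F", "M", "F"),
    mmse = c(27, 29, 25),
    apoe_e4_count = c(1, 0, 2),
    plasma_ab40 = c(230, 215, 226),
    plasma_ab42 = c(43, 47, 44),
    csf_ab40 = c(13000, 12400, 10700),
    csf_ab42 = c(640, 1280, 440),
    csf_ptau181 = c(96, 39, 94),
    storage_years = c(0.8, 0.6, 1.5),
    stringsAsFactors = FALSE
  )
}

write_toy_csv <- function(df = toy_cohort_df()) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# small labelled score set used across threshold tests
toy_scores <- function() {
  list(p = c(0.1, 0.2, 0.3, 0.4, 0.6, 0.7, 0.8, 0.9),
       y = c(0L, 0L, 1L, 0L, 1L, 0L, 1L, 1L))
}

# independent oracle: exhaustive Youden scan over a dense threshold set
brute_youden_j <- function(scores, labels) {
  cand <- sort(unique(c(scores - 1e-9, scores + 1e-9, scores,
                        min(scores) - 1, max(scores) + 1)))
  j <- vapply(cand, function(t) {
    pred <- scores >= t
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    sens + spec - 1
  }, numeric(1))
  max(j)
}

# independent oracle: dual cutoffs by direct scan over observed p +/- eps
brute_dual_cutoffs <- function(p, y, target, eps = 1e-9) {
  cand <- sort(unique(c(0, 1, p - eps, p, p + eps)))
  cand <- cand[cand >= 0 & cand <= 1]
  ppv_at <- function(t) {
    s <- p >= t
    if (!any(s)) NA_real_ else sum(y[s] == 1) / sum(s)
  }
  npv_at <- function(t) {
    s <- p <= t
    if (!any(s)) NA_real_ else sum(y[s] == 0) / sum(s)
  }
  ppv <- vapply(cand, ppv_at, numeric(1))
  npv <- vapply(cand, npv_at, numeric(1))
  ok_p <- which(!is.na(ppv) & ppv >= target)
  ok_n <- which(!is.na(npv) & npv >= target)
  if (!length(ok_p) || !length(ok_n)) return(NULL)
  list(p_pos = cand[min(ok_p)], p_neg = cand[max(ok_n)])
}

# cached default synthetic cohort, statuses resolved per-cohort rule
default_cohort_cached <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      spec <- default_synthetic_spec()
      co <- generate_cohort(spec, seed = 1)
      memo <<- assign_amyloid_status(co, rule = spec$rules)
    }
    memo
  }
})
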