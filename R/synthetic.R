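#' Log-normal parameters from a median and quartiles
#'
#' Positive, right-skewed biomarker concentrations are summarised in clinical
#' tables as median \[q25–q75\]. This fits the log-normal distribution whose
#' median equals the reported median and whose spread matches the geometric
#' mean of the two observed quartile ratios: `mu = log(median)` and
#' `sigma = mean(log(median/q25), log(q75/median)) / qnorm(0.75)`.
#'
#' @param median,q25,q75 Reported median and quartiles; must satisfy
#'   `0 < q25 < median < q75`.
#' @return A list `(mu, sigma)` of log-scale parameters.
#' @examples
#' fit_lognormal_from_quartiles(0.195, 0.180, 0.212)
#' @export
fit_lognormal_from_quartiles <- function(median, q25, q75) {
  stopifnot(is.numeric(median), is.numeric(q25), is.numeric(q75))
  if (!(q25 > 0 && q25 < median && median < q75))
    stop("quartiles must satisfy 0 < q25 < median < q75 (got ",
         q25, ", ", median, ", ", q75, ")")
  z75 <- stats::qnorm(0.75)
  sigma <- mean(c(log(median / q25), log(q75 / median))) / z75
  list(mu = log(median), sigma = sigma)
}

#' Describe one status group of a synthetic cohort
#'
#' Summary statistics (median and quartiles of each continuous variable,
#' APOE epsilon-4 allele-count probabilities, fraction female) from which
#' a status-conditional stratum of participants is simulated.
#'
#' @param age,mmse,storage_years,plasma_ab40,plasma_ratio,csf_ab40,csf_ratio,csf_ptau181
#'   Length-3 numeric vectors `c(median, q25, q75)`.
#' @param apoe_e4_probs Probabilities of carrying 0, 1, 2 epsilon-4 alleles;
#'   must sum to 1 (renormalised if within 0.01, else error).
#' @param female_frac Proportion of female participants.
#' @return An object of class `group_distribution`.
#' @export
group_distribution <- function(age, mmse, storage_years, plasma_ab40, plasma_ratio,
                               csf_ab40, csf_ratio, csf_ptau181,
                               apoe_e4_probs, female_frac) {
  chk <- function(v, nm) {
    stopifnot(length(v) == 3L)
    if (!(v[2] < v[1] && v[1] < v[3]))
      stop(nm, ": need q25 < median < q75")
    v
  }
  vars <- list(age = chk(age, "age"), mmse = chk(mmse, "mmse"),
               storage_years = chk(storage_years, "storage_years"),
               plasma_ab40 = chk(plasma_ab40, "plasma_ab40"),
               plasma_ratio = chk(plasma_ratio, "plasma_ratio"),
               csf_ab40 = chk(csf_ab40, "csf_ab40"),
               csf_ratio = chk(csf_ratio, "csf_ratio"),
               csf_ptau181 = chk(csf_ptau181, "csf_ptau181"))
  stopifnot(length(apoe_e4_probs) == 3L, all(apoe_e4_probs >= 0))
  if (abs(sum(apoe_e4_probs) - 1) > 0.01) stop("apoe_e4_probs must sum to 1")
  apoe_e4_probs <- apoe_e4_probs / sum(apoe_e4_probs)
  stopifnot(female_frac >= 0, female_frac <= 1)
  structure(c(vars, list(apoe_e4_probs = apoe_e4_probs, female_frac = female_frac)),
            class = "group_distribution")
}

#' Default two-cohort synthetic population specification
#'
#' Encodes the published group-level summary statistics of two real-world
#' memory-clinic MCI cohorts: cohort A (training role, n = 190, CSF-amyloid
#' prevalence 51%) and cohort B (validation role, n = 260, prevalence 70%),
#' each split by CSF amyloid status. Continuous biomarkers are modelled
#' log-normal from the reported median/IQR; age and MMSE truncated normal.
#' The plasma and CSF Abeta42/Abeta40 ratios are coupled through a Gaussian
#' copula whose within-status rank correlation is calibrated so the
#' cohort-level Spearman correlation between the two ratios reproduces the
#' observed values (about 0.52 in cohort A, 0.47 in cohort B).
#'
#' @param n_a,n_b Cohort sizes.
#' @param prevalence_a,prevalence_b CSF-amyloid positivity prevalences.
#' @param rho_target_a,rho_target_b Cohort-level plasma–CSF Spearman targets.
#' @param rho_within_a,rho_within_b Within-status copula rank correlations
#'   (calibrated defaults; see the methods vignette).
#' @param fraction_missing_csf_ratio Fraction of records whose CSF Abeta40 is
#'   blanked so amyloid status must come from the p-tau181/Abeta42 fallback
#'   (default 30/450).
#' @param rng_seed Integer seed recorded in the spec.
#' @return An object of class `synthetic_spec`.
#' @export
default_synthetic_spec <- function(n_a = 190L, n_b = 260L,
                                   prevalence_a = 0.51, prevalence_b = 0.70,
                                   rho_target_a = 0.52, rho_target_b = 0.47,
                                   rho_within_a = 0.035, rho_within_b = 0.19,
                                   fraction_missing_csf_ratio = 30 / 450,
                                   rng_seed = 20260101L) {
  g <- group_distribution
  groups <- list(
    A = list(
      positive = g(age = c(72.5, 68.3, 76.0), mmse = c(27, 25, 29),
                   storage_years = c(0.8, 0.33, 1.3),
                   plasma_ab40 = c(233.9, 206.4, 264.2),
                   plasma_ratio = c(0.185, 0.174, 0.204),
                   csf_ab40 = c(13384, 10552.3, 16648.8),
                   csf_ratio = c(0.049, 0.042, 0.058),
                   csf_ptau181 = c(96.2, 73.4, 143.2),
                   apoe_e4_probs = c(0.448, 0.438, 0.115), female_frac = 0.594),
      negative = g(age = c(66.5, 61.0, 72.0), mmse = c(28, 26, 30),
                   storage_years = c(0.6, 0.4, 1.3),
                   plasma_ab40 = c(216.7, 201.2, 252.2),
                   plasma_ratio = c(0.216, 0.198, 0.227),
                   csf_ab40 = c(12405, 9258.5, 15813.3),
                   csf_ratio = c(0.109, 0.099, 0.114),
                   csf_ptau181 = c(38.8, 29.5, 50.3),
                   apoe_e4_probs = c(0.809, 0.191, 0.000), female_frac = 0.521)),
    B = list(
      positive = g(age = c(74.0, 71.0, 77.0), mmse = c(26, 24, 27.8),
                   storage_years = c(1.5, 0.9, 2.2),
                   plasma_ab40 = c(226.3, 199.9, 255.9),
                   plasma_ratio = c(0.195, 0.180, 0.212),
                   csf_ab40 = c(10726, 8147, 13469),
                   csf_ratio = c(0.043, 0.035, 0.049),
                   csf_ptau181 = c(94.0, 69.1, 127.5),
                   apoe_e4_probs = c(0.429, 0.500, 0.071), female_frac = 0.637),
      negative = g(age = c(70.0, 65.0, 74.3), mmse = c(27, 24.3, 28.0),
                   storage_years = c(1.5, 0.8, 2.3),
                   plasma_ab40 = c(226.0, 206.1, 265.1),
                   plasma_ratio = c(0.221, 0.209, 0.240),
                   csf_ab40 = c(10799, 8047.3, 12982),
                   csf_ratio = c(0.089, 0.081, 0.102),
                   csf_ptau181 = c(39.5, 29.7, 48.3),
                   apoe_e4_probs = c(0.859, 0.115, 0.026), female_frac = 0.551))
  )
  spec <- list(
    cohorts = c("A", "B"),
    sizes = c(A = as.integer(n_a), B = as.integer(n_b)),
    prevalence = c(A = prevalence_a, B = prevalence_b),
    rho_target = c(A = rho_target_a, B = rho_target_b),
    rho_within = c(A = rho_within_a, B = rho_within_b),
    fraction_missing_csf_ratio = fraction_missing_csf_ratio,
    rng_seed = as.integer(rng_seed),
    groups = groups,
    rules = list(A = default_positivity_rule("A"), B = default_positivity_rule("B"))
  )
  stopifnot(all(spec$prevalence > 0 & spec$prevalence < 1), all(spec$sizes >= 2),
            fraction_missing_csf_ratio >= 0, fraction_missing_csf_ratio < 1)
  structure(spec, class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Synthetic two-cohort specification\n")
  for (co in x$cohorts)
    cat(sprintf("  cohort %s: n = %d, prevalence = %.2f, plasma-CSF rho target = %.2f\n",
                co, x$sizes[[co]], x$prevalence[[co]], x$rho_target[[co]]))
  cat(sprintf("  missing CSF ratio fraction = %.3f, seed = %d\n",
              x$fraction_missing_csf_ratio, x$rng_seed))
  invisible(x)
}

#' Serialise / read a synthetic specification as JSON
#'
#' @param spec A `synthetic_spec`.
#' @param path JSON file path.
#' @return `write_synthetic_spec()` returns `path`; `read_synthetic_spec()`
#'   returns a `synthetic_spec`.
#' @export
write_synthetic_spec <- function(spec, path) {
  x <- unclass(spec)
  for (f in c("sizes", "prevalence", "rho_target", "rho_within"))
    x[[f]] <- as.list(x[[f]])   # keep cohort names in JSON objects
  x$groups <- lapply(x$groups, function(co) lapply(co, unclass))
  x$rules <- lapply(x$rules, unclass)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_synthetic_spec
#' @export
read_synthetic_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$groups <- lapply(x$groups, function(co)
    lapply(co, function(g) do.call(group_distribution, g)))
  x$rules <- lapply(x$rules, function(r) do.call(positivity_rule, r))
  x$sizes <- unlist(x$sizes); x$prevalence <- unlist(x$prevalence)
  x$rho_target <- unlist(x$rho_target); x$rho_within <- unlist(x$rho_within)
  structure(x, class = "synthetic_spec")
}

# truncated-normal draws by redraw; mean/sd chosen to match median and IQR
rtrunc_norm <- function(n, median, q25, q75, lower, upper) {
  sd <- (q75 - q25) / (2 * stats::qnorm(0.75))
  x <- stats::rnorm(n, median, sd)
  for (i in seq_len(100)) {
    bad <- x < lower | x > upper
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), median, sd)
  }
  pmin(pmax(x, lower), upper)
}

rlnorm_q <- function(n, q) {
  p <- fit_lognormal_from_quartiles(q[1], q[2], q[3])
  stats::rlnorm(n, p$mu, p$sigma)
}

# one status stratum of one cohort; rejection keeps CSF measures on the
# generating-status side of both positivity rules
.generate_group <- function(n, g, status, rule, rho_within, maxit = 200L) {
  pos <- identical(status, "positive")
  pr <- fit_lognormal_from_quartiles(g$plasma_ratio[1], g$plasma_ratio[2], g$plasma_ratio[3])
  cr <- fit_lognormal_from_quartiles(g$csf_ratio[1], g$csf_ratio[2], g$csf_ratio[3])
  r_norm <- 2 * sin(pi * rho_within / 6)  # Spearman -> Gaussian-copula correlation

  draw_pair <- function(m) {
    z1 <- stats::rnorm(m)
    z2 <- r_norm * z1 + sqrt(1 - r_norm^2) * stats::rnorm(m)
    cbind(plasma = exp(pr$mu + pr$sigma * z1), csf = exp(cr$mu + cr$sigma * z2))
  }
  xy <- draw_pair(n)
  ok_side <- function(v) if (pos) v <= rule$ratio_cutoff else v > rule$ratio_cutoff
  for (i in seq_len(maxit)) {
    bad <- !ok_side(xy[, "csf"])
    if (!any(bad)) break
    xy[bad, ] <- draw_pair(sum(bad))
  }
  if (any(!ok_side(xy[, "csf"])))
    stop("could not generate CSF Abeta42/Abeta40 on the ", status,
         " side of cutoff ", rule$ratio_cutoff, " after ", maxit, " rounds")

  csf_ab40 <- rlnorm_q(n, g$csf_ab40)
  csf_ab42 <- xy[, "csf"] * csf_ab40

  # p-tau181 consistent with the fallback rule for the same status
  pt <- fit_lognormal_from_quartiles(g$csf_ptau181[1], g$csf_ptau181[2], g$csf_ptau181[3])
  ptau <- stats::rlnorm(n, pt$mu, pt$sigma)
  ok_fb <- function(v) if (pos) v / csf_ab42 >= rule$fallback_cutoff
                       else v / csf_ab42 < rule$fallback_cutoff
  for (i in seq_len(maxit)) {
    bad <- !ok_fb(ptau)
    if (!any(bad)) break
    ptau[bad] <- stats::rlnorm(sum(bad), pt$mu, pt$sigma)
  }
  if (any(!ok_fb(ptau)))
    stop("could not generate p-tau181/Abeta42 on the ", status,
         " side of fallback cutoff after ", maxit, " rounds")

  plasma_ab40 <- rlnorm_q(n, g$plasma_ab40)
  data.frame(
    age = rtrunc_norm(n, g$age[1], g$age[2], g$age[3], 40, 95),
    sex = ifelse(stats::runif(n) < g$female_frac, "F", "M"),
    mmse = round(rtrunc_norm(n, g$mmse[1], g$mmse[2], g$mmse[3], 0, 30)),
    apoe_e4_count = sample(0:2, n, replace = TRUE, prob = g$apoe_e4_probs),
    plasma_ab40 = plasma_ab40,
    plasma_ab42 = xy[, "plasma"] * plasma_ab40,
    csf_ab40 = csf_ab40,
    csf_ab42 = csf_ab42,
    csf_ptau181 = ptau,
    storage_years = rlnorm_q(n, g$storage_years),
    amyloid_status = status,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic two-cohort population
#'
#' Draws participant records cohort by cohort and status stratum by status
#' stratum. Each cohort contains exactly `floor(prevalence * n)` amyloid-
#' positive subjects (stratified construction, so prevalence-sensitive
#' metrics are stable). CSF measures are rejection-sampled onto the
#' generating-status side of both positivity rules, so re-deriving status
#' with [assign_amyloid_status()] reproduces the generating labels exactly.
#' A fixed fraction of records per cohort has CSF Abeta40 blanked so that
#' status determination must use the p-tau181/Abeta42 fallback.
#'
#' @param spec A `synthetic_spec` (see [default_synthetic_spec()]).
#' @param seed Integer seed; defaults to the seed recorded in the spec.
#' @return An `amyloid_cohort` data frame of `sum(spec$sizes)` records.
#' @export
generate_cohort <- function(spec = default_synthetic_spec(), seed = spec$rng_seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(as.integer(seed))
  out <- list()
  for (co in spec$cohorts) {
    n <- spec$sizes[[co]]
    n_pos <- as.integer(floor(spec$prevalence[[co]] * n))
    n_neg <- n - n_pos
    rule <- spec$rules[[co]]
    dpos <- .generate_group(n_pos, spec$groups[[co]]$positive, "positive", rule,
                            spec$rho_within[[co]])
    dneg <- .generate_group(n_neg, spec$groups[[co]]$negative, "negative", rule,
                            spec$rho_within[[co]])
    d <- rbind(dpos, dneg)
    d <- d[sample.int(nrow(d)), , drop = FALSE]   # shuffle within cohort
    d$id <- sprintf("%s-%03d", co, seq_len(nrow(d)))
    d$cohort <- co
    n_miss <- round(spec$fraction_missing_csf_ratio * n)
    if (n_miss > 0) d$csf_ab40[sample.int(n, n_miss)] <- NA_real_
    out[[co]] <- d
  }
  as_cohort(do.call(rbind, out), source = "synthetic")
}

#' Generate a cohort whose outcome follows a known logistic model
#'
#' Parameter-recovery harness: covariates (plasma ratio, age, APOE carriage)
#' are drawn from the prevalence-weighted marginal distribution of one
#' cohort of the default specification, and amyloid status is then drawn
#' `Bernoulli(plogis(X beta))` under the supplied coefficients, so model
#' fitting can be checked against a known truth.
#'
#' @param beta Length-4 coefficient vector: intercept, plasma ratio, age
#'   (years), APOE epsilon-4 carrier indicator.
#' @param n Number of records.
#' @param seed Integer seed.
#' @param spec Synthetic specification supplying covariate marginals.
#' @param cohort Which cohort's marginals to use (default `"A"`).
#' @return An `amyloid_cohort`; attribute `"true_beta"` stores `beta`.
#' @export
generate_from_true_model <- function(beta, n, seed = 1L,
                                     spec = default_synthetic_spec(),
                                     cohort = "A") {
  stopifnot(length(beta) == 4L, is.numeric(beta))
  set.seed(as.integer(seed))
  prev <- spec$prevalence[[cohort]]
  grp <- spec$groups[[cohort]]
  from_pos <- stats::runif(n) < prev
  draw <- function(g, m) {
    if (m == 0L) return(NULL)
    data.frame(
      age = rtrunc_norm(m, g$age[1], g$age[2], g$age[3], 40, 95),
      plasma_ratio = rlnorm_q(m, g$plasma_ratio),
      apoe_e4_count = sample(0:2, m, replace = TRUE, prob = g$apoe_e4_probs),
      plasma_ab40 = rlnorm_q(m, g$plasma_ab40)
    )
  }
  d <- rbind(draw(grp$positive, sum(from_pos)), draw(grp$negative, sum(!from_pos)))
  d <- d[sample.int(n), , drop = FALSE]
  eta <- beta[1] + beta[2] * d$plasma_ratio + beta[3] * d$age +
    beta[4] * as.numeric(d$apoe_e4_count >= 1)
  y <- stats::rbinom(n, 1L, stats::plogis(eta))
  d$id <- sprintf("T-%05d", seq_len(n))
  d$cohort <- cohort
  d$plasma_ab42 <- d$plasma_ratio * d$plasma_ab40
  d$amyloid_status <- ifelse(y == 1L, "positive", "negative")
  out <- as_cohort(d, source = "true-model simulation")
  attr(out, "true_beta") <- beta
  out
}
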