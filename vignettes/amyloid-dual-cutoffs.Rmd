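---
title: "Dual-cutoff evaluation of a plasma amyloid risk model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-cutoff evaluation of a plasma amyloid risk model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Confirming brain amyloid pathology in mild cognitive impairment (MCI)
currently requires amyloid PET or a lumbar puncture for CSF biomarkers —
costly, invasive procedures that are poorly suited to the screening volumes
that anti-amyloid therapies now demand. Blood-based biomarkers offer a
triage route: the plasma Abeta42/Abeta40 ratio falls when brain amyloid
accumulates, and combining it with age and APOE epsilon-4 carriage in a
logistic model yields a usable pre-screen.

`amyloidrisk` implements that model together with the full evaluation
pipeline a clinical-validation study needs: external validation with frozen
coefficients, ROC/Youden analysis, dual-cutoff ("grey zone") decision rules
at fixed predictive values, prevalence-fixed bootstrap resampling,
measurement-noise Monte Carlo, flexible calibration, and plasma–CSF
agreement statistics.

## The model

For subject $i$ with plasma ratio $r_i$, age $a_i$ (years) and APOE
epsilon-4 carrier indicator $e_i \in \{0,1\}$,

$$\Pr(\text{CSF amyloid positive}) =
  \operatorname{logit}^{-1}(\beta_0 + \beta_1 r_i + \beta_2 a_i + \beta_3 e_i).$$

Fitting is maximum likelihood via IRLS (`stats::glm`). APOE enters
dichotomised — carriage of at least one epsilon-4 allele — because allele
count adds little once carriage is known and the dichotomous term keeps the
model identifiable in cohorts with no epsilon-4 homozygotes. Age enters in
years, untransformed; coefficients stay interpretable on natural units, and
no standardisation is applied by default. A ratio-only reference fit is
always produced so the AIC improvement from the covariates can be read off
(`$aic_ratio_only`).

Reference status ("truth") is CSF-based: amyloid positive iff CSF
Abeta42/Abeta40 $\le$ 0.068 (cohort A convention) or $\le$ 0.069 (cohort
B), boundary inclusive; when that ratio is unavailable the fallback rule
CSF p-tau181/Abeta42 $\ge$ 0.0815 applies. The fallback threshold is itself
the Youden-optimal cutoff on subjects with both measurements
(`derive_fallback_cutoff()`). When both rules can be evaluated the ratio
rule always wins; disagreements are flagged, not resolved silently, because
no principled reconciliation exists at the record level.

## Decision rules and conventions

All classification in the package uses one convention: **predicted positive
iff score $\ge$ threshold**.

* **Youden threshold.** Candidates are midpoints between adjacent distinct
  scores (plus sentinels beyond the range), not the observed values
  themselves; this avoids boundary effects that depend on the $\ge$/$>$
  convention. Ties in $J$ break toward the larger threshold (higher
  specificity).
* **Dual cutoffs.** On a 0.001-step grid, the positivity cutoff is the
  smallest threshold whose empirical PPV of $\{p \ge t\}$ reaches the
  target, the negativity cutoff the largest threshold whose NPV of
  $\{p \le t\}$ reaches it. Because the NPV side uses $\le$, the reported
  cutoff is directly usable in the classification rule — search and rule
  share one convention. Boundaries are classified, the grey zone is the
  open interval between the cutoffs. A target reachable on neither side is
  an error naming the failed side; cutoffs that cross are reported
  unmodified with `crossed = TRUE` rather than "fixed".
* **Post-exclusion metrics** are computed only over classified subjects;
  a class that vanishes into the grey zone yields a flagged `NA`, never a
  silent `NaN`.

The default predictive-value target is 0.875, with 0.85 supported as the
secondary choice; both are arguments, not constants.

## The synthetic cohort generator

The patient-level data behind this kind of validation study are not
publicly deposited, so the package ships a generator
(`default_synthetic_spec()`, `generate_cohort()`) that emulates the
published group-level structure of two real-world memory-clinic MCI
cohorts: cohort A (n = 190, CSF-amyloid prevalence 51%) and cohort B
(n = 260, prevalence 70%), each described per status group by median/IQR
summaries of age, MMSE, storage time, plasma Abeta40 and Abeta42/Abeta40,
CSF Abeta40, Abeta42/Abeta40 and p-tau181, APOE allele-count frequencies
and sex ratios.

Design choices, made once and recorded here:

* **Distributional family.** Only medians and IQRs are published.
  Concentrations and ratios are positive and right-skewed, so each is
  modelled log-normal with $\mu = \log(\text{median})$ and $\sigma$ from
  the geometric mean of the two quartile ratios
  (`fit_lognormal_from_quartiles()`); age and MMSE are truncated normal
  (bounds 40–95 years and 0–30 points).
* **Exact stratification.** Each cohort contains exactly
  $\lfloor \text{prevalence} \cdot n \rfloor$ positives. Bernoulli status
  draws would make prevalence-sensitive metrics noisy in tests for no
  scientific gain.
* **Label consistency by rejection.** CSF values are rejection-sampled onto
  the generating-status side of both positivity rules, so re-deriving
  status from the generated CSF reproduces the labels exactly — the
  generator and the status-assignment code cross-validate each other.
  Acceptance rates are high (the group distributions sit far from the
  cutoffs), so the distortion of the tails is negligible.
* **Plasma–CSF dependence.** The plasma and CSF Abeta42/Abeta40 ratios are
  drawn jointly through a Gaussian copula within each status group. The
  published association is cohort-level (Spearman rho about 0.52 in cohort
  A, 0.47 in cohort B), and between-group separation already induces most
  of it; the within-group copula correlation is therefore a calibration
  parameter, swept once over a coarse grid and frozen at 0.035 (A) and
  0.19 (B), which reproduces the cohort-level targets to within about
  0.01–0.02 on average (Monte Carlo SD across seeds about 0.04–0.06). No
  other cross-variable correlations are fabricated: age, APOE and the
  remaining biomarkers are linked only through status conditioning.
* **Missing-CSF fallback path.** A fraction 30/450 of records has CSF
  Abeta40 blanked, forcing status determination through the
  p-tau181/Abeta42 fallback, as in the real cohorts.

What the generator does *not* emulate: longitudinal change, assay batch
effects, pre-analytical handling, within-status age–biomarker correlations
(not published), or cohort differences beyond the tabulated summaries.
Tests passing on this synthetic population therefore demonstrate that the
*machinery* is correct under realistic group structure — not that the
model's headline numbers transfer to any particular clinic.

## Resampling, noise and calibration

* **Prevalence-fixed bootstrap** (`bootstrap_cutoff_table()`): stratified
  resampling with replacement, the only construction that fixes prevalence
  exactly in every population. The model is *not* refit per population —
  the frozen coefficients are the object under evaluation (refitting is
  available behind a flag). Per-population seeds derive from the master
  seed by a counter scheme, so any subset of the grid reproduces in
  isolation. Populations with crossed or unreachable cutoffs are counted
  separately and excluded from means/SDs; more than 50% degenerate flags
  the summary unreliable.
* **Noise Monte Carlo** (`noise_study()`): "x% noise" is interpreted as
  multiplicative Gaussian noise on the ratio,
  $r' = r(1 + \varepsilon)$, $\varepsilon \sim N(0, \sigma_{rel})$, with
  redraw (not clipping) below zero, since percent noise on a positive
  measurand is naturally relative; an additive-on-components mode
  (independent noise on Abeta40 and Abeta42) is provided as an option. Each
  iteration refits the model on the perturbed data and records the
  in-sample AUC — no holdout, matching how such robustness checks are run.
* **Calibration** (`recalibration_coefficients()`,
  `bootstrap_calibration()`): the standard two-step logistic recalibration —
  slope free in a fit on $\operatorname{logit}(\hat p)$, intercept with the
  slope fixed at 1 via an offset. The flexible curve is local-linear LOESS
  (tricube weights, default span 0.75, recorded in the output) of the 0/1
  outcome on $\hat p$; no extrapolation beyond the observed probability
  range, and smoothed values outside [0, 1] are reported, not clamped.
  Bootstrap cycles average the coefficients and the curve point-wise
  (averaging curves, not averaging data); probabilities are clipped to
  $[10^{-10}, 1-10^{-10}]$ for logit stability with the clipped count
  reported.
* **Agreement** (`deming_fit()`, `spearman_assoc()`): Deming regression in
  closed form with error-variance ratio $\lambda$ (default 1, orthogonal
  regression; the value is not identifiable from the data and is always
  logged in the output since the slope depends on it);
  $\lambda \to \infty$ recovers ordinary least squares of $y$ on $x$.

## Numerical and degenerate-input behaviour

Threshold grids are snapped back to their nominal values to avoid
floating-point drift in `seq()`. Constant scores give AUC 0.5 with a
degenerate-CI warning; single-class inputs error. Zero-variance covariates
are dropped with a warning and reported as zero coefficients. Complete
separation is detected and flagged. Storage-time filtering keeps exactly
5.0 years (strict-greater exclusion). Eligibility validation collects
row-level failures and reports them with row numbers; it only aborts when
every row fails.

## Problem sizes used in the tests

The shipped test-suite and acceptance script run the full pipeline at the
study's design sizes (two cohorts of 190 and 260; n = 450 combined) with
replicate counts scaled to 200 bootstrap populations per prevalence, 200
noise iterations per level and 200 calibration cycles — one fifth of the
1,000 used for final reported numbers — which leaves Monte Carlo error on
the summarised means well below the tolerances asserted. Parameter-recovery
checks use n = 5,000 across 20 seeds.

## Known limitations

* The generator reproduces group-level margins and one targeted rank
  correlation; real cohorts have richer dependence.
* Calibration averaging (curves averaged point-wise across cycles) is one
  of several defensible conventions; alternatives would change the curve,
  not the slope/intercept summaries.
* Deming's $\lambda$ is conventionally set, not estimated; slopes are
  comparable only at matching $\lambda$.
* No regularised or Bayesian model variants; no additional biomarkers
  (e.g. p-tau217) in the default model.
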