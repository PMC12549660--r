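#' Positivity rule for CSF amyloid status
#'
#' Bundles the two CSF decision rules used to define amyloid positivity:
#' the primary rule on the CSF Abeta42/Abeta40 ratio (low ratio = positive)
#' and the fallback rule on CSF p-tau181/Abeta42 (high ratio = positive),
#' used only when the Abeta42/Abeta40 ratio cannot be formed.
#'
#' @param ratio_cutoff CSF Abeta42/Abeta40 cutoff; values `<=` this are
#'   positive. Routine clinical cutoffs are 0.068 (cohort A role) and 0.069
#'   (cohort B role); 0.0685 is the pooled mean used for combined displays.
#' @param fallback_cutoff CSF p-tau181/Abeta42 cutoff; values `>=` this are
#'   positive. Default 0.0815 (Youden-derived on subjects with both measures,
#'   see [derive_fallback_cutoff()]).
#' @return An object of class `positivity_rule`.
#' @seealso [assign_amyloid_status()]
#' @export
positivity_rule <- function(ratio_cutoff = 0.068, fallback_cutoff = 0.0815) {
  stopifnot(is.numeric(ratio_cutoff), length(ratio_cutoff) == 1L, ratio_cutoff > 0,
            is.numeric(fallback_cutoff), length(fallback_cutoff) == 1L, fallback_cutoff > 0)
  structure(list(ratio_cutoff = ratio_cutoff, fallback_cutoff = fallback_cutoff),
            class = "positivity_rule")
}

#' Default per-cohort positivity rules
#'
#' Cohort "A" (training role) uses a CSF Abeta42/Abeta40 cutoff of 0.068,
#' cohort "B" (validation role) 0.069; `"pooled"` uses the mean 0.0685 for
#' combined-cohort displays. All share the p-tau181/Abeta42 fallback 0.0815.
#'
#' @param cohort One of `"A"`, `"B"`, `"pooled"`.
#' @return A `positivity_rule`.
#' @export
default_positivity_rule <- function(cohort = c("A", "B", "pooled")) {
  cohort <- match.arg(cohort)
  positivity_rule(ratio_cutoff = switch(cohort, A = 0.068, B = 0.069, pooled = 0.0685))
}

#' @export
print.positivity_rule <- function(x, ...) {
  cat("CSF amyloid positivity rule\n")
  cat(sprintf("  CSF Abeta42/Abeta40 <= %.4g  => positive\n", x$ratio_cutoff))
  cat(sprintf("  fallback: CSF p-tau181/Abeta42 >= %.4g => positive\n", x$fallback_cutoff))
  invisible(x)
}

.required_cols <- c("id", "cohort", "age", "apoe_e4_count", "plasma_ab40", "plasma_ab42")
.optional_cols <- c("sex", "mmse", "csf_ab40", "csf_ab42", "csf_ptau181",
                    "storage_years", "amyloid_status")

#' Normalise an APOE specification to an epsilon-4 allele count
#'
#' Accepts either an integer count in 0..2 or an allele-pair string such as
#' `"e3/e4"`, `"E4/E4"` or `"3/4"`; the count is the number of epsilon-4
#' alleles in the pair.
#'
#' @param x Vector of counts or genotype strings.
#' @return Integer vector of epsilon-4 counts (NA where unparseable).
#' @export
apoe_e4_count <- function(x) {
  if (is.numeric(x)) {
    out <- as.integer(x)
    out[!(out %in% 0:2) | is.na(x) | x != out] <- NA_integer_
    return(out)
  }
  x <- as.character(x)
  suppress <- function(v) suppressWarnings(as.integer(v))
  num <- suppress(x)
  out <- ifelse(!is.na(num) & num %in% 0:2, num, NA_integer_)
  str_idx <- which(is.na(out) & !is.na(x) & grepl("/", x, fixed = TRUE))
  if (length(str_idx)) {
    alleles <- strsplit(tolower(x[str_idx]), "/", fixed = TRUE)
    cnt <- vapply(alleles, function(a) {
      a <- gsub("[^0-9]", "", a)
      if (length(a) != 2L || any(!a %in% c("2", "3", "4"))) return(NA_integer_)
      sum(a == "4")
    }, integer(1))
    out[str_idx] <- cnt
  }
  as.integer(out)
}

#' Load a participant cohort from CSV
#'
#' Reads a participant-level table (comma-separated, header row, "." decimal
#' separator, missing values as empty string or `NA`), validates each row, and
#' returns a normalised cohort data frame with the derived plasma
#' Abeta42/Abeta40 ratio and APOE epsilon-4 carrier flag. Rows that fail
#' validation (non-positive or non-numeric biomarkers, APOE count outside
#' 0..2) are excluded and reported with row numbers in the `"validation"`
#' attribute and via warnings.
#'
#' @param path CSV file path.
#' @param schema Optional named character vector mapping canonical column
#'   names (names) to the file's column names (values), e.g.
#'   `c(plasma_ab42 = "AB42_plasma")`.
#' @return A data frame of class `amyloid_cohort`; attribute `"validation"`
#'   holds a data frame of excluded rows (row, id, reason).
#' @export
load_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), check.names = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(raw))
        stop("schema column not in file: ", schema[[canon]])
      names(raw)[names(raw) == schema[[canon]]] <- canon
    }
  }
  missing_req <- setdiff(.required_cols, names(raw))
  if (length(missing_req))
    stop("missing required column(s): ", paste(missing_req, collapse = ", "))
  as_cohort(raw, source = path)
}

#' Coerce a raw participant table to a validated cohort
#'
#' Workhorse behind [load_cohort()]; also usable on in-memory data frames.
#'
#' @param x Data frame with at least the required columns
#'   (`id, cohort, age, apoe_e4_count, plasma_ab40, plasma_ab42`).
#' @param source Label recorded for provenance messages.
#' @return A validated `amyloid_cohort` data frame.
#' @export
as_cohort <- function(x, source = "data.frame") {
  missing_req <- setdiff(.required_cols, names(x))
  if (length(missing_req))
    stop("missing required column(s): ", paste(missing_req, collapse = ", "))
  n_in <- nrow(x)
  num <- function(v) suppressWarnings(as.numeric(v))

  d <- data.frame(
    id = as.character(x$id),
    cohort = as.character(x$cohort),
    age = num(x$age),
    sex = if ("sex" %in% names(x)) as.character(x$sex) else NA_character_,
    mmse = if ("mmse" %in% names(x)) num(x$mmse) else NA_real_,
    apoe_e4_count = apoe_e4_count(x$apoe_e4_count),
    plasma_ab40 = num(x$plasma_ab40),
    plasma_ab42 = num(x$plasma_ab42),
    csf_ab40 = if ("csf_ab40" %in% names(x)) num(x$csf_ab40) else NA_real_,
    csf_ab42 = if ("csf_ab42" %in% names(x)) num(x$csf_ab42) else NA_real_,
    csf_ptau181 = if ("csf_ptau181" %in% names(x)) num(x$csf_ptau181) else NA_real_,
    storage_years = if ("storage_years" %in% names(x)) num(x$storage_years) else NA_real_,
    amyloid_status = if ("amyloid_status" %in% names(x)) as.character(x$amyloid_status)
                     else "unknown",
    stringsAsFactors = FALSE
  )
  d$amyloid_status[is.na(d$amyloid_status)] <- "unknown"

  reason <- rep(NA_character_, n_in)
  flag <- function(bad, why) reason[bad & is.na(reason)] <<- why
  flag(is.na(d$age) | d$age <= 0, "invalid age")
  flag(is.na(d$apoe_e4_count), "apoe_e4_count not in 0..2")
  flag(is.na(d$plasma_ab40) | d$plasma_ab40 <= 0, "invalid plasma_ab40")
  flag(is.na(d$plasma_ab42) | d$plasma_ab42 <= 0, "invalid plasma_ab42")
  flag(!is.na(d$csf_ab40) & d$csf_ab40 <= 0, "non-positive csf_ab40")
  flag(!is.na(d$csf_ab42) & d$csf_ab42 <= 0, "non-positive csf_ab42")
  flag(!is.na(d$csf_ptau181) & d$csf_ptau181 <= 0, "non-positive csf_ptau181")
  flag(!d$amyloid_status %in% c("positive", "negative", "unknown"),
       "unrecognised amyloid_status")

  bad <- !is.na(reason)
  dropped <- data.frame(row = which(bad), id = d$id[bad], reason = reason[bad],
                        stringsAsFactors = FALSE)
  if (nrow(dropped) == n_in && n_in > 0)
    stop("all ", n_in, " rows failed validation (first reason: ",
         dropped$reason[1], ")")
  if (nrow(dropped) > 0)
    warning(nrow(dropped), " row(s) excluded during validation of ", source,
            " (see attr(, \"validation\"))")

  d <- d[!bad, , drop = FALSE]
  rownames(d) <- NULL
  d$plasma_ratio <- d$plasma_ab42 / d$plasma_ab40
  d$apoe_carrier <- d$apoe_e4_count >= 1L
  structure(d, validation = dropped, class = c("amyloid_cohort", "data.frame"))
}

#' Write a cohort back to CSV
#'
#' @param cohort An `amyloid_cohort` (or compatible data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Exclude samples by plasma storage time
#'
#' Partitions a cohort into records kept for analysis and records excluded
#' for long frozen-storage time. The boundary is inclusive: a sample stored
#' exactly `max_years` is kept (only strictly longer storage is excluded).
#' Records with missing `storage_years` are excluded with reason "missing".
#'
#' @param cohort An `amyloid_cohort`.
#' @param max_years Maximum allowed storage time in years (default 5).
#' @return A list with elements `kept`, `excluded` (both cohorts; `excluded`
#'   carries an `exclusion_reason` column) and `report`, a list
#'   `(n_in, n_kept, n_excluded, reasons)` suitable for JSON export.
#' @export
filter_storage <- function(cohort, max_years = 5) {
  stopifnot(is.numeric(max_years), max_years >= 0)
  st <- cohort$storage_years
  miss <- is.na(st)
  over <- !miss & st > max_years
  keep <- !miss & !over
  excluded <- cohort[!keep, , drop = FALSE]
  excluded$exclusion_reason <- ifelse(is.na(excluded$storage_years), "missing",
                                      sprintf("storage > %g years", max_years))
  reasons <- as.list(table(excluded$exclusion_reason))
  list(kept = cohort[keep, , drop = FALSE],
       excluded = excluded,
       report = list(n_in = nrow(cohort), n_kept = sum(keep),
                     n_excluded = sum(!keep), reasons = reasons))
}

#' Assign CSF amyloid status from CSF biomarkers
#'
#' Applies the positivity rule to every record: when both CSF Abeta42 and
#' Abeta40 are present, status is positive iff their ratio is `<=` the ratio
#' cutoff (boundary inclusive); otherwise, when both CSF p-tau181 and Abeta42
#' are present, the fallback rule declares positive iff p-tau181/Abeta42 is
#' `>=` the fallback cutoff. Records where neither rule can be evaluated get
#' status `"unknown"`. The ratio rule always takes precedence when it can be
#' evaluated; records where the two rules would disagree are flagged in the
#' `"rule_conflicts"` attribute (ids) but still follow the ratio rule.
#'
#' @param cohort An `amyloid_cohort`.
#' @param rule A [positivity_rule()]. A named list of rules keyed by cohort
#'   label applies per-cohort cutoffs in one call.
#' @return The cohort with `amyloid_status` filled in; attribute
#'   `"rule_conflicts"` lists ids where ratio and fallback rules disagree.
#' @export
assign_amyloid_status <- function(cohort, rule = default_positivity_rule("A")) {
  if (inherits(rule, "positivity_rule")) {
    rules <- list(rule)
    rule_for <- rep(1L, nrow(cohort))
  } else {
    stopifnot(is.list(rule), all(vapply(rule, inherits, TRUE, "positivity_rule")))
    rule_for <- match(cohort$cohort, names(rule))
    if (anyNA(rule_for)) stop("no positivity rule for cohort label(s): ",
                              paste(unique(cohort$cohort[is.na(rule_for)]), collapse = ", "))
    rules <- rule
  }
  ratio_cut <- vapply(rules, `[[`, numeric(1), "ratio_cutoff")[rule_for]
  fb_cut <- vapply(rules, `[[`, numeric(1), "fallback_cutoff")[rule_for]

  has_ratio <- !is.na(cohort$csf_ab42) & !is.na(cohort$csf_ab40)
  has_fb <- !is.na(cohort$csf_ptau181) & !is.na(cohort$csf_ab42)

  ratio_pos <- has_ratio & (cohort$csf_ab42 / cohort$csf_ab40 <= ratio_cut)
  fb_pos <- has_fb & (cohort$csf_ptau181 / cohort$csf_ab42 >= fb_cut)

  status <- rep("unknown", nrow(cohort))
  status[has_ratio] <- ifelse(ratio_pos[has_ratio], "positive", "negative")
  only_fb <- !has_ratio & has_fb
  status[only_fb] <- ifelse(fb_pos[only_fb], "positive", "negative")

  conflicts <- cohort$id[has_ratio & has_fb & (ratio_pos != fb_pos)]
  cohort$amyloid_status <- status
  attr(cohort, "rule_conflicts") <- conflicts
  cohort
}

# 0/1 outcome vector from a cohort's amyloid_status; errors on "unknown"
status_binary <- function(cohort) {
  s <- cohort$amyloid_status
  if (any(s == "unknown"))
    stop(sum(s == "unknown"), " record(s) with unknown amyloid status; ",
         "run assign_amyloid_status() first or subset to known statuses")
  as.integer(s == "positive")
}
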