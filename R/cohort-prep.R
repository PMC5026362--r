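# Inclusion/exclusion filtering, patient-ear-frequency (PEF) coding, and
# the regression design view used by all three models.

design_columns <- function() c("(Intercept)", "log_age", "gender_f", "log_diag")

required_record_columns <- function() {
  c("patient_id", "ear", "conduction", "frequency_hz", "age_years",
    "gender", "diag_count", "threshold_db")
}

check_records <- function(records) {
  missing <- setdiff(required_record_columns(), names(records))
  if (length(missing))
    stop("record table is missing columns: ", paste(missing, collapse = ", "))
  num_cols <- c("frequency_hz", "age_years", "diag_count", "threshold_db")
  for (cn in num_cols) {
    bad <- which(!is.finite(records[[cn]]))
    if (length(bad))
      stop("malformed value in column '", cn, "' at row ", bad[1])
  }
  bad <- which(is.na(records$patient_id) | is.na(records$ear) |
                 is.na(records$conduction) | is.na(records$gender))
  if (length(bad))
    stop("malformed value in identifier columns at row ", bad[1])
  invisible(records)
}

#' Apply the cohort inclusion/exclusion criteria
#'
#' Filters an audiogram record table by six criteria: (1) the tested ear
#' must be documented as left, right, or soundfield; (2) only
#' bone-conduction tests are kept; (3) only the frequencies of interest
#' (500, 1000, 2000, 4000 Hz) are kept; (4) thresholds recorded as 0 dB are
#' removed as failed test attempts; (5) PEFs with fewer than `min_tests`
#' surviving tests are removed entirely (this guarantees the 4-bin
#' cross-validation design downstream); (6) ages outside `[age_min,
#' age_max]` years are removed to focus on a pediatric population.
#'
#' Criteria are applied sequentially in the order 1, 2, 3, 4, 6, 5: the
#' minimum-test-count rule counts tests that survive every record-level
#' criterion, so that every retained PEF is guaranteed at least
#' `min_tests` rows.  Removal counts are reported under the criterion
#' numbering above regardless of application order.  `age_min` defaults to
#' one week because a zero age has no log transform.
#'
#' @param records a record data.frame (see [generate_cohort()] for the
#'   schema).
#' @param min_tests minimum surviving tests per PEF (default 4).
#' @param age_min,age_max retained age range in years.
#' @param frequencies the frequency grid of interest, Hz.
#' @return A list: `records` (surviving rows) and `report`, a named integer
#'   vector of removal counts for criteria `ear`, `conduction`,
#'   `frequency`, `zero_threshold`, `min_tests`, `age_range`.
#' @export
apply_filters <- function(records, min_tests = 4L,
                          age_min = 7 / 365, age_max = 21,
                          frequencies = c(500, 1000, 2000, 4000)) {
  check_records(records)
  report <- c(ear = 0L, conduction = 0L, frequency = 0L,
              zero_threshold = 0L, min_tests = 0L, age_range = 0L)

  keep <- records$ear %in% c("left", "right", "soundfield")
  report["ear"] <- sum(!keep)
  records <- records[keep, , drop = FALSE]

  keep <- records$conduction == "bone"
  report["conduction"] <- sum(!keep)
  records <- records[keep, , drop = FALSE]

  keep <- records$frequency_hz %in% frequencies
  report["frequency"] <- sum(!keep)
  records <- records[keep, , drop = FALSE]

  keep <- records$threshold_db != 0
  report["zero_threshold"] <- sum(!keep)
  records <- records[keep, , drop = FALSE]

  keep <- records$age_years >= age_min & records$age_years <= age_max
  report["age_range"] <- sum(!keep)
  records <- records[keep, , drop = FALSE]

  key <- pef_key(records)
  n_per <- table(key)
  keep <- n_per[key] >= min_tests
  report["min_tests"] <- sum(!keep)
  records <- records[keep, , drop = FALSE]

  rownames(records) <- NULL
  list(records = records, report = report)
}

#' PEF keys for a record table
#'
#' One ear of one patient at one test frequency is coded as a separate
#' longitudinal entity ("patient-ear-frequency", PEF).
#'
#' @param records a record data.frame.
#' @return Character vector `patient:ear:frequency`, one per row.
#' @export
pef_key <- function(records) {
  paste(records$patient_id, records$ear, records$frequency_hz, sep = ":")
}

#' Group records into a PEF dataset
#'
#' Attaches the PEF key and sorts rows by key and then by ascending age
#' within a PEF (age ties keep input order).  Expects already-filtered
#' records.
#'
#' @param records a filtered record data.frame.
#' @return The data.frame with a `pef_key` column, ordered by (key, age),
#'   of class `pef_dataset`.
#' @export
code_pefs <- function(records) {
  records$pef_key <- pef_key(records)
  ord <- order(records$pef_key, records$age_years, method = "radix")
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pef_dataset", "data.frame")
  out
}

#' @export
print.pef_dataset <- function(x, ...) {
  cat("PEF dataset: ", nrow(x), " records, ",
      length(unique(x$pef_key)), " PEFs\n", sep = "")
  NextMethod()
}

#' Populate the regression design columns
#'
#' Adds `log_age = ln(age_years)`, `gender_f` (1 if F), and
#' `log_diag = ln(diag_count + 1)`.  The `+ 1` keeps a zero diagnosis count
#' mapped to 0 and the transform monotone.  Idempotent.
#'
#' @param dataset a `pef_dataset` (or any record data.frame).
#' @return The input with design columns populated.
#' @export
build_design <- function(dataset) {
  if (any(dataset$age_years <= 0))
    stop("age_years <= 0 cannot enter log(age); re-run apply_filters() ",
         "with a positive age_min floor (default one week)")
  dataset$log_age <- log(dataset$age_years)
  dataset$gender_f <- as.numeric(dataset$gender == "F")
  dataset$log_diag <- log(dataset$diag_count + 1)
  dataset
}

#' Design matrix view of a dataset
#'
#' @param dataset rows carrying `log_age`, `gender_f`, `log_diag`
#'   (see [build_design()]).
#' @return Numeric matrix with columns `(Intercept)`, `log_age`,
#'   `gender_f`, `log_diag`.
#' @export
design_matrix <- function(dataset) {
  if (is.null(dataset$log_age))
    stop("design columns missing; call build_design() first")
  X <- cbind(1, dataset$log_age, dataset$gender_f, dataset$log_diag)
  colnames(X) <- design_columns()
  X
}

#' Prepare a record table for modelling
#'
#' Convenience chain: [apply_filters()], [code_pefs()], [build_design()].
#'
#' @inheritParams apply_filters
#' @return A `pef_dataset` with design columns, plus the filter report as
#'   attribute `"filter_report"`.
#' @export
prepare_cohort <- function(records, min_tests = 4L, age_min = 7 / 365,
                           age_max = 21,
                           frequencies = c(500, 1000, 2000, 4000)) {
  f <- apply_filters(records, min_tests = min_tests, age_min = age_min,
                     age_max = age_max, frequencies = frequencies)
  out <- build_design(code_pefs(f$records))
  attr(out, "filter_report") <- f$report
  out
}
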