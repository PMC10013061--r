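cohort_required_columns <- function() {
  c("patient_id", clinical_variables(), "event", "time", "meld", "child_pugh")
}

as_numeric_checked <- function(col, name) {
  out <- suppressWarnings(as.numeric(col))
  bad <- which(!is.na(col) & is.na(out))
  if (length(bad)) {
    stop(sprintf("non-numeric value '%s' in column '%s' at row %d",
                 col[bad[1L]], name, bad[1L]), call. = FALSE)
  }
  out
}

#' Validate a cohort table
#'
#' Checks the structural invariants of a cohort table: required columns
#' present, unique patient ids, binary event indicator, positive follow-up
#' times and HE grades in \{0, 1, 2\}. Missing clinical values are allowed
#' and preserved.
#'
#' @param cohort A data frame.
#' @return The cohort, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(cohort) {
  missing_cols <- setdiff(cohort_required_columns(), names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(cohort$patient_id)) {
    dup <- unique(cohort$patient_id[duplicated(cohort$patient_id)])
    stop("duplicate patient_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(cohort$event)) || !all(cohort$event %in% c(0, 1))) {
    stop("event must be 0 or 1 for every patient", call. = FALSE)
  }
  if (any(is.na(cohort$time)) || any(cohort$time <= 0)) {
    stop("time must be positive for every patient", call. = FALSE)
  }
  he <- cohort$HE
  if (any(!is.na(he) & !(he %in% c(0, 1, 2)))) {
    stop("HE grade must be 0, 1, 2 or missing", call. = FALSE)
  }
  invisible(cohort)
}

#' Read a cohort table from CSV
#'
#' Reads a comma-separated cohort file with one row per patient and the
#' columns `patient_id`, the seven clinical variables
#' (see [clinical_variables()]), `event` (1 = death or transplant within
#' follow-up), `time` (days), `meld` and `child_pugh`. Empty cells are
#' treated as missing and preserved. The HE column may hold text grades
#' ("unimpaired"/"minimal"/"overt") or integers 0/1/2; text is encoded via
#' [encode_he()].
#'
#' @param path Path to the CSV file.
#' @param config An [analysis_config()] (currently unused by the reader but
#'   accepted for interface symmetry).
#' @return A validated cohort data frame.
#' @export
read_cohort <- function(path, config = analysis_config()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character",
                         na.strings = c("", "NA"))
  missing_cols <- setdiff(cohort_required_columns(), names(raw))
  if (length(missing_cols)) {
    stop("cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(patient_id = raw$patient_id, stringsAsFactors = FALSE)
  for (v in setdiff(clinical_variables(), "HE")) {
    out[[v]] <- as_numeric_checked(raw[[v]], v)
  }
  out$HE <- encode_he(raw$HE)
  for (v in c("event", "time", "meld", "child_pugh")) {
    out[[v]] <- as_numeric_checked(raw[[v]], v)
  }
  validate_cohort(out)
  out
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: missing cells are written as empty strings,
#' so a write/read round trip reproduces the table exactly.
#'
#' @param cohort A cohort data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort[, cohort_required_columns()], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

# administrative censoring at the follow-up horizon: events beyond the
# horizon are treated as censored at the horizon
censor_at_horizon <- function(cohort, horizon_days) {
  late <- cohort$time > horizon_days
  cohort$event[late] <- 0
  cohort$time[late] <- horizon_days
  cohort
}
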