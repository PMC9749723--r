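#' Write a cohort to delimited text files
#'
#' Writes `subjects.csv`, `measurements.csv` and `smoking.csv` into `path`
#' (created if needed). Ground truth, when present, is deliberately not
#' written: downstream inference must never see it.
#'
#' @param cohort an `lmv_cohort` or a list with `subjects`, `measurements`
#'   and `smoking` data frames.
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$subjects, file.path(path, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$measurements, file.path(path, "measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$smoking, file.path(path, "smoking.csv"),
                   row.names = FALSE)
  invisible(path)
}

SUBJECT_COLS <- c("subject_id", "practice_id", "sex", "ethnicity", "entry_age",
                  "exit_age", "diabetes_dx_age", "event_indicator",
                  "af_dx_age", "bp_med_first_age")
MEASUREMENT_COLS <- c("subject_id", "factor", "age", "value")
SMOKING_COLS <- c("subject_id", "age", "current_smoker")

#' Read and validate a cohort from delimited text files
#'
#' Reads the three tables written by [write_cohort()] and enforces the
#' schema: required columns, strictly increasing measurement ages within
#' each subject x factor series, no duplicated (subject, factor, age)
#' rows, exit after entry, diagnosis on/before exit, and finite values.
#'
#' @param path directory containing `subjects.csv`, `measurements.csv`
#'   and `smoking.csv`.
#' @return an `lmv_cohort` (with `truth = NULL`).
#' @export
read_cohort <- function(path) {
  subjects <- utils::read.csv(file.path(path, "subjects.csv"),
                              stringsAsFactors = FALSE)
  measurements <- utils::read.csv(file.path(path, "measurements.csv"),
                                  stringsAsFactors = FALSE)
  smoking <- utils::read.csv(file.path(path, "smoking.csv"),
                             stringsAsFactors = FALSE)
  validate_cohort_tables(subjects, measurements, smoking)
  structure(list(subjects = subjects, measurements = measurements,
                 smoking = smoking, truth = NULL),
            class = "lmv_cohort")
}

validate_cohort_tables <- function(subjects, measurements, smoking) {
  miss <- setdiff(SUBJECT_COLS, names(subjects))
  if (length(miss))
    stop("subjects table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  miss <- setdiff(MEASUREMENT_COLS, names(measurements))
  if (length(miss))
    stop("measurements table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  miss <- setdiff(SMOKING_COLS, names(smoking))
  if (length(miss))
    stop("smoking table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)

  bad <- subjects$subject_id[subjects$exit_age <= subjects$entry_age]
  if (length(bad))
    stop("exit_age (event/censoring age) not after entry_age for subject_id ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- subjects$subject_id[subjects$diabetes_dx_age > subjects$exit_age]
  if (length(bad))
    stop("diabetes_dx_age after exit_age for subject_id ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(subjects$subject_id))
    stop("duplicate subject_id in subjects table", call. = FALSE)

  if (nrow(measurements)) {
    if (!all(measurements$factor %in% RISK_FACTORS))
      stop("measurements contain unknown factor names: ",
           paste(unique(setdiff(measurements$factor, RISK_FACTORS)),
                 collapse = ", "), call. = FALSE)
    if (any(!is.finite(measurements$value)))
      stop("non-finite measurement values", call. = FALSE)
    key <- paste(measurements$subject_id, measurements$factor, measurements$age)
    if (anyDuplicated(key))
      stop("duplicate (subject_id, factor, age) rows in measurements table",
           call. = FALSE)
    # series are stored sorted: within each (subject, factor) block, ages
    # must be strictly increasing in file order
    same <- c(FALSE,
              measurements$subject_id[-1] == measurements$subject_id[-nrow(measurements)] &
              measurements$factor[-1] == measurements$factor[-nrow(measurements)])
    if (any(same & c(FALSE, diff(measurements$age) <= 0)))
      stop("measurement ages not strictly increasing within a series",
           call. = FALSE)
    unknown <- setdiff(measurements$subject_id, subjects$subject_id)
    if (length(unknown))
      stop("measurements reference unknown subject_id ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
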