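# CSV input/output for cohorts.
#
# Long-form burden file: patient_id, day_index, burden_hours (one row per
# patient-day with recorded AT/AF; absent days are zero-burden).
# Covariates file: patient_id, chads2, on_warfarin_or_aad, followup_days.
# Covariates may instead be embedded as constant columns in the burden file,
# in which case every patient needs at least one row.

#' Read a cohort from delimited text
#'
#' Reads long-form patient-day burden rows plus per-patient covariates and
#' returns a validated [af_cohort()]. Validation failures (burden outside
#' \[0, 24\], duplicate patient-day pairs, non-positive day indices) are
#' collected and reported together with the offending patient and day.
#'
#' @param burden_file Path to the long-form burden CSV with columns
#'   `patient_id`, `day_index`, `burden_hours`.
#' @param covariates_file Path to the per-patient covariates CSV with columns
#'   `patient_id`, `chads2`, and optionally `on_warfarin_or_aad` and
#'   `followup_days`. If `NULL`, the same columns are looked up in
#'   `burden_file` (embedded covariates).
#' @param sep Field separator (default comma).
#' @return An [af_cohort()].
#' @details When `followup_days` is absent, each patient's follow-up is taken
#'   as their last recorded day. Missing `on_warfarin_or_aad` defaults to
#'   `FALSE`.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(burden_file, covariates_file = NULL, sep = ",") {
  if (!file.exists(burden_file)) {
    stop("burden_file not found: ", burden_file, call. = FALSE)
  }
  burden <- utils::read.csv(burden_file, sep = sep,
                            stringsAsFactors = FALSE)
  need <- c("patient_id", "day_index", "burden_hours")
  miss <- setdiff(need, names(burden))
  if (length(miss)) {
    stop("burden file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  burden$patient_id <- as.character(burden$patient_id)

  if (!is.null(covariates_file)) {
    if (!file.exists(covariates_file)) {
      stop("covariates_file not found: ", covariates_file, call. = FALSE)
    }
    covar <- utils::read.csv(covariates_file, sep = sep,
                             stringsAsFactors = FALSE)
  } else {
    covar <- burden
  }
  if (!all(c("patient_id", "chads2") %in% names(covar))) {
    stop("covariates missing column(s): patient_id and/or chads2",
         call. = FALSE)
  }
  covar$patient_id <- as.character(covar$patient_id)
  covar <- covar[!duplicated(covar$patient_id),
                 intersect(c("patient_id", "chads2", "on_warfarin_or_aad",
                             "followup_days"), names(covar)),
                 drop = FALSE]
  rownames(covar) <- covar$patient_id

  no_cov <- setdiff(unique(burden$patient_id), covar$patient_id)
  if (length(no_cov)) {
    stop("no covariates for patient(s): ",
         paste(utils::head(no_cov, 5L), collapse = ", "), call. = FALSE)
  }

  # Collect row-level violations before constructing, so one bad file read
  # reports every offending line at once.
  problems <- character()
  dup <- duplicated(burden[c("patient_id", "day_index")])
  if (any(dup)) {
    d <- burden[dup, ]
    problems <- c(problems, sprintf(
      "duplicate (patient, day): patient %s day %s", d$patient_id,
      d$day_index))
  }
  bad_day <- is.na(burden$day_index) | burden$day_index < 1 |
    burden$day_index != as.integer(burden$day_index)
  if (any(bad_day)) {
    d <- burden[bad_day, ]
    problems <- c(problems, sprintf(
      "invalid day_index: patient %s day %s", d$patient_id, d$day_index))
  }
  bad_h <- is.na(burden$burden_hours) | burden$burden_hours < 0 |
    burden$burden_hours > 24
  if (any(bad_h)) {
    d <- burden[bad_h, ]
    problems <- c(problems, sprintf(
      "burden outside [0, 24]: patient %s day %s value %s", d$patient_id,
      d$day_index, d$burden_hours))
  }
  if (length(problems)) {
    stop("cohort validation failed:\n  ",
         paste(utils::head(problems, 20L), collapse = "\n  "),
         if (length(problems) > 20L) "\n  ...", call. = FALSE)
  }

  records <- lapply(covar$patient_id, function(id) {
    rows <- burden[burden$patient_id == id, , drop = FALSE]
    fu <- if ("followup_days" %in% names(covar)) {
      covar[id, "followup_days"]
    } else if (nrow(rows)) {
      max(rows$day_index)
    } else 1L
    flag <- if ("on_warfarin_or_aad" %in% names(covar)) {
      covar[id, "on_warfarin_or_aad"]
    } else FALSE
    patient_record(
      burden_series(id, rows$day_index, rows$burden_hours,
                    followup_days = fu),
      chads2 = covar[id, "chads2"],
      on_warfarin_or_aad = flag
    )
  })
  af_cohort(records)
}

#' Write a cohort to delimited text
#'
#' Writes the long-form burden file and the per-patient covariates file in
#' the format read by [read_cohort()]; the pair round-trips exactly.
#'
#' @param cohort An [af_cohort()].
#' @param burden_file Output path for patient-day rows.
#' @param covariates_file Output path for per-patient covariates.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, burden_file, covariates_file) {
  stopifnot(inherits(cohort, "af_cohort"))
  burden <- do.call(rbind, lapply(unclass(cohort), function(r) {
    s <- r$series
    if (!length(s$day)) return(NULL)
    data.frame(patient_id = s$patient_id, day_index = s$day,
               burden_hours = s$hours, stringsAsFactors = FALSE)
  }))
  if (is.null(burden)) {
    burden <- data.frame(patient_id = character(), day_index = integer(),
                         burden_hours = numeric())
  }
  covar <- do.call(rbind, lapply(unclass(cohort), function(r) {
    data.frame(patient_id = r$series$patient_id, chads2 = r$chads2,
               on_warfarin_or_aad = r$on_warfarin_or_aad,
               followup_days = r$series$followup_days,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(burden, burden_file, row.names = FALSE, quote = FALSE)
  utils::write.csv(covar, covariates_file, row.names = FALSE, quote = FALSE)
  invisible(c(burden_file, covariates_file))
}
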