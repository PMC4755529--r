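# Data model for per-patient daily AT/AF burden series.
#
# A series is sparse: days with no row carry zero burden. Day 1 is the day of
# device implant; `followup_days` is the last day for which the device
# recorded data, so days beyond it are *unknown*, not zero.

#' Daily AT/AF burden series for one patient
#'
#' Constructs a validated sparse daily burden series. Each element of `day`
#' pairs with the corresponding element of `hours`: the cumulative time spent
#' in atrial tachycardia / atrial fibrillation (AT/AF) on that calendar day.
#' Days not listed are interpreted as zero burden. Days after `followup_days`
#' are outside the recorded follow-up.
#'
#' @param patient_id Identifier, coerced to character scalar.
#' @param day Integer vector of day indices since implant (implant day = 1).
#'   Must be unique and positive; rows are sorted by day internally.
#' @param hours Numeric vector of daily AT/AF burden in hours, each in
#'   \[0, 24\].
#' @param followup_days Last day with device data; every `day` must be
#'   `<= followup_days`.
#' @return An object of class `burden_series`.
#' @examples
#' s <- burden_series("P1", day = c(31L, 40L), hours = c(6, 0.5),
#'                    followup_days = 395L)
#' summarize_burden(s)
#' @export
burden_series <- function(patient_id, day = integer(), hours = numeric(),
                          followup_days = if (length(day)) max(day) else 1L) {
  patient_id <- as.character(patient_id)
  stopifnot(length(patient_id) == 1L, nchar(patient_id) > 0L)
  if (length(day) != length(hours)) {
    stop("`day` and `hours` must have the same length", call. = FALSE)
  }
  day <- as.integer(day)
  hours <- as.numeric(hours)
  followup_days <- as.integer(followup_days)
  if (is.na(followup_days) || followup_days < 1L) {
    stop("`followup_days` must be a positive integer", call. = FALSE)
  }
  if (anyNA(day) || any(day < 1L)) {
    stop("day indices must be positive integers (patient ", patient_id, ")",
         call. = FALSE)
  }
  if (anyDuplicated(day)) {
    stop("duplicate day index ", day[duplicated(day)][1L], " for patient ",
         patient_id, call. = FALSE)
  }
  if (any(day > followup_days)) {
    stop("day index beyond followup_days (", followup_days, ") for patient ",
         patient_id, call. = FALSE)
  }
  bad <- which(is.na(hours) | hours < 0 | hours > 24)
  if (length(bad)) {
    stop("burden outside [0, 24] for patient ", patient_id, ", day ",
         day[bad[1L]], " (", hours[bad[1L]], " hours)", call. = FALSE)
  }
  o <- order(day)
  structure(
    list(patient_id = patient_id, day = day[o], hours = hours[o],
         followup_days = followup_days),
    blanked_through = 0L,
    class = "burden_series"
  )
}

#' @export
print.burden_series <- function(x, ...) {
  cat("<burden_series> patient", x$patient_id,
      "| follow-up", x$followup_days, "days |",
      length(x$day), "recorded days")
  bt <- attr(x, "blanked_through")
  if (bt > 0L) cat(" | blanked through day", bt)
  cat("\n")
  invisible(x)
}

#' Patient record: burden series plus covariates
#'
#' @param series A [burden_series()].
#' @param chads2 Integer CHADS2 stroke-risk score in \[0, 6\].
#' @param on_warfarin_or_aad Logical; `TRUE` when the patient was taking
#'   warfarin or antiarrhythmic drugs at baseline. Used only to mirror the
#'   primary (excluded) versus secondary (included) cohort split.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(series, chads2, on_warfarin_or_aad = FALSE) {
  stopifnot(inherits(series, "burden_series"))
  chads2 <- as.integer(chads2)
  if (is.na(chads2) || chads2 < 0L || chads2 > 6L) {
    stop("chads2 must be an integer in [0, 6] (patient ", series$patient_id,
         ")", call. = FALSE)
  }
  on_warfarin_or_aad <- isTRUE(as.logical(on_warfarin_or_aad))
  structure(
    list(series = series, chads2 = chads2,
         on_warfarin_or_aad = on_warfarin_or_aad),
    class = "patient_record"
  )
}

#' @export
print.patient_record <- function(x, ...) {
  cat("<patient_record> CHADS2 =", x$chads2, "\n")
  print(x$series)
  invisible(x)
}

#' Cohort container
#'
#' A cohort is a list of [patient_record()] objects with unique patient ids.
#'
#' @param records List of `patient_record` objects.
#' @return An object of class `af_cohort`.
#' @export
af_cohort <- function(records = list()) {
  ok <- vapply(records, inherits, logical(1L), what = "patient_record")
  if (!all(ok)) stop("all elements must be patient_record objects",
                     call. = FALSE)
  ids <- vapply(records, function(r) r$series$patient_id, character(1L))
  if (anyDuplicated(ids)) {
    stop("duplicate patient_id: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  names(records) <- ids
  structure(records, class = "af_cohort")
}

#' @export
print.af_cohort <- function(x, ...) {
  cat("<af_cohort>", length(x), "patients\n")
  invisible(x)
}

#' @export
`[.af_cohort` <- function(x, i) {
  af_cohort(unclass(x)[i])
}

#' Remove the post-implant blanking period
#'
#' Drops all recorded days with `day <= blanking_days`. The first days after
#' device implant are excluded from analysis because the implant procedure
#' itself can provoke transient AF; with the default of 30 days, monitoring
#' effectively begins on day 31. `followup_days` is unchanged. The operation
#' is idempotent for a fixed `blanking_days`.
#'
#' @param x A `burden_series`, `patient_record`, or `af_cohort`.
#' @param blanking_days Non-negative integer; days `1..blanking_days` are
#'   removed. Default 30.
#' @return Object of the same class with blanked days removed.
#' @export
apply_blanking <- function(x, blanking_days = 30L) {
  UseMethod("apply_blanking")
}

#' @export
apply_blanking.burden_series <- function(x, blanking_days = 30L) {
  blanking_days <- as.integer(blanking_days)
  stopifnot(!is.na(blanking_days), blanking_days >= 0L)
  keep <- x$day > blanking_days
  x$day <- x$day[keep]
  x$hours <- x$hours[keep]
  attr(x, "blanked_through") <- max(attr(x, "blanked_through"), blanking_days)
  x
}

#' @export
apply_blanking.patient_record <- function(x, blanking_days = 30L) {
  x$series <- apply_blanking(x$series, blanking_days)
  x
}

#' @export
apply_blanking.af_cohort <- function(x, blanking_days = 30L) {
  af_cohort(lapply(unclass(x), apply_blanking, blanking_days = blanking_days))
}

#' AF-day classification
#'
#' A day counts as an AT/AF day when its burden *strictly* exceeds the
#' threshold (default 5 minutes). The strict inequality means a day with
#' exactly 5 minutes of device-detected AT/AF is not an AF day; short
#' episodes below this duration are commonly atrial oversensing artefacts.
#'
#' @param hours Numeric vector of daily burden in hours, each in \[0, 24\].
#' @param threshold_minutes Threshold in minutes (default 5).
#' @return Logical vector.
#' @export
is_af_day <- function(hours, threshold_minutes = 5) {
  if (anyNA(hours) || any(hours < 0 | hours > 24)) {
    stop("burden hours must be in [0, 24]", call. = FALSE)
  }
  hours > threshold_minutes / 60
}

#' Burden summary over a span
#'
#' Computes the three per-patient burden metrics: average daily burden over
#' the span (zero-burden days count in the denominator), maximum single-day
#' burden, and the percentage of span days that are AF days (see
#' [is_af_day()]).
#'
#' The span is either an explicit [monitoring_window()] or, when `window` is
#' `NULL`, the patient's full recorded follow-up after any blanking applied
#' with [apply_blanking()] (i.e. days `blanked_through + 1 .. followup_days`).
#' A window is truncated at `followup_days`; a span with no evaluable days is
#' an error.
#'
#' @param series A [burden_series()].
#' @param window A [monitoring_window()] or `NULL` for the full (post-
#'   blanking) follow-up.
#' @param threshold_minutes AF-day threshold in minutes passed to
#'   [is_af_day()].
#' @return A `burden_summary`: list with `avg_burden` (hours/day),
#'   `max_daily_burden` (hours), `pct_af_days` (percent), `n_days`.
#' @examples
#' s <- burden_series("P1", day = 31L, hours = 6, followup_days = 130L)
#' summarize_burden(apply_blanking(s))  # 100-day span, one 6 h day
#' @export
summarize_burden <- function(series, window = NULL, threshold_minutes = 5) {
  stopifnot(inherits(series, "burden_series"))
  if (is.null(window)) {
    start <- attr(series, "blanked_through") + 1L
    end <- series$followup_days
  } else {
    stopifnot(inherits(window, "monitoring_window"))
    start <- window$start_day
    end <- min(window$end_day, series$followup_days)
  }
  n_days <- end - start + 1L
  if (n_days < 1L) {
    stop("empty span: no evaluable days in [", start, ", ", end,
         "] for patient ", series$patient_id, call. = FALSE)
  }
  keep <- series$day >= start & series$day <= end
  h <- series$hours[keep]
  structure(
    list(
      avg_burden = sum(h) / n_days,
      max_daily_burden = if (length(h)) max(h) else 0,
      pct_af_days = 100 * sum(is_af_day(h, threshold_minutes)) / n_days,
      n_days = n_days
    ),
    class = "burden_summary"
  )
}

#' @export
print.burden_summary <- function(x, ...) {
  cat(sprintf(
    "<burden_summary> avg %.4f h/day | max %.2f h | %.2f%% AF days over %d days\n",
    x$avg_burden, x$max_daily_burden, x$pct_af_days, x$n_days))
  invisible(x)
}
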