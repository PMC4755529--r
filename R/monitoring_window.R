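#' Monitoring window
#'
#' A contiguous span of once-daily snapshot recordings. Windows start on day
#' 31 post implant by default, immediately after the 30-day blanking period,
#' and span `[start_day, start_day + length_days - 1]` inclusive. The study
#' windows are 14, 28, 56, 112 and 365 days, but any positive length is
#' accepted.
#'
#' @param length_days Positive integer window length in days.
#' @param start_day First monitoring day (default 31).
#' @return An object of class `monitoring_window` with fields `start_day`,
#'   `length_days`, `end_day`.
#' @examples
#' monitoring_window(14)   # days 31..44
#' @export
monitoring_window <- function(length_days, start_day = 31L) {
  length_days <- as.integer(length_days)
  start_day <- as.integer(start_day)
  stopifnot(length(length_days) == 1L, length(start_day) == 1L)
  if (is.na(length_days) || length_days < 1L) {
    stop("length_days must be a positive integer", call. = FALSE)
  }
  if (is.na(start_day) || start_day < 1L) {
    stop("start_day must be a positive integer", call. = FALSE)
  }
  structure(
    list(start_day = start_day, length_days = length_days,
         end_day = start_day + length_days - 1L),
    class = "monitoring_window"
  )
}

#' @export
print.monitoring_window <- function(x, ...) {
  cat("<monitoring_window> days", x$start_day, "..", x$end_day,
      paste0("(", x$length_days, " days)\n"))
  invisible(x)
}
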