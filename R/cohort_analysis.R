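# Reporting layer: per-window eligibility and gold-standard (device)
# detection denominators, stratification, detection rates with exact
# binomial confidence intervals.

#' Patients with device data covering a window
#'
#' A patient is eligible for a window when their recorded follow-up reaches
#' the window's last day (`followup_days >= start_day + length_days - 1`).
#' This is the "patients with CIED data in window" denominator; it shrinks
#' as windows lengthen.
#'
#' @param cohort An [af_cohort()] (blanking already applied).
#' @param window A [monitoring_window()].
#' @return The eligible sub-cohort, an [af_cohort()].
#' @export
eligible_patients <- function(cohort, window) {
  stopifnot(inherits(cohort, "af_cohort"),
            inherits(window, "monitoring_window"))
  keep <- vapply(unclass(cohort),
                 function(r) r$series$followup_days >= window$end_day,
                 logical(1L))
  cohort[keep]
}

#' Device (gold standard) detection within a window
#'
#' `TRUE` iff the continuously monitoring device recorded at least one AF
#' day (burden strictly above the threshold, see [is_af_day()]) within the
#' window. This is the denominator for the "% of patients with AT/AF in
#' window" sensitivity column.
#'
#' @param record A [patient_record()].
#' @param window A [monitoring_window()].
#' @param threshold_minutes AF-day threshold in minutes (default 5).
#' @return Logical scalar.
#' @export
cied_detected_in_window <- function(record, window, threshold_minutes = 5) {
  stopifnot(inherits(record, "patient_record"),
            inherits(window, "monitoring_window"))
  s <- record$series
  keep <- s$day >= window$start_day & s$day <= window$end_day
  any(is_af_day(s$hours[keep], threshold_minutes))
}

#' Per-patient average daily burden over post-blanking follow-up
#'
#' Convenience accessor used for burden-based stratification.
#'
#' @param record A [patient_record()].
#' @param blanking_days Blanking period (default 30).
#' @return Average burden in hours/day.
#' @export
avg_daily_burden <- function(record, blanking_days = 30L) {
  stopifnot(inherits(record, "patient_record"))
  s <- apply_blanking(record$series, blanking_days)
  summarize_burden(s)$avg_burden
}

#' Define a stratum
#'
#' @param name Stratum label.
#' @param predicate Function of a [patient_record()] returning `TRUE` for
#'   members.
#' @return A `stratum_spec`.
#' @export
stratum_spec <- function(name, predicate) {
  stopifnot(is.character(name), length(name) == 1L, is.function(predicate))
  structure(list(name = name, predicate = predicate),
            class = "stratum_spec")
}

#' CHADS2 risk stratification
#'
#' Partition into intermediate risk (CHADS2 = 1) and high risk
#' (CHADS2 >= 2).
#'
#' @return List of two [stratum_spec()] objects.
#' @export
stratify_chads2 <- function() {
  list(
    stratum_spec("CHADS2=1", function(r) r$chads2 == 1L),
    stratum_spec("CHADS2>=2", function(r) r$chads2 >= 2L)
  )
}

#' Fixed-cutoff burden stratification
#'
#' Partition patients at a fixed average-daily-burden cutoff computed over
#' each patient's post-blanking follow-up: low stratum strictly below the
#' cutoff, high stratum at or above it. The study's cutoffs were its cohort
#' median, 0.044 hours/day, and the thromboembolism-linked alternative of
#' 5.5 hours/day.
#'
#' @param cutoff_hours Cutoff in hours/day.
#' @param blanking_days Blanking period for the average (default 30).
#' @return List of two [stratum_spec()] objects.
#' @export
stratify_burden <- function(cutoff_hours, blanking_days = 30L) {
  force(cutoff_hours); force(blanking_days)
  list(
    stratum_spec(sprintf("burden<%g", cutoff_hours),
                 function(r) avg_daily_burden(r, blanking_days) <
                   cutoff_hours),
    stratum_spec(sprintf("burden>=%g", cutoff_hours),
                 function(r) avg_daily_burden(r, blanking_days) >=
                   cutoff_hours)
  )
}

#' Median split on average daily burden
#'
#' Computes the cohort median of per-patient average daily burden (over
#' post-blanking follow-up) and returns it with the corresponding low
#' (`< median`) / high (`>= median`) strata. With ties at the median, tied
#' patients fall in the high stratum.
#'
#' @param cohort An [af_cohort()].
#' @param blanking_days Blanking period (default 30).
#' @return List with `cutoff_hours` (the median) and `strata` (two
#'   [stratum_spec()] objects).
#' @export
median_burden_split <- function(cohort, blanking_days = 30L) {
  stopifnot(inherits(cohort, "af_cohort"), length(cohort) >= 1L)
  avgs <- vapply(unclass(cohort), avg_daily_burden, numeric(1L),
                 blanking_days = blanking_days)
  cutoff <- stats::median(avgs)
  list(cutoff_hours = cutoff,
       strata = stratify_burden(cutoff, blanking_days))
}

#' Percentage rate
#'
#' @param successes,n Numerator and denominator.
#' @return `100 * successes / n` (`NA` when `n` is 0).
#' @export
rate_percent <- function(successes, n) {
  ifelse(n > 0, 100 * successes / n, NA_real_)
}

#' Binomial confidence interval on the percentage scale
#'
#' Exact Clopper-Pearson (default) or Wilson score interval for a binomial
#' proportion, returned in percent. Clopper-Pearson is the default because
#' it reproduces the published tables' intervals exactly (e.g. 126/254 ->
#' \[43.3, 55.9\]%, which the Wilson interval does not give); `successes` is
#' rounded half-up to an integer for the exact method.
#'
#' @param successes Number of successes (non-negative, `<= n`; may be the
#'   fractional Monte Carlo mean, rounded internally).
#' @param n Number of trials.
#' @param method `"clopper_pearson"` or `"wilson"`.
#' @param level Confidence level (default 0.95).
#' @return Named numeric `c(lower, upper)` in percent; both `NA` with a
#'   warning when `n = 0`.
#' @export
binomial_ci <- function(successes, n,
                        method = c("clopper_pearson", "wilson"),
                        level = 0.95) {
  method <- match.arg(method)
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("n must be a non-negative integer",
                               call. = FALSE)
  if (n == 0L) {
    warning("binomial_ci undefined for n = 0", call. = FALSE)
    return(c(lower = NA_real_, upper = NA_real_))
  }
  if (successes < 0 || successes > n) {
    stop("successes must lie in [0, n]", call. = FALSE)
  }
  alpha <- 1 - level
  if (method == "clopper_pearson") {
    x <- floor(successes + 0.5)  # round half up: printed counts are integers
    lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
    upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  } else {
    p <- successes / n
    z <- stats::qnorm(1 - alpha / 2)
    denom <- 1 + z^2 / n
    centre <- p + z^2 / (2 * n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
    lower <- max(0, (centre - half) / denom)
    upper <- min(1, (centre + half) / denom)
  }
  c(lower = 100 * lower, upper = 100 * upper)
}

#' Chi-square comparison of two detection-rate rows
#'
#' Plain chi-square test on the rounded detected / not-detected counts of
#' two strata (no continuity correction, matching large-sample table
#' comparisons).
#'
#' @param detected_a,n_a Detected count and denominator for stratum A.
#' @param detected_b,n_b Detected count and denominator for stratum B.
#' @return p-value.
#' @export
strata_chisq <- function(detected_a, n_a, detected_b, n_b) {
  a <- floor(detected_a + 0.5); b <- floor(detected_b + 0.5)
  tab <- rbind(c(a, n_a - a), c(b, n_b - b))
  stats::chisq.test(tab, correct = FALSE)$p.value
}

#' Detection-rate table across windows and strata
#'
#' Reproduces the study's reporting layout: for each monitoring window and
#' stratum it counts eligible patients (device data covering the window),
#' those with device-detected AT/AF in the window, and runs the snapshot
#' simulation on the device-detected subset. Rates are reported as a
#' percentage of all eligible patients and as a percentage of
#' device-detected patients (the snapshot sensitivity), each with a 95%
#' binomial confidence interval computed on the rounded Monte Carlo mean
#' count.
#'
#' Blanking is applied internally (idempotent), so the same cohort object
#' can be passed blanked or raw. Per-patient random substreams depend only
#' on `seed` and the patient id, so stratum rows are consistent with the
#' whole-cohort rows.
#'
#' @param cohort An [af_cohort()].
#' @param windows Integer vector of window lengths in days (default
#'   `c(14, 28, 56, 112, 365)`).
#' @param strata `NULL` for a single "all" stratum, or a list of
#'   [stratum_spec()] objects partitioning the cohort (see
#'   [stratify_chads2()], [stratify_burden()], [median_burden_split()]).
#' @param n_reps Monte Carlo repetitions per patient-window (default 5000).
#' @param seed Master seed (required).
#' @param ci_method Passed to [binomial_ci()].
#' @param af_threshold_minutes AF-day threshold in minutes (default 5).
#' @param sub_threshold_policy Passed to [daily_probability()].
#' @param blanking_days Blanking period (default 30).
#' @param start_day First monitoring day (default 31).
#' @return A data frame of class `detection_table`, one row per
#'   window-stratum, with columns `stratum`, `window_days`, `n_with_data`,
#'   `n_cied_detected`, `mc_detected` (fractional MC mean),
#'   `n_snapshot_detected` (rounded), `expected_detected` (analytic),
#'   `rate_total_pct`, `rate_total_lo`, `rate_total_hi`, `rate_cied_pct`,
#'   `rate_cied_lo`, `rate_cied_hi`, `n_reps`. Empty stratum-window cells
#'   yield a row with zero counts and `NA` rates rather than being dropped.
#' @export
detection_table <- function(cohort, windows = c(14L, 28L, 56L, 112L, 365L),
                            strata = NULL, n_reps = 5000L, seed,
                            ci_method = c("clopper_pearson", "wilson"),
                            af_threshold_minutes = 5,
                            sub_threshold_policy = c("zero", "raw"),
                            blanking_days = 30L, start_day = 31L) {
  stopifnot(inherits(cohort, "af_cohort"))
  ci_method <- match.arg(ci_method)
  sub_threshold_policy <- match.arg(sub_threshold_policy)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  cohort <- apply_blanking(cohort, blanking_days)
  if (is.null(strata)) {
    strata <- list(stratum_spec("all", function(r) TRUE))
  }
  rows <- list()
  for (st in strata) {
    stopifnot(inherits(st, "stratum_spec"))
    members <- vapply(unclass(cohort), st$predicate, logical(1L))
    sub <- cohort[members]
    for (w in windows) {
      win <- monitoring_window(w, start_day)
      elig <- eligible_patients(sub, win)
      det <- if (length(elig)) {
        vapply(unclass(elig), cied_detected_in_window, logical(1L),
               window = win, threshold_minutes = af_threshold_minutes)
      } else logical()
      cied <- elig[det]
      if (length(cied)) {
        sim <- simulate_cohort(cied, win, n_reps = n_reps,
                               af_threshold_minutes = af_threshold_minutes,
                               sub_threshold_policy = sub_threshold_policy,
                               seed = seed)
        mc <- sim$mc_detected
        expd <- sim$expected_detected
      } else {
        mc <- 0; expd <- 0
      }
      count <- floor(mc + 0.5)
      ci_tot <- if (length(elig)) {
        binomial_ci(count, length(elig), ci_method)
      } else c(NA_real_, NA_real_)
      ci_cied <- if (length(cied)) {
        binomial_ci(count, length(cied), ci_method)
      } else c(NA_real_, NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = st$name, window_days = as.integer(w),
        n_with_data = length(elig), n_cied_detected = length(cied),
        mc_detected = mc, n_snapshot_detected = count,
        expected_detected = expd,
        rate_total_pct = rate_percent(count, length(elig)),
        rate_total_lo = ci_tot[[1L]], rate_total_hi = ci_tot[[2L]],
        rate_cied_pct = rate_percent(count, length(cied)),
        rate_cied_lo = ci_cied[[1L]], rate_cied_hi = ci_cied[[2L]],
        n_reps = as.integer(n_reps), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("detection_table", "data.frame")
  out
}

#' @export
print.detection_table <- function(x, digits = 1, ...) {
  df <- as.data.frame(x)
  fmt <- function(p, lo, hi) {
    ifelse(is.na(p), "-",
           sprintf("%.1f [%.1f-%.1f]%%", p, lo, hi))
  }
  show <- data.frame(
    stratum = df$stratum, window = df$window_days,
    n = df$n_with_data, cied = df$n_cied_detected,
    snapshot = df$n_snapshot_detected,
    `of total` = fmt(df$rate_total_pct, df$rate_total_lo, df$rate_total_hi),
    `of CIED+` = fmt(df$rate_cied_pct, df$rate_cied_lo, df$rate_cied_hi),
    check.names = FALSE)
  print(show, row.names = FALSE)
  invisible(x)
}
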