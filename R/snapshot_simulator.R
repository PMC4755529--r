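# Daily-snapshot Bernoulli detection model.
#
# One instantaneous ECG snapshot per day: the probability that the snapshot
# lands inside AT/AF equals the fraction of that day spent in AT/AF
# (burden_hours / 24; e.g. 6 h of AT/AF -> 25%). Days are independent, and a
# window detects the patient iff at least one daily trial succeeds. The
# window detection probability therefore has the closed form
#   P(detect) = 1 - prod_d (1 - p_d)
# which serves as the exact oracle for the Monte Carlo route.

#' Snapshot success probability for one day
#'
#' Maps daily AT/AF burden (hours) to the probability that a single
#' instantaneous daily snapshot falls within AT/AF, i.e. `hours / 24`.
#'
#' Days at or below the AF-day threshold (default 5 minutes) are handled by
#' `sub_threshold_policy`:
#' * `"zero"` (default): such days contribute probability 0, consistent with
#'   the AT/AF definition that excludes episodes of 5 minutes or less as
#'   likely oversensing;
#' * `"raw"`: the burden fraction is used unchanged.
#'
#' @param hours Numeric vector of daily burden in hours, each in \[0, 24\].
#' @param af_threshold_minutes AF-day threshold in minutes (default 5).
#' @param sub_threshold_policy `"zero"` or `"raw"`.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @examples
#' daily_probability(6)            # 0.25
#' daily_probability(3 / 60)       # 0   (below 5-minute threshold)
#' daily_probability(3 / 60, sub_threshold_policy = "raw")
#' @export
daily_probability <- function(hours, af_threshold_minutes = 5,
                              sub_threshold_policy = c("zero", "raw")) {
  sub_threshold_policy <- match.arg(sub_threshold_policy)
  if (anyNA(hours) || any(hours < 0 | hours > 24)) {
    stop("burden hours must be in [0, 24]", call. = FALSE)
  }
  p <- hours / 24
  if (sub_threshold_policy == "zero") {
    p[hours <= af_threshold_minutes / 60] <- 0
  }
  p
}

#' Per-day snapshot probabilities across a window
#'
#' Expands a sparse series to the vector of daily success probabilities over
#' the window, one element per window day. Days with no recorded row (zero
#' burden) and days beyond the recorded follow-up contribute probability 0;
#' eligibility (sufficient follow-up) is the caller's responsibility.
#'
#' @inheritParams daily_probability
#' @param series A [burden_series()].
#' @param window A [monitoring_window()].
#' @return Numeric vector of length `window$length_days`.
#' @export
window_probabilities <- function(series, window, af_threshold_minutes = 5,
                                 sub_threshold_policy = c("zero", "raw")) {
  stopifnot(inherits(series, "burden_series"),
            inherits(window, "monitoring_window"))
  p <- numeric(window$length_days)
  keep <- series$day >= window$start_day & series$day <= window$end_day
  idx <- series$day[keep] - window$start_day + 1L
  p[idx] <- daily_probability(series$hours[keep], af_threshold_minutes,
                              sub_threshold_policy)
  p
}

#' Exact window detection probability
#'
#' Closed form of the daily Bernoulli process:
#' `1 - prod(1 - p_d)` over the days of the window, where `p_d` is
#' [daily_probability()]. This is the analytic oracle against which the
#' Monte Carlo estimate of [simulate_patient_window()] converges.
#'
#' @inheritParams window_probabilities
#' @return Probability in \[0, 1\]; exactly 0 iff all daily probabilities
#'   are 0, exactly 1 if any day has probability 1 (a full 24-hour AT/AF
#'   day).
#' @examples
#' s <- burden_series("P1", day = 31:44, hours = rep(6, 14),
#'                    followup_days = 44L)
#' analytic_window_prob(s, monitoring_window(14))   # 1 - 0.75^14
#' @export
analytic_window_prob <- function(series, window, af_threshold_minutes = 5,
                                 sub_threshold_policy = c("zero", "raw")) {
  p <- window_probabilities(series, window, af_threshold_minutes,
                            sub_threshold_policy)
  if (any(p >= 1)) return(1)
  # log-space product avoids underflow on long windows of small p
  1 - exp(sum(log1p(-p)))
}

# Stable per-patient seed derived from a master seed and the patient id, so
# that a patient's random substream does not depend on cohort order or
# subsetting. Polynomial rolling hash mod the Mersenne prime 2^31 - 1; all
# intermediates stay well below 2^53 so double arithmetic is exact.
patient_substream_seed <- function(master_seed, patient_id) {
  h <- 0
  for (ch in utf8ToInt(as.character(patient_id))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((h + as.numeric(master_seed)) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Monte Carlo snapshot detection for one patient-window
#'
#' Simulates the daily Bernoulli snapshot trials `n_reps` times (default
#' 5,000). A repetition detects the patient when at least one daily trial in
#' the window succeeds; `mc_detect_fraction` is the fraction of detecting
#' repetitions. The exact probability is returned alongside as
#' `analytic_prob`.
#'
#' @inheritParams window_probabilities
#' @param n_reps Number of Monte Carlo repetitions (default 5000).
#' @param seed Optional integer seed for this patient-window simulation; when
#'   supplied the result is reproducible and the caller's RNG state is left
#'   untouched.
#' @return A `detection_outcome`: list with `patient_id`, `window`,
#'   `analytic_prob`, `mc_detect_fraction`, `n_reps`.
#' @export
simulate_patient_window <- function(series, window, n_reps = 5000L,
                                    af_threshold_minutes = 5,
                                    sub_threshold_policy = c("zero", "raw"),
                                    seed = NULL) {
  n_reps <- as.integer(n_reps)
  stopifnot(n_reps >= 1L)
  p <- window_probabilities(series, window, af_threshold_minutes,
                            sub_threshold_policy)
  run <- function() {
    if (any(p >= 1)) return(1)
    nz <- p[p > 0]
    if (!length(nz)) return(0)
    u <- stats::runif(n_reps * length(nz))
    hit <- matrix(u < rep(nz, each = n_reps), nrow = n_reps)
    mean(rowSums(hit) > 0L)
  }
  frac <- if (is.null(seed)) run() else with_seed(seed, run())
  structure(
    list(patient_id = series$patient_id, window = window,
         analytic_prob = analytic_window_prob(series, window,
                                              af_threshold_minutes,
                                              sub_threshold_policy),
         mc_detect_fraction = frac, n_reps = n_reps),
    class = "detection_outcome"
  )
}

#' @export
print.detection_outcome <- function(x, ...) {
  cat(sprintf(
    "<detection_outcome> patient %s | %d-day window | analytic %.4f | MC %.4f (%d reps)\n",
    x$patient_id, x$window$length_days, x$analytic_prob,
    x$mc_detect_fraction, x$n_reps))
  invisible(x)
}

#' Cohort-level snapshot detection simulation
#'
#' Runs [simulate_patient_window()] for every patient. The expected number of
#' detected patients is the sum of the exact per-patient probabilities (the
#' mean of the Poisson-binomial detection count); the Monte Carlo analogue is
#' the sum of per-patient detection fractions and is kept fractional —
#' rounding to a whole patient count happens only in table rendering.
#'
#' Each patient's random substream is derived from `seed` and the patient id
#' by a stable hash, so subsetting the cohort (e.g. to a stratum) does not
#' change any retained patient's draws.
#'
#' @inheritParams simulate_patient_window
#' @param cohort An [af_cohort()], already filtered to window-eligible
#'   patients by the caller (see [eligible_patients()]).
#' @param seed Master integer seed (required).
#' @return A `cohort_detection`: list with `outcomes` (per patient),
#'   `expected_detected`, `mc_detected`, `n_patients`, `window`, `n_reps`,
#'   `seed`.
#' @export
simulate_cohort <- function(cohort, window, n_reps = 5000L,
                            af_threshold_minutes = 5,
                            sub_threshold_policy = c("zero", "raw"),
                            seed) {
  stopifnot(inherits(cohort, "af_cohort"))
  sub_threshold_policy <- match.arg(sub_threshold_policy)
  outcomes <- lapply(unclass(cohort), function(r) {
    simulate_patient_window(
      r$series, window, n_reps = n_reps,
      af_threshold_minutes = af_threshold_minutes,
      sub_threshold_policy = sub_threshold_policy,
      seed = patient_substream_seed(seed, r$series$patient_id))
  })
  structure(
    list(outcomes = outcomes,
         expected_detected = sum(vapply(outcomes, `[[`, numeric(1L),
                                        "analytic_prob")),
         mc_detected = sum(vapply(outcomes, `[[`, numeric(1L),
                                  "mc_detect_fraction")),
         n_patients = length(outcomes), window = window,
         n_reps = as.integer(n_reps), seed = seed),
    class = "cohort_detection"
  )
}

#' @export
print.cohort_detection <- function(x, ...) {
  cat(sprintf(
    "<cohort_detection> %d patients | %d-day window | expected %.2f | MC %.2f detected\n",
    x$n_patients, x$window$length_days, x$expected_detected, x$mc_detected))
  invisible(x)
}
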