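test_that("daily_probability maps burden to the day fraction", {
  expect_equal(daily_probability(6), 0.25)     # 6 h of 24 = 25%
  expect_equal(daily_probability(24), 1)
  expect_equal(daily_probability(0), 0)
  # 3 minutes is below the 5-minute threshold
  expect_equal(daily_probability(3 / 60), 0)
  expect_equal(daily_probability(3 / 60, sub_threshold_policy = "raw"),
               (3 / 60) / 24)
  # exactly 5 minutes: excluded under "zero", kept under "raw"
  expect_equal(daily_probability(5 / 60), 0)
  expect_equal(daily_probability(5 / 60, sub_threshold_policy = "raw"),
               (5 / 60) / 24)
  expect_error(daily_probability(-1), "\\[0, 24\\]")
  expect_error(daily_probability(24.5), "\\[0, 24\\]")
})

test_that("analytic_window_prob equals the complement product", {
  s <- mk_series("A", 31:44, rep(6, 14), 44L)
  expect_equal(analytic_window_prob(s, monitoring_window(14)),
               1 - 0.75^14)

  expect_equal(analytic_window_prob(mk_series("A", followup = 400L),
                                    monitoring_window(365)), 0)

  s24 <- mk_series("A", 200L, 24, 400L)
  expect_equal(analytic_window_prob(s24, monitoring_window(365)), 1)

  # missing days are p = 0 trials: only recorded days matter
  sp <- mk_series("A", c(31L, 60L), c(12, 6), 400L)
  expect_equal(analytic_window_prob(sp, monitoring_window(56)),
               1 - 0.5 * 0.75)

  # blanked / out-of-window AF does not count
  pre <- mk_series("A", 10L, 12, 400L)
  expect_equal(analytic_window_prob(apply_blanking(pre),
                                    monitoring_window(365)), 0)
})

test_that("exhaustive enumeration matches the analytic form on tiny windows", {
  with_seed_local(99, {
    for (i in 1:30) {
      n_days <- sample(1:3, 1L)
      hours <- sample(c(0, 1, 3, 6, 12, 18, 24), n_days, replace = TRUE)
      s <- mk_series("A", seq(31L, length.out = n_days), hours,
                     followup = 40L)
      w <- monitoring_window(n_days)
      p <- window_probabilities(s, w)
      expect_equal(analytic_window_prob(s, w), enum_detect_prob(p),
                   tolerance = 1e-14)
    }
  })
})

test_that("Monte Carlo detection matches the analytic oracle within 4 SE", {
  s <- mk_series("A", 31:44, rep(6, 14), 44L)
  w <- monitoring_window(14)
  out <- simulate_patient_window(s, w, n_reps = 5000L, seed = 12L)
  p <- 1 - 0.75^14
  se <- sqrt(p * (1 - p) / 5000)
  expect_lt(abs(out$mc_detect_fraction - p), 4 * se)
  expect_equal(out$analytic_prob, p)

  # degenerate endpoints are exact for any seed
  z <- simulate_patient_window(mk_series("A", followup = 60L),
                               monitoring_window(14), seed = 1L)
  expect_equal(z$mc_detect_fraction, 0)
  o <- simulate_patient_window(mk_series("A", 40L, 24, 60L),
                               monitoring_window(14), seed = 1L)
  expect_equal(o$mc_detect_fraction, 1)

  # determinism in the seed
  a <- simulate_patient_window(s, w, seed = 77L)
  b <- simulate_patient_window(s, w, seed = 77L)
  expect_identical(a, b)
})

test_that("window extension, day permutation, and policy behave as the
           model implies", {
  with_seed_local(7, {
    for (i in 1:15) {
      followup <- 400L
      k <- sample(1:10, 1L)
      day <- sort(sample(31:395, k))
      hours <- runif(k, 0, 24)
      s <- mk_series("A", day, hours, followup)

      # monotone in window length
      probs <- vapply(c(14, 28, 56, 112, 365), function(L) {
        analytic_window_prob(s, monitoring_window(L))
      }, numeric(1L))
      expect_true(all(diff(probs) >= -1e-12))

      # order invariance: permuting burdens among window days
      w <- monitoring_window(365)
      inwin <- day >= 31L & day <= w$end_day
      perm_day <- day
      perm_day[inwin] <- sample(day[inwin])
      s2 <- mk_series("A", perm_day, hours, followup)
      expect_equal(analytic_window_prob(s2, w),
                   analytic_window_prob(s, w))

      # raw policy dominates zero policy
      expect_gte(
        analytic_window_prob(s, w, sub_threshold_policy = "raw"),
        analytic_window_prob(s, w, sub_threshold_policy = "zero"))
    }
  })
})

test_that("simulate_cohort sums probabilities and respects substreams", {
  # two identical patients with analytic probability 1/2 each
  half_day <- 12  # 12 h -> p = 0.5 on a single day
  coh <- af_cohort(list(
    mk_record("A", 31L, half_day, 60L),
    mk_record("B", 31L, half_day, 60L)))
  sim <- simulate_cohort(coh, monitoring_window(14), n_reps = 2000L,
                         seed = 5L)
  expect_equal(sim$expected_detected, 1.0)

  # MC count within the Poisson-binomial 4-sigma bound
  bound <- 4 * sqrt(2 * 0.5 * 0.5 / 2000)
  expect_lt(abs(sim$mc_detected - sim$expected_detected), bound)

  # identical seeds -> identical outcomes
  expect_identical(sim, simulate_cohort(coh, monitoring_window(14),
                                        n_reps = 2000L, seed = 5L))

  # subsetting the cohort leaves the retained patient's draws unchanged
  solo <- simulate_cohort(coh["B"], monitoring_window(14), n_reps = 2000L,
                          seed = 5L)
  expect_identical(solo$outcomes$B, sim$outcomes$B)

  # empty cohort
  e <- simulate_cohort(af_cohort(), monitoring_window(14), seed = 1L)
  expect_equal(e$expected_detected, 0)
  expect_equal(e$n_patients, 0L)
})

test_that("MC converges to the analytic value on random patients", {
  with_seed_local(31, {
    for (i in 1:12) {
      k <- sample(1:8, 1L)
      s <- mk_series("A", sort(sample(31:90, k)),
                     runif(k, 0.2, 23), followup = 100L)
      w <- monitoring_window(sample(c(14, 28, 60), 1L))
      out <- simulate_patient_window(s, w, n_reps = 5000L,
                                     seed = 1000L + i)
      p <- out$analytic_prob
      se <- sqrt(p * (1 - p) / 5000)
      if (se == 0) expect_equal(out$mc_detect_fraction, p)
      else expect_lt(abs(out$mc_detect_fraction - p), 4 * se)
    }
  })
})
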