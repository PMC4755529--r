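test_that("eligibility is follow-up reaching the window's last day", {
  w14 <- monitoring_window(14)          # days 31..44
  coh <- af_cohort(list(
    mk_record("in", 31L, 6, followup = 44L),
    mk_record("out", 31L, 6, followup = 43L)))
  expect_equal(names(eligible_patients(coh, w14)), "in")

  p <- synthetic_cohort_params(n_patients = 40L,
                               followup_days_range = c(395L, 395L),
                               full_followup_fraction = 1, seed = 3L)
  all_full <- generate_cohort(p)
  expect_length(eligible_patients(all_full, monitoring_window(365)), 40L)
})

test_that("device detection in window follows the strict AF-day rule", {
  w <- monitoring_window(365)
  expect_true(cied_detected_in_window(mk_record("A", 60L, 6, 400L), w))
  # AF only during blanking does not count for windows starting day 31
  expect_false(cied_detected_in_window(mk_record("A", 10L, 6, 400L), w))
  # exactly 5 minutes on every day is never an AF day
  expect_false(cied_detected_in_window(
    mk_record("A", 31:60, rep(5 / 60, 30), 400L), w))
})

test_that("median burden split puts ties in the high stratum", {
  coh <- af_cohort(list(
    mk_record_with_avg("a", 0.01),
    mk_record_with_avg("b", 0.05),
    mk_record_with_avg("c", 1.0)))
  sp <- median_burden_split(coh)
  expect_equal(sp$cutoff_hours, 0.05)
  low <- vapply(coh, sp$strata[[1L]]$predicate, logical(1L))
  expect_equal(names(coh)[low], "a")
  expect_equal(names(coh)[!low], c("b", "c"))

  same <- af_cohort(lapply(c("x", "y", "z"), mk_record_with_avg,
                           avg = 0.5))
  sp2 <- median_burden_split(same)
  expect_false(any(vapply(same, sp2$strata[[1L]]$predicate, logical(1L))))
})

test_that("strata partition any cohort", {
  coh <- generate_cohort(synthetic_cohort_params(n_patients = 60L,
                                                 seed = 9L))
  for (strata in list(stratify_chads2(),
                      median_burden_split(coh)$strata,
                      stratify_burden(5.5))) {
    member <- vapply(unclass(coh), function(r) {
      sum(vapply(strata, function(st) st$predicate(r), logical(1L)))
    }, numeric(1L))
    expect_true(all(member == 1L))  # each patient in exactly one stratum
  }
})

test_that("binomial_ci reproduces printed intervals with Clopper-Pearson", {
  # the published 126/254 interval [43.3, 55.9]% identifies the method:
  cp <- binomial_ci(126, 254, "clopper_pearson")
  expect_equal(round(unname(cp), 1), c(43.3, 55.9))
  wi <- binomial_ci(126, 254, "wilson")
  expect_false(all(round(unname(wi), 1) == c(43.3, 55.9)))

  expect_equal(binomial_ci(0, 10)[["lower"]], 0)
  expect_equal(binomial_ci(10, 10)[["upper"]], 100)
  expect_warning(na_ci <- binomial_ci(0, 0), "n = 0")
  expect_true(all(is.na(na_ci)))
  expect_error(binomial_ci(5, 3), "\\[0, n\\]")

  # wilson interval stays inside [0, 100] at the boundaries
  expect_gte(binomial_ci(0, 10, "wilson")[["lower"]], 0)
  expect_lte(binomial_ci(10, 10, "wilson")[["upper"]], 100)
})

test_that("detection_table rows are internally consistent", {
  coh <- generate_cohort(synthetic_cohort_params(n_patients = 80L,
                                                 seed = 21L))
  tab <- detection_table(coh, windows = c(14L, 56L, 365L),
                         strata = stratify_chads2(), n_reps = 400L,
                         seed = 21L)
  expect_s3_class(tab, "detection_table")
  expect_equal(nrow(tab), 6L)

  # detected <= CIED-detected <= eligible
  expect_true(all(tab$n_snapshot_detected <= tab$n_cied_detected))
  expect_true(all(tab$n_cied_detected <= tab$n_with_data))

  # the two percentages express the same count over different denominators
  ok <- tab$n_with_data > 0 & tab$n_cied_detected > 0
  expect_equal(tab$rate_total_pct[ok] * tab$n_with_data[ok],
               tab$rate_cied_pct[ok] * tab$n_cied_detected[ok])
  expect_equal(tab$rate_total_pct[ok] * tab$n_with_data[ok] / 100,
               tab$n_snapshot_detected[ok])

  # denominators shrink (weakly) as windows lengthen, per stratum
  for (st in unique(tab$stratum)) {
    expect_true(all(diff(tab$n_with_data[tab$stratum == st]) <= 0))
  }

  # rates bounded
  r <- c(tab$rate_total_pct, tab$rate_cied_pct)
  expect_true(all(is.na(r) | (r >= 0 & r <= 100)))
})

test_that("empty strata yield flagged rows, not dropped ones", {
  coh <- af_cohort(list(mk_record_with_avg("a", 0.5, chads2 = 2L)))
  tab <- detection_table(coh, windows = 14L, strata = stratify_chads2(),
                         n_reps = 50L, seed = 1L)
  expect_equal(nrow(tab), 2L)
  row1 <- tab[tab$stratum == "CHADS2=1", ]
  expect_equal(row1$n_with_data, 0L)
  expect_true(is.na(row1$rate_total_pct))
})

test_that("high-burden stratum dominates low-burden stratum in expectation", {
  coh <- generate_cohort(synthetic_cohort_params(n_patients = 120L,
                                                 seed = 33L))
  sp <- median_burden_split(coh)
  tab <- detection_table(coh, windows = c(28L, 365L), strata = sp$strata,
                         n_reps = 200L, seed = 33L)
  for (w in unique(tab$window_days)) {
    rows <- tab[tab$window_days == w, ]
    lo <- rows[grepl("^burden<", rows$stratum), ]
    hi <- rows[grepl("^burden>=", rows$stratum), ]
    if (lo$n_cied_detected > 0 && hi$n_cied_detected > 0) {
      expect_gte(hi$expected_detected / hi$n_cied_detected,
                 lo$expected_detected / lo$n_cied_detected)
    }
  }
})

test_that("strata_chisq flags a large rate difference", {
  expect_lt(strata_chisq(108, 119, 19, 135), 0.001)
  expect_gt(strata_chisq(50, 100, 52, 100), 0.5)
})
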