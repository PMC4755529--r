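---
title: "Methods: daily-snapshot AT/AF detection modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: daily-snapshot AT/AF detection modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afsnapshot)
```

## The model

Continuously monitoring cardiac implantable electronic devices (CIEDs)
aggregate atrial tachycardia / atrial fibrillation (AT/AF) into a daily
*burden* $b_d \in [0, 24]$: hours spent in AT/AF on day $d$ since implant.
Once-daily snapshot ECG monitoring is modelled as one instantaneous
Bernoulli trial per day with success probability equal to the fraction of
the day in AT/AF,

$$p_d = b_d / 24,$$

independent across days; a monitoring window $W$ detects the patient iff
at least one trial succeeds. `simulate_patient_window()` estimates this by
Monte Carlo (default 5,000 repetitions, the repetition count of the
original analysis); `analytic_window_prob()` computes it exactly as
$1 - \prod_{d \in W}(1 - p_d)$, in log space
(`1 - exp(sum(log1p(-p)))`) to avoid underflow on long windows, with an
early exit to exactly 1 when any $p_d = 1$. At cohort level the expected
detected count is the Poisson-binomial mean $\sum_i P_i$; the Monte Carlo
count is kept fractional and rounded half-up only for display, because
published counts are integers.

**Assumptions inherited from the model.** The snapshot is instantaneous
and uniformly timed (no recording duration, no time-of-day structure —
device data are aggregated per day), compliance is perfect, and the device
is treated as a gold standard (its >95% episode sensitivity/specificity is
not modelled). Day-to-day independence matters for the *variance* of the
detected count but not for a single window's detection probability, which
depends only on the multiset of daily burdens in the window.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `blanking_days` | 30 | days 1–30 post implant excluded (procedure-induced transient AF); windows start day 31 |
| `af_threshold_minutes` | 5 | a day is an AF day iff burden **strictly** exceeds 5 min; shorter episodes are typically atrial oversensing |
| `sub_threshold_policy` | `"zero"` | days at or below the threshold contribute $p_d = 0$; `"raw"` uses $b_d/24$ unchanged |
| `n_reps` | 5000 | Monte Carlo repetitions per patient-window |
| `windows` | 14, 28, 56, 112, 365 | window lengths in days |
| `ci_method` | `clopper_pearson` | 95% CI on detection rates |

The sub-threshold policy is a genuine ambiguity: the AT/AF *definition*
excludes days with ≤5 minutes, but whether such trend days were zeroed
before the original simulation is unstated. `"zero"` is the default
because it is the only reading consistent with the stated AT/AF
definition; `"raw"` is provided and always yields a probability at least
as large (a tested dominance property).

**Confidence intervals.** The source tables print 95% CIs without naming
a method. Both Clopper–Pearson (exact, via `qbeta`) and Wilson are
implemented; on every printed cell we checked (e.g. 126/254 →
[43.3, 55.9]%), Clopper–Pearson reproduces the printed interval to the
printed decimal and Wilson does not, so Clopper–Pearson is the default.
CIs are computed on the rounded Monte Carlo mean count treated as
binomial successes; Monte Carlo uncertainty in that count (standard error
$\le \sqrt{n/4 \cdot 1/5000}$ patients) is not propagated, matching the
apparent treatment in the published tables.

## The synthetic cohort generator

The study's patient-level data are proprietary, so `generate_cohort()`
emulates the *published summaries* of its 370-patient primary cohort. A
per-patient severity latent $z \sim N(0,1)$ drives both occurrence and
intensity:

* AF-day rate $q = \min(1, \exp(\log 0.005 + 2.2 z))$ — each follow-up
  day is an AF day independently with probability $q$;
* per-patient burden scale
  $m = \min(24, \exp(\log 0.9 + 1.5 z + 0.5 \varepsilon))$,
  $\varepsilon \sim N(0,1)$;
* AF-day burden $\sim$ log-normal$(\log m, 0.9)$, clipped to (5 min, 24 h];
* a 2% point mass of patients in near-permanent AF (24 h every day),
  reproducing the extreme right tail of the published histograms;
* follow-up: 68.6% of patients complete 395 days (254/370 with full-year
  data in the published denominators); the rest are censored uniformly on
  [44, 394];
* CHADS₂: score 1 with probability 0.25, else 2–6 with weights
  0.45/0.30/0.15/0.07/0.03 (cohort mean ≈ 2.4, published 2.3 ± 1.0);
* rejection sampling until ≥1 AF day falls after day 30, mirroring the
  inclusion criterion (new AT/AF during follow-up), capped at
  `max_rejections`.

The severity coupling (the shared $z$) is what lets one cohort satisfy
simultaneously a median average burden of ~0.044 h/day *and* ~20% of
patients above 1 h/day: the spread of log average burden must be ~3.7,
far more than either occurrence or intensity alone provides. Defaults
were fixed by a one-off grid simulation at large $n$ against the five
calibration targets (median average burden, fraction < 1 h/day, median
maximum daily burden, median % AF days, fraction < 10% AF days),
*accounting for the rejection truncation*, which roughly doubles the
pre-rejection medians; they have not been adjusted since.
`calibration_report()` recomputes the five statistics for any cohort.

**Design choice — follow-up mixture.** Drawing follow-up uniformly on
[44, 395] (the simplest reading of "a range") leaves essentially no
patient eligible for the 365-day window, which contradicts the published
denominators (254 of 370 with full-year data) and would make the
365-day stratified contrast vacuous. The generator therefore uses a
completed-follow-up point mass plus uniform censoring, with the point
mass at the published 254/370.

**What a green calibration test does not establish.** The generator
matches five marginal summaries; it does not claim distributional
equivalence to the real cohort. In particular AF days are placed
independently given $q$, while real AF clusters temporally — harmless for
single-window detection probabilities (order invariance is a tested
property) but wrong for, e.g., time-to-first-detection analyses. Detection
rates on synthetic cohorts are therefore compared to published rates only
directionally, never numerically.

## Numerical and reproducibility choices

* **Seeding.** Cohort simulation derives each patient's substream as
  `(hash(patient_id) + master_seed) mod (2^31 - 1)` with a polynomial
  rolling hash, so subsetting a cohort (stratification) never shifts a
  retained patient's draws, and stratum rows are consistent with
  whole-cohort rows. All seeds stay below $2^{31}$.
* **Median split ties.** Patients exactly at the median go to the high
  stratum ("greater than or equal to the median"); with all-equal burdens
  the low stratum is empty, which the reporting layer flags rather than
  drops.
* **Average burden span.** The burden used for stratification is averaged
  over each patient's full post-blanking follow-up (the span is exposed
  as an option); zero-burden days count in the denominator.
* **Degenerate inputs.** Empty windows/spans are errors; empty strata and
  empty eligible sets yield rows with $n = 0$ and `NA` rates; a window is
  truncated at `followup_days` when summarising but eligibility requires
  full coverage.
* **Monte Carlo versus 4-SE checks.** When the analytic probability is
  within ~$1/n_{reps}$ of 0 or 1, a ±4 SE band is narrower than one Monte
  Carlo count and no correct sampler can satisfy it; the test suite
  asserts the literal band where the normal approximation is valid
  ($np(1-p) \ge 9$) and the exact binomial central region of equal tail
  mass everywhere (computed on the rarer-outcome parametrization, where
  `qbinom` is numerically trustworthy).

## Limitations

Published headline rates (10/15/21/28/50% of eligible patients by window
length; 91% vs 14% for the 365-day high/low burden strata) were computed
on the non-public patient-level data and are not reproduction targets;
the package reproduces the *arithmetic* of the published tables exactly
and the *direction* of their contrasts on calibrated synthetic cohorts
(e.g. 84.9% vs 12.1% at seed 1). No symptom-triggered recordings,
imperfect single-lead sensitivity, intra-day episode timing, or stroke
outcomes are modelled.
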