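# afsnapshot

Simulation of once-daily **snapshot ECG monitoring** for detecting
paroxysmal atrial tachycardia / atrial fibrillation (AT/AF), aimed at
biostatisticians and screening-strategy researchers who work with daily
AT/AF *burden* series from continuously monitoring cardiac implantable
electronic devices (CIEDs).

Smartphone and hand-held single-lead ECGs can record a brief rhythm strip
once a day. How often does such intermittent screening actually catch a
patient whose paroxysmal AT/AF is documented by their implanted device?
The model: on day *d* the patient spends *b\_d* hours (of 24) in AT/AF, and
an instantaneous daily snapshot succeeds with probability

> p\_d = b\_d / 24  (e.g. 6 h of AT/AF → 25%),

with days independent. A monitoring window *W* (14, 28, 56, 112 or 365
consecutive days, starting day 31 post implant after a 30-day blanking
period) detects the patient iff at least one daily trial succeeds, so

> P(detect in W) = 1 − ∏\_{d ∈ W} (1 − p\_d).

The package computes this both by Monte Carlo (5,000 repetitions by
default, as in the source analysis) and by the exact closed form, which
serves as the oracle for the Monte Carlo route. Days with burden ≤ 5
minutes are treated as non-AF days (probability 0) by default, matching
the >5-minute AT/AF definition used to exclude atrial oversensing; a
`"raw"` policy is available. Cohort-level expected detection counts are
Poisson-binomial means (sums of per-patient probabilities).

Because the underlying patient-level device data are proprietary, the
package ships a **synthetic cohort generator** whose defaults are
calibrated (once) to the published cohort summaries — median average
burden 0.044 h/day, ~80% of patients under 1 h/day, median maximum daily
burden 5.5 h, median 1.6% of days with AT/AF — plus a **reporting layer**
(eligibility denominators, device-detection denominators, CHADS₂ and
burden stratification, detection rates with exact Clopper–Pearson 95%
CIs) and a reproducible **pipeline/CLI**.

## Worked example

```r
library(afsnapshot)

# one patient, 6 h of AT/AF on each of the 14 window days
s <- burden_series("P1", day = 31:44, hours = rep(6, 14),
                   followup_days = 44L)
analytic_window_prob(s, monitoring_window(14))
#> [1] 0.9821821                  # = 1 - 0.75^14
simulate_patient_window(s, monitoring_window(14), n_reps = 5000, seed = 7)
#> <detection_outcome> patient P1 | 14-day window | analytic 0.9822 | MC 0.9850 (5000 reps)

# calibrated synthetic cohort of 370 patients
cohort <- generate_cohort(synthetic_cohort_params(seed = 1))
calibration_report(cohort)
#> <calibration_report> 370 patients
#>   median average burden     0.0277 h/day
#>   median max daily burden   4.13 h
#>   median % AF days          1.37%
#>   patients < 1 h/day avg    86.5%
#>   patients < 10% AF days    84.6%

# stratify at the cohort-median average burden; 365-day window
sp <- median_burden_split(cohort)
detection_table(cohort, windows = 365, strata = sp$strata, seed = 1)
#>            stratum window   n cied snapshot          of total          of CIED+
#>   burden<0.0276799    365 132  132       16  12.1 [7.1-18.9]%  12.1 [7.1-18.9]%
#>  burden>=0.0276799    365 119  119      101 84.9 [77.2-90.8]% 84.9 [77.2-90.8]%
```

Reading the table: of the 119 patients at or above the median burden with
a full year of device data, a year of daily snapshots detects a Monte
Carlo mean of 101 (84.9%, 95% CI 77.2–90.8), versus 12.1% below the
median — the strong burden dependence of snapshot sensitivity. `n` is the
per-window eligibility denominator (device data covering the window);
`cied` counts patients whose device recorded an AF day (>5 min) inside
the window; rates are shown as % of both denominators.

## Command line

```sh
Rscript inst/cli/afsnapshot.R run --seed 11 --strata median_burden \
    --windows 14,28,56,112,365 --reps 5000 --out out/
```

Subcommands `generate`, `simulate`, `report`, `run`; configuration via
`--config cfg.json` (or `.yaml`) with flags overriding; every run writes
a `manifest.json` from which it can be re-executed byte-identically
(`run_from_manifest()`).

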