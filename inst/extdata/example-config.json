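{
  "generator": { "n_patients": 370 },
  "windows": [14, 28, 56, 112, 365],
  "n_reps": 5000,
  "seed": 11,
  "blanking_days": 30,
  "af_threshold_minutes": 5,
  "sub_threshold_policy": "zero",
  "ci_method": "clopper_pearson",
  "strata": "median_burden",
  "output_dir": "afsnapshot-out"
}
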