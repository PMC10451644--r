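{
  "pipeline": {
    "z_threshold": 4.5,
    "utm_zone": "13N",
    "day_timezone": "America/Denver",
    "min_fixes_per_day": 2
  },
  "scenario": {
    "n_animal": 6,
    "n_indoor": 5,
    "n_outdoor": 6,
    "days": 7,
    "gps_interval_min": 15,
    "motion_interval_min": 1,
    "fix_dropout_prob": 0.1,
    "r95_outdoor_m": 15,
    "r95_indoor_m": 40,
    "outlier_prob": 0.005
  },
  "seed": 1
}
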