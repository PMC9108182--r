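[
  {
    "label": "day2",
    "description": "EPOS independent-gait model, predictors assessed around day 2 post-stroke",
    "link": "logit",
    "intercept": -0.982,
    "terms": [
      {"name": "tct", "coefficient": 2.691},
      {"name": "mi", "coefficient": 2.083}
    ]
  },
  {
    "label": "day9",
    "description": "EPOS independent-gait model, predictors reassessed around day 9 post-stroke",
    "link": "logit",
    "intercept": -2.226,
    "terms": [
      {"name": "tct", "coefficient": 3.629},
      {"name": "mi", "coefficient": 1.854}
    ]
  }
]
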