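{
  "units": "events per person-year",
  "chads2_stroke_rates": {
    "0": 0.019, "1": 0.028, "2": 0.040, "3": 0.059,
    "4": 0.085, "5": 0.125, "6": 0.182
  },
  "hemorrhages_bleed_rates": {
    "0": 0.019, "1": 0.025, "2": 0.053, "3": 0.084,
    "4": 0.104, "5+": 0.123
  },
  "baseline_bleed_table": {
    "age_bands": ["<60", "60-69", "70-79", ">=80"],
    "no_prior_bleed": [0.0012, 0.005, 0.012, 0.025],
    "prior_bleed": [0.010, 0.015, 0.030, 0.060]
  },
  "aspirin_stroke_rrr": 0.21,
  "warfarin_stroke_rrr": 0.67,
  "aspirin_bleed_rr": 2,
  "default_horizon_years": 5
}
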