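{
  "description": "Calibration moments of the provincial e-consult feasibility evaluation reference case (2022 CAD, healthcare-payer perspective, economic window May 2022 to November 2023).",
  "benefit": {
    "label": "In-person referral costs avoided",
    "mean": 389439,
    "ci95": [331417, 451226]
  },
  "cost": {
    "label": "Implementation and ongoing costs",
    "mean": 145020,
    "ci95": [100014, 203922]
  },
  "avoidance": {
    "label": "Proportion of consults avoiding an in-person referral",
    "numerator": 511,
    "denominator": 608
  },
  "consults_completed": 6072,
  "n_draws": 1000
}
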