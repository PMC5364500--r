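{
  "schema_version": "1.0",
  "model_id": "SCORE-low",
  "sex": "male",
  "family": "weibull_score",
  "native_horizon": 10,
  "thresholds": [0.01, 0.05],
  "categories": ["low", "intermediate", "high"],
  "units": {
    "total_cholesterol": "mmol/L"
  },
  "causes": {
    "chd": {
      "alpha": -22.1,
      "p": 4.7,
      "beta_tc": 0.24,
      "beta_sbp": 0.018,
      "beta_smoker": 0.7
    },
    "non_chd": {
      "alpha": -26.7,
      "p": 5.6,
      "beta_tc": 0.02,
      "beta_sbp": 0.022,
      "beta_smoker": 0.4
    }
  },
  "region": "low",
  "notes": "synthetic placeholder Weibull parameters for testing; supply published SCORE parameters for real use"
}
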