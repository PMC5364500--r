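{
  "schema_version": "1.0",
  "model_id": "SCORE-high",
  "sex": "female",
  "family": "weibull_score",
  "native_horizon": 10,
  "thresholds": [0.01, 0.05],
  "categories": ["low", "intermediate", "high"],
  "units": {
    "total_cholesterol": "mmol/L"
  },
  "causes": {
    "chd": {
      "alpha": -28.2,
      "p": 6.2,
      "beta_tc": 0.2,
      "beta_sbp": 0.018,
      "beta_smoker": 0.65
    },
    "non_chd": {
      "alpha": -30.5,
      "p": 6.5,
      "beta_tc": 0.02,
      "beta_sbp": 0.022,
      "beta_smoker": 0.4
    }
  },
  "region": "high",
  "notes": "synthetic placeholder Weibull parameters for testing; supply published SCORE parameters for real use"
}
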