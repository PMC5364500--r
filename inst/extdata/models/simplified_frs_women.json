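{
  "schema_version": "1.0",
  "model_id": "simplified-FRS",
  "sex": "female",
  "family": "cox_form",
  "native_horizon": 5,
  "baseline_survival": {
    "5": 0.993261
  },
  "mean_lp": 30.74361,
  "terms": [
    {
      "covariate": "age",
      "transform": "log",
      "coefficient": 4.0899
    },
    {
      "covariate": "bmi",
      "transform": "log",
      "coefficient": -0.6864
    },
    {
      "covariate": "sbp",
      "transform": "log",
      "coefficient": 3.4689,
      "condition": "bp_untreated"
    },
    {
      "covariate": "sbp",
      "transform": "log",
      "coefficient": 3.4942,
      "condition": "bp_treated"
    },
    {
      "covariate": "current_smoker",
      "transform": "identity",
      "coefficient": -3.0307
    },
    {
      "covariate": "diabetes",
      "transform": "identity",
      "coefficient": 0.7639
    }
  ],
  "thresholds": [0.1, 0.2],
  "categories": ["low", "intermediate", "high"],
  "units": []
}
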