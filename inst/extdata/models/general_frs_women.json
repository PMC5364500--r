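{
  "schema_version": "1.0",
  "model_id": "general-FRS",
  "sex": "female",
  "family": "cox_form",
  "native_horizon": 5,
  "baseline_survival": {
    "5": 0.9934118
  },
  "mean_lp": 27.33517,
  "terms": [
    {
      "covariate": "age",
      "transform": "log",
      "coefficient": 4.4913
    },
    {
      "covariate": "total_cholesterol",
      "transform": "log",
      "coefficient": -0.9884
    },
    {
      "covariate": "hdl",
      "transform": "log",
      "coefficient": -0.4972
    },
    {
      "covariate": "sbp",
      "transform": "log",
      "coefficient": 3.4325,
      "condition": "bp_untreated"
    },
    {
      "covariate": "sbp",
      "transform": "log",
      "coefficient": 3.4539,
      "condition": "bp_treated"
    },
    {
      "covariate": "current_smoker",
      "transform": "identity",
      "coefficient": -3.0644
    },
    {
      "covariate": "diabetes",
      "transform": "identity",
      "coefficient": 0.7695
    }
  ],
  "thresholds": [0.1, 0.2],
  "categories": ["low", "intermediate", "high"],
  "units": {
    "total_cholesterol": "mg/dL",
    "hdl": "mg/dL"
  }
}
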