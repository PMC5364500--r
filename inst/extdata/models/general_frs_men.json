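{
  "schema_version": "1.0",
  "model_id": "general-FRS",
  "sex": "male",
  "family": "cox_form",
  "native_horizon": 5,
  "baseline_survival": {
    "5": 0.9914698
  },
  "mean_lp": 32.45731,
  "terms": [
    {
      "covariate": "age",
      "transform": "log",
      "coefficient": 5.1215
    },
    {
      "covariate": "total_cholesterol",
      "transform": "log",
      "coefficient": -0.2727
    },
    {
      "covariate": "hdl",
      "transform": "log",
      "coefficient": -0.4596
    },
    {
      "covariate": "sbp",
      "transform": "log",
      "coefficient": 3.2282,
      "condition": "bp_untreated"
    },
    {
      "covariate": "sbp",
      "transform": "log",
      "coefficient": 3.3088,
      "condition": "bp_treated"
    },
    {
      "covariate": "current_smoker",
      "transform": "identity",
      "coefficient": -0.4882
    },
    {
      "covariate": "diabetes",
      "transform": "identity",
      "coefficient": 0.6518
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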