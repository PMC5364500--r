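{
  "schema_version": "1.0",
  "model_id": "simplified-FRS",
  "sex": "male",
  "family": "cox_form",
  "native_horizon": 5,
  "baseline_survival": {
    "5": 0.9914576
  },
  "mean_lp": 27.67513,
  "terms": [
    {
      "covariate": "age",
      "transform": "log",
      "coefficient": 4.6867
    },
    {
      "covariate": "bmi",
      "transform": "log",
      "coefficient": -2.2998
    },
    {
      "covariate": "sbp",
      "transform": "log",
      "coefficient": 3.4576,
      "condition": "bp_untreated"
    },
    {
      "covariate": "sbp",
      "transform": "log",
      "coefficient": 3.5505,
      "condition": "bp_treated"
    },
    {
      "covariate": "current_smoker",
      "transform": "identity",
      "coefficient": -0.5276
    },
    {
      "covariate": "diabetes",
      "transform": "identity",
      "coefficient": 0.7303
    }
  ],
  "thresholds": [0.1, 0.2],
  "categories": ["low", "intermediate", "high"],
  "units": []
}
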