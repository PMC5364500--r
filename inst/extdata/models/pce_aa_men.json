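{
  "schema_version": "1.0",
  "model_id": "PCE-AA",
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
      "coefficient": 3.3088,
      "condition": "bp_treated"
    },
    {
      "covariate": "sbp",
      "transform": "log",
      "coefficient": 3.2282,
      "condition": "bp_untreated"
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
  "thresholds": [0.075, 0.1, 0.2],
  "categories": ["<7.5%", "7.5-9.9%", "10.0-19.9%", ">=20%"],
  "units": {
    "total_cholesterol": "mg/dL",
    "hdl": "mg/dL"
  },
  "notes": "transcription_note: published PCE-AA men column is identical to the general-FRS men column (likely typesetting artifact); transcribed as printed"
}
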