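{
  "schema_version": "1.0",
  "model_id": "PCE-white",
  "sex": "male",
  "family": "cox_form",
  "native_horizon": 5,
  "baseline_survival": {
    "5": 0.9915944
  },
  "mean_lp": -19.22938,
  "terms": [
    {
      "covariate": "age",
      "transform": "log",
      "coefficient": -7.6938
    },
    {
      "covariate": "total_cholesterol",
      "transform": "log",
      "coefficient": -20.8736
    },
    {
      "covariate": {},
      "transform": "product",
      "coefficient": 5.0969,
      "factors": [
        {
          "covariate": "age",
          "transform": "log"
        },
        {
          "covariate": "total_cholesterol",
          "transform": "log"
        }
      ]
    },
    {
      "covariate": "hdl",
      "transform": "log",
      "coefficient": 14.2871
    },
    {
      "covariate": {},
      "transform": "product",
      "coefficient": -3.6424,
      "factors": [
        {
          "covariate": "age",
          "transform": "log"
        },
        {
          "covariate": "hdl",
          "transform": "log"
        }
      ]
    },
    {
      "covariate": "sbp",
      "transform": "log",
      "coefficient": 3.3128,
      "condition": "bp_treated"
    },
    {
      "covariate": "sbp",
      "transform": "log",
      "coefficient": 3.2339,
      "condition": "bp_untreated"
    },
    {
      "covariate": "current_smoker",
      "transform": "identity",
      "coefficient": -2.9244
    },
    {
      "covariate": {},
      "transform": "product",
      "coefficient": 0.6021,
      "factors": [
        {
          "covariate": "age",
          "transform": "log"
        },
        {
          "covariate": "current_smoker",
          "transform": "identity"
        }
      ]
    },
    {
      "covariate": "diabetes",
      "transform": "identity",
      "coefficient": 0.6608
    }
  ],
  "thresholds": [0.075, 0.1, 0.2],
  "categories": ["<7.5%", "7.5-9.9%", "10.0-19.9%", ">=20%"],
  "units": {
    "total_cholesterol": "mg/dL",
    "hdl": "mg/dL"
  }
}
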