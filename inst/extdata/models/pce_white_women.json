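{
  "schema_version": "1.0",
  "model_id": "PCE-white",
  "sex": "female",
  "family": "cox_form",
  "native_horizon": 5,
  "baseline_survival": {
    "5": 0.9934143
  },
  "mean_lp": -51.67933,
  "terms": [
    {
      "covariate": "age",
      "transform": "log",
      "coefficient": -22.3973
    },
    {
      "covariate": {},
      "transform": "product",
      "coefficient": 1.7899,
      "factors": [
        {
          "covariate": "age",
          "transform": "log"
        },
        {
          "covariate": "age",
          "transform": "log"
        }
      ]
    },
    {
      "covariate": "total_cholesterol",
      "transform": "log",
      "coefficient": 15.0642
    },
    {
      "covariate": {},
      "transform": "product",
      "coefficient": 3.5038,
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
      "coefficient": 5.1555
    },
    {
      "covariate": {},
      "transform": "product",
      "coefficient": -1.4068,
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
      "coefficient": 3.4666,
      "condition": "bp_treated"
    },
    {
      "covariate": "sbp",
      "transform": "log",
      "coefficient": 3.4459,
      "condition": "bp_untreated"
    },
    {
      "covariate": "current_smoker",
      "transform": "identity",
      "coefficient": 17.8261
    },
    {
      "covariate": {},
      "transform": "product",
      "coefficient": -5.6228,
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
      "coefficient": 0.7707
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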