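{
  "schema_version": "1.0",
  "model_id": "PCE-AA",
  "sex": "female",
  "family": "cox_form",
  "native_horizon": 5,
  "baseline_survival": {
    "5": 0.9931984
  },
  "mean_lp": -162.2403,
  "terms": [
    {
      "covariate": "age",
      "transform": "log",
      "coefficient": -42.607
    },
    {
      "covariate": "total_cholesterol",
      "transform": "log",
      "coefficient": -0.9533
    },
    {
      "covariate": "hdl",
      "transform": "log",
      "coefficient": 0.5844
    },
    {
      "covariate": {},
      "transform": "product",
      "coefficient": -0.2728,
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
      "coefficient": -34.6531,
      "condition": "bp_treated"
    },
    {
      "covariate": {},
      "transform": "product",
      "coefficient": 9.4585,
      "condition": "bp_treated",
      "factors": [
        {
          "covariate": "age",
          "transform": "log"
        },
        {
          "covariate": "sbp",
          "transform": "log"
        }
      ]
    },
    {
      "covariate": "sbp",
      "transform": "log",
      "coefficient": -36.7922,
      "condition": "bp_untreated"
    },
    {
      "covariate": {},
      "transform": "product",
      "coefficient": 9.9831,
      "condition": "bp_untreated",
      "factors": [
        {
          "covariate": "age",
          "transform": "log"
        },
        {
          "covariate": "sbp",
          "transform": "log"
        }
      ]
    },
    {
      "covariate": "current_smoker",
      "transform": "identity",
      "coefficient": -3.874
    },
    {
      "covariate": "diabetes",
      "transform": "identity",
      "coefficient": 0.7789
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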