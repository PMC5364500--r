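{
  "schema_version": "1.0",
  "model_id": "CN-ICVD",
  "sex": "male",
  "family": "cox_form",
  "native_horizon": 5,
  "baseline_survival": {
    "5": 0.9918239
  },
  "mean_lp": 4.400718,
  "terms": [
    {
      "covariate": "age",
      "transform": "identity",
      "coefficient": 0.0844
    },
    {
      "covariate": "sbp",
      "transform": "bands",
      "bands": [
        {
          "lo": {},
          "hi": 120,
          "coefficient": 0.0186
        },
        {
          "lo": 120,
          "hi": 130,
          "coefficient": 0
        },
        {
          "lo": 130,
          "hi": 140,
          "coefficient": 0.7914
        },
        {
          "lo": 140,
          "hi": 160,
          "coefficient": 1.6302
        },
        {
          "lo": 160,
          "hi": 180,
          "coefficient": 1.9703
        },
        {
          "lo": 180,
          "hi": {},
          "coefficient": 1.8387
        }
      ]
    },
    {
      "covariate": "bmi",
      "transform": "bands",
      "bands": [
        {
          "lo": {},
          "hi": 24,
          "coefficient": 0
        },
        {
          "lo": 24,
          "hi": {},
          "coefficient": -0.3101
        }
      ]
    },
    {
      "covariate": "total_cholesterol",
      "transform": "bands",
      "bands": [
        {
          "lo": {},
          "hi": 3.62,
          "coefficient": 0
        },
        {
          "lo": 3.62,
          "hi": 5.17,
          "coefficient": -0.0059
        },
        {
          "lo": 5.17,
          "hi": {},
          "coefficient": -0.268
        }
      ]
    },
    {
      "covariate": "current_smoker",
      "transform": "identity",
      "coefficient": -0.4775
    },
    {
      "covariate": "diabetes",
      "transform": "identity",
      "coefficient": 0.7168
    }
  ],
  "thresholds": [0.05, 0.1],
  "categories": ["low", "intermediate", "high"],
  "units": {
    "total_cholesterol": "mmol/L"
  }
}
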