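{
  "standard_id": "figueras",
  "family": "customized",
  "efw_formula_id": "hadlock4",
  "parameters": {
    "base_term_weight_g": 3310,
    "proportionality": {
      "ga_ref": 280,
      "b1": 0.0065,
      "b2": -5.32e-05
    },
    "dispersion": {
      "transform": "identity",
      "cv": 0.125904584522388
    },
    "scale": 0.937241426294624,
    "covariate_effects": {
      "maternal_height": {
        "type": "linear",
        "ref": 163,
        "per_unit": 7.5
      },
      "maternal_bmi": {
        "type": "linear",
        "ref": 23.2,
        "per_unit": 10
      },
      "parity": {
        "type": "categorical",
        "ref": "0",
        "effects": {
          "1": 110,
          "2+": 150
        }
      },
      "sex": {
        "type": "categorical",
        "ref": "female",
        "effects": {
          "male": 126
        }
      }
    }
  },
  "customization_covariates": ["maternal_height", "maternal_bmi", "parity", "sex"],
  "citation": "Customized standard (maternal height, BMI, parity, fetal sex); effect sizes are representative, location/dispersion are calibration fits.",
  "label": "Figueras-type customized",
  "version": "calibrated-1"
}
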