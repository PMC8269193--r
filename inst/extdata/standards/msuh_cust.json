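{
  "standard_id": "msuh_cust",
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
      "cv": 0.11393447363464
    },
    "scale": 0.956898762114765,
    "covariate_effects": {
      "maternal_height": {
        "type": "linear",
        "ref": 163,
        "per_unit": 7.8
      },
      "paternal_height": {
        "type": "linear",
        "ref": 176,
        "per_unit": 3
      },
      "maternal_bmi": {
        "type": "linear",
        "ref": 23.2,
        "per_unit": 11
      },
      "maternal_age": {
        "type": "linear",
        "ref": 33.3,
        "per_unit": -1.5
      },
      "parity": {
        "type": "categorical",
        "ref": "0",
        "effects": {
          "1": 105,
          "2+": 140
        }
      },
      "sex": {
        "type": "categorical",
        "ref": "female",
        "effects": {
          "male": 130
        }
      }
    }
  },
  "customization_covariates": ["maternal_height", "paternal_height", "maternal_bmi", "maternal_age", "parity", "sex"],
  "citation": "Gardosi-methodology customized standard (parity, age, BMI, maternal and paternal height, fetal sex); effect sizes are representative, location/dispersion are calibration fits.",
  "label": "Customized MSUH-type",
  "version": "calibrated-1"
}
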