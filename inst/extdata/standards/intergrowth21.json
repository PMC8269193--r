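{
  "standard_id": "intergrowth21",
  "family": "zscore_curve",
  "efw_formula_id": "stirnemann",
  "parameters": {
    "median_curve": {
      "w_ref_g": 3310,
      "ga_ref": 280,
      "b1": 0.0065,
      "b2": -5.32e-05,
      "scale_log": -0.0359875859715114
    },
    "dispersion": {
      "transform": "log",
      "sigma_log": 0.125724071076001
    }
  },
  "customization_covariates": [],
  "citation": "International standard using the Stirnemann HC/AC EFW model; location/dispersion are calibration fits.",
  "label": "INTERGROWTH-21st-type",
  "version": "calibrated-1"
}
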