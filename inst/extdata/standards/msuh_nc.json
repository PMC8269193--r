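{
  "standard_id": "msuh_nc",
  "family": "zscore_curve",
  "efw_formula_id": "hadlock4",
  "parameters": {
    "median_curve": {
      "w_ref_g": 3310,
      "ga_ref": 280,
      "b1": 0.0065,
      "b2": -5.32e-05,
      "scale_log": -0.00693810402011769
    },
    "dispersion": {
      "transform": "log",
      "sigma_log": 0.109550227593331
    }
  },
  "customization_covariates": [],
  "citation": "Population z-score curve standard (Hadlock-type chart with GA-varying CV); location/dispersion are calibration fits.",
  "label": "Non-customized MSUH-type",
  "version": "calibrated-1"
}
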