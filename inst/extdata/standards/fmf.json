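{
  "standard_id": "fmf",
  "family": "zscore_curve",
  "efw_formula_id": "hadlock3",
  "parameters": {
    "median_curve": {
      "w_ref_g": 3310,
      "ga_ref": 280,
      "b1": 0.0065,
      "b2": -5.32e-05,
      "scale_log": 0.0273585155123202
    },
    "dispersion": {
      "transform": "log",
      "sigma_log": 0.0913009464591144
    }
  },
  "customization_covariates": [],
  "citation": "Local standard using the Hadlock HC/AC/FL EFW model; location/dispersion are calibration fits.",
  "label": "FMF-type",
  "version": "calibrated-1"
}
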