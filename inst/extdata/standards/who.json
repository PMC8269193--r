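{
  "standard_id": "who",
  "family": "quantile_grid",
  "efw_formula_id": "hadlock4",
  "parameters": {
    "ga_grid": [238, 245, 252, 259],
    "levels": [5, 10, 25, 50, 75, 90, 95],
    "weights": [
      [1869.78557744094, 1966.63930646103, 2139.80227551466, 2350.13747112916, 2581.1478922168, 2808.41846039591, 2953.89278847928],
      [2013.74980731009, 2118.06079382353, 2304.55645395278, 2531.08641800295, 2779.88349749938, 3024.65277393392, 3181.3279048585],
      [2157.52074628855, 2269.27897794752, 2469.08942826314, 2711.79241714492, 2978.35227412466, 3240.59676450003, 3408.45765971659],
      [2299.53599165118, 2418.65052461925, 2631.61316833853, 2890.29168124508, 3174.39740125205, 3453.903702764, 3632.81376460478]
    ],
    "source_curve": {
      "w_ref_g": 3310,
      "ga_ref": 280,
      "b1": 0.0065,
      "b2": -5.32e-05,
      "scale_log": 0.0243704354089686
    }
  },
  "customization_covariates": [],
  "citation": "WHO-chart-type standard: weekly weights at the 5th-95th percentile levels, percentile by probit interpolation; grid values are calibration fits.",
  "label": "WHO-type quantile grid",
  "version": "calibrated-1"
}
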