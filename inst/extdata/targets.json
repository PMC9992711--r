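{
  "comment": "Published macroscopic values targeted by the parameter-recovery pipeline. 'sem' is the printed SEM; the tolerance rule is max(3*sem, rel_tol*value). slowdown_ratio entries divide the numerator preset's metric by the denominator's (presets given as 'num/den').",
  "targets": [
    { "id": "t1", "preset": "wt_gtp", "metric": "tau1_on",
      "value": 0.22, "sem": 0.02, "rel_tol": 0.2, "units": "s" },
    { "id": "t2", "preset": "wt_gtp", "metric": "tau2_on",
      "value": 1.92, "sem": 0.30, "rel_tol": 0.2, "units": "s" },
    { "id": "t3", "preset": "wt_gtp", "metric": "pct_step1_on",
      "value": 50, "sem": null, "rel_tol": 0.2, "units": "%" },
    { "id": "t4", "preset": "wt_gdpbs/wt_gtp", "metric": "slowdown_ratio",
      "numerator_metric": "tau2_on",
      "value": 5, "sem": null, "rel_tol": 0.3, "units": "fold" },
    { "id": "t5", "preset": "rgbg_gtp", "metric": "tau1_on",
      "value": 0.23, "sem": 0.04, "rel_tol": 0.2, "units": "s" },
    { "id": "t6", "preset": "gabg_gtp", "metric": "tau1_on",
      "value": 1.45, "sem": 0.19, "rel_tol": 0.2, "units": "s" },
    { "id": "t7", "preset": "gabg_gdpbs", "metric": "tau1_on",
      "value": 10.38, "sem": 1.46, "rel_tol": 0.2, "units": "s" },
    { "id": "t8", "preset": "rgbg_gtp", "metric": "tau1_off",
      "value": 0.53, "sem": 0.04, "rel_tol": 0.2, "units": "s" },
    { "id": "t9", "preset": "gabg_gtp", "metric": "tau1_off",
      "value": 21.37, "sem": 1.34, "rel_tol": 0.2, "units": "s" },
    { "id": "t10", "preset": "oxom_dose", "metric": "ec50",
      "value": 0.112, "sem": null, "rel_tol": 0.25, "units": "uM" }
  ]
}
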