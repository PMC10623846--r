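{
  "note": "2x2 contingency tables printed in the study's Results, row-wise [a, b, c, d] with columns positive/negative. printed_p is the p-value as printed (strings preserve '<' bounds).",
  "tables": {
    "pooled_pyro_vaf_0325": {
      "counts": [152, 118, 65, 110],
      "rows": ["VAF >= 0.325", "VAF < 0.325"],
      "assay": "PYRO",
      "printed_p": "<0.0001"
    },
    "gbm_array_vs_pyro_cut10": {
      "counts": [79, 88, 101, 200],
      "rows": ["array", "pyrosequencing (10.0% cutoff)"],
      "printed_p": "0.004"
    },
    "gbm_pyro_cut728_vs_array": {
      "counts": [118, 183, 79, 88],
      "rows": ["pyrosequencing (7.28% cutoff)", "array"],
      "printed_p": "0.097"
    },
    "gbm_lowvaf_pyro_vs_array": {
      "counts": [3, 11, 35, 30],
      "rows": ["pyrosequencing VAF < 0.115 (7.28% cutoff)", "array VAF < 0.325"],
      "printed_p": "0.039"
    },
    "gbm_highvaf_pyro_vs_array": {
      "counts": [115, 172, 44, 58],
      "rows": ["pyrosequencing VAF >= 0.115 (7.28% cutoff)", "array VAF >= 0.325"],
      "printed_p": "0.639"
    }
  },
  "fn_rate_inputs": {
    "frac_below_cutoff_finder": 0.043,
    "frac_below_regression": 0.126,
    "gbm_methylation_prevalence": 0.35,
    "printed_range_pct": [1.5, 4.4]
  }
}
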