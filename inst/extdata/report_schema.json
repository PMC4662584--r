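{
  "required": ["package", "version", "seed", "parameters", "input",
               "diversity", "kruskal_wallis", "discriminant_analysis",
               "network", "resampling_ci"],
  "sections": {
    "parameters": ["L_sample", "resampling_L", "resampling_N", "ci_level",
                   "f_enter", "f_remove", "correlation_level", "p_threshold"],
    "input": ["n_taxa", "n_samples", "min_depth", "max_depth", "group_sizes"],
    "kruskal_wallis": ["n_tested", "n_significant"],
    "discriminant_analysis": ["predictors", "wilks_lambda", "chisq", "df",
                              "p", "loo_accuracy"],
    "network": ["edge_count", "n_positive", "n_negative"],
    "resampling_ci": ["n_taxa", "n_flagged", "flagged_taxa"]
  }
}
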