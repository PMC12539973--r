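{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "shaperate analysis report",
  "type": "object",
  "required": ["metadata", "table1", "region_rates", "correlations", "allometry", "branch_rates"],
  "properties": {
    "metadata": {
      "type": "object",
      "required": ["package", "version", "seed", "n_sims", "n_perm", "mode", "estimator", "focal", "reference", "regions", "sexes"]
    },
    "table1": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["sex", "region", "pv_ratio", "pv_p", "distance_ratio", "distance_p", "excess_ratio", "excess_p", "bm_rate_ratio", "bm_rate_p"]
      }
    },
    "region_rates": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["sex", "region", "sigma2_mult", "max_min_ratio", "p_value"]
      }
    },
    "correlations": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["sex", "region_a", "region_b", "stratum", "n", "r", "p_value", "stars"]
      }
    },
    "allometry": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["region", "sex", "lambda", "r_squared", "p_value"]
      }
    },
    "branch_rates": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["sex", "region", "edge", "parent", "child", "child_label", "terminal", "clade", "d_obs", "d_exp", "R", "classification"]
      }
    }
  }
}
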