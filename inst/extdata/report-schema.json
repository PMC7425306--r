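{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "connectolesion pipeline report",
  "type": "object",
  "required": ["config", "cohort", "q50"],
  "properties": {
    "config": {
      "type": "object",
      "required": ["seed", "n_nulls", "n_perm", "local_kappa", "kappas"]
    },
    "cohort": {
      "type": "object",
      "required": ["n_patients", "n_controls", "seed"]
    },
    "q50": {
      "type": "object",
      "required": ["lambda2", "p_omnibus", "group_means", "posthoc"]
    },
    "mtpc": {
      "type": "object",
      "description": "one entry per global graph parameter, each with whole_brain / left_hemisphere / right_hemisphere / pooled_residual MTPC summaries",
      "additionalProperties": {
        "type": "object",
        "additionalProperties": {
          "type": "object",
          "required": ["a_crit", "significant", "null_mean_auc", "clusters"]
        }
      }
    },
    "nodes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["region", "lambda2", "p", "significant"]
      }
    },
    "nbs": {
      "type": "object",
      "required": ["t_threshold", "components"]
    },
    "clinical": {
      "type": "object",
      "required": ["q50_vs_grip", "q50_vs_uefm"]
    },
    "lesion_sim": {
      "type": "object",
      "required": ["table", "tests"]
    },
    "elapsed_s": { "type": "number" }
  }
}
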