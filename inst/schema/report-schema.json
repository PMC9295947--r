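{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "placenorm run report",
  "type": "object",
  "required": ["software", "config", "n_scans", "group_fits",
               "band_separation", "group_stats", "roc"],
  "properties": {
    "software": {
      "type": "object",
      "required": ["package", "version"],
      "properties": {
        "package": {"type": "string"},
        "version": {"type": "string"}
      }
    },
    "config": {
      "type": "object",
      "required": ["seed", "n_subjects", "group_probs",
                   "candidate_models", "windows"]
    },
    "n_scans": {"type": "integer", "minimum": 0},
    "group_fits": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["form", "params", "rms", "n", "bic", "converged"]
      }
    },
    "band_separation": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["start", "end"]
      }
    },
    "group_stats": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["n", "mean_z", "sd_z", "median_z"]
      }
    },
    "roc": {
      "type": ["object", "array"],
      "additionalProperties": {
        "type": "object",
        "required": ["auc", "j_max", "c_opt", "n_pos", "n_neg"]
      }
    },
    "phantom": {"type": ["object", "array"]}
  }
}
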