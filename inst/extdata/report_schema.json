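{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "ratiodx discrimination report",
  "type": "object",
  "required": ["software", "generated_at", "config", "seed", "model", "roc"],
  "properties": {
    "software": {
      "type": "object",
      "required": ["package", "version"]
    },
    "generated_at": {"type": "string"},
    "config": {"type": "object"},
    "seed": {"type": "integer"},
    "model": {
      "type": "object",
      "required": ["outcome_coding", "method", "n", "parameters"],
      "properties": {
        "outcome_coding": {"enum": ["case", "control"]},
        "parameters": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["term", "estimate", "ci_low", "ci_high", "p_value"]
          }
        }
      }
    },
    "roc": {
      "type": "object",
      "required": ["training"],
      "properties": {
        "training": {"$ref": "#/$defs/roc_block"},
        "validation": {
          "oneOf": [{"$ref": "#/$defs/roc_block"}, {"type": "null"}]
        }
      }
    },
    "cross_validation": {
      "oneOf": [{"$ref": "#/$defs/validation_block"}, {"type": "null"}]
    },
    "bootstrap": {
      "oneOf": [
        {
          "type": "object",
          "required": ["training"],
          "properties": {
            "training": {"$ref": "#/$defs/validation_block"},
            "validation": {
              "oneOf": [{"$ref": "#/$defs/validation_block"},
                        {"type": "null"}]
            }
          }
        },
        {"type": "null"}
      ]
    }
  },
  "$defs": {
    "roc_block": {
      "type": "object",
      "required": ["auc", "ci_low", "ci_high", "ci_method", "p_value",
                   "n_case", "n_control"],
      "properties": {
        "auc": {"type": "number", "minimum": 0, "maximum": 1},
        "ci_method": {"enum": ["hanley_mcneil", "delong"]}
      }
    },
    "validation_block": {
      "type": "object",
      "required": ["scheme", "n_trials", "median_auc", "ci_low", "ci_high",
                   "per_trial_auc"],
      "properties": {
        "scheme": {"enum": ["repeated_cv", "bootstrap"]}
      }
    }
  }
}
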