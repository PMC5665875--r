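{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Non-homogeneous DBN network schema",
  "description": "Wire format for discrete monthly-slice dynamic Bayesian networks: nodes with ordered states and within/cross-slice parents, dense conditional probability tables keyed by full parent-state combinations, and regime selectors mapping calendar months (or slice ranges) to tables. Sparse or default-row table dialects are not admitted.",
  "type": "object",
  "required": ["nodes", "tables", "selectors"],
  "properties": {
    "nodes": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["name", "states", "role"],
        "properties": {
          "name": {"type": "string", "minLength": 1},
          "states": {
            "type": "array", "minItems": 2, "uniqueItems": true,
            "items": {"type": "string"}
          },
          "zero_label": {"type": ["string", "null"]},
          "intra_parents": {"type": "array", "items": {"type": "string"}},
          "inter_parents": {"type": "array", "items": {"type": "string"}},
          "role": {"enum": ["environment", "site", "population", "process", "output"]}
        }
      }
    },
    "tables": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "child", "parent_order", "rows"],
        "properties": {
          "id": {"type": "string", "minLength": 1},
          "child": {"type": "string"},
          "parent_order": {
            "type": "array",
            "items": {
              "type": "string",
              "description": "Parent node name; previous-slice parents carry the suffix '@prev'."
            }
          },
          "rows": {
            "type": "object",
            "description": "One entry per full parent-state combination, keyed 'p1=s1,p2=s2'; each value a probability vector over the child's states summing to 1 within 1e-9.",
            "additionalProperties": {
              "type": "array", "minItems": 2,
              "items": {"type": "number", "minimum": 0, "maximum": 1}
            }
          }
        }
      }
    },
    "selectors": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["node", "default"],
        "properties": {
          "node": {"type": "string"},
          "default": {"type": "string", "description": "Table id used when no rule matches."},
          "rules": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["table"],
              "properties": {
                "table": {"type": "string"},
                "months": {
                  "type": "array",
                  "items": {"type": "integer", "minimum": 1, "maximum": 12}
                },
                "slices": {
                  "type": "array", "minItems": 2, "maxItems": 2,
                  "items": {"type": "integer", "minimum": 0}
                }
              }
            }
          }
        }
      }
    }
  }
}
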