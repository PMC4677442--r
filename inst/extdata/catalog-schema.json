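{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Contraindication catalog config",
  "description": "A catalog of 26 stroke-thrombolysis contraindication items plus advisory history items. Extractable items carry a negation-free predicate over event-existence clauses; non-extractable items carry an on-site note.",
  "type": "object",
  "required": ["items"],
  "properties": {
    "items": {
      "type": "array",
      "minItems": 26,
      "maxItems": 26,
      "items": {
        "type": "object",
        "required": ["id", "label", "severity", "extractable"],
        "properties": {
          "id": { "type": "integer", "minimum": 1, "maximum": 26 },
          "label": { "type": "string", "minLength": 1 },
          "severity": { "enum": ["exclusion", "advisory"] },
          "extractable": { "type": "boolean" },
          "provisional": {
            "type": "boolean",
            "description": "True for items whose content and numbering are a local configuration convention rather than an authoritative mapping."
          },
          "on_site_note": { "type": "string" },
          "predicate": { "$ref": "#/definitions/predicate" }
        }
      }
    },
    "advisories": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["label", "predicate"],
        "properties": {
          "label": { "type": "string" },
          "predicate": { "$ref": "#/definitions/predicate" }
        }
      }
    }
  },
  "definitions": {
    "predicate": {
      "oneOf": [
        {
          "type": "object",
          "required": ["all"],
          "properties": {
            "all": {
              "type": "array",
              "minItems": 1,
              "items": { "$ref": "#/definitions/predicate" }
            }
          },
          "additionalProperties": false
        },
        {
          "type": "object",
          "required": ["any"],
          "properties": {
            "any": {
              "type": "array",
              "minItems": 1,
              "items": { "$ref": "#/definitions/predicate" }
            }
          },
          "additionalProperties": false
        },
        {
          "type": "object",
          "required": ["exists"],
          "properties": {
            "exists": {
              "type": "object",
              "required": ["source", "concepts", "lookback_days"],
              "properties": {
                "source": { "enum": ["diagnosis", "medication", "adr"] },
                "concepts": {
                  "type": "object",
                  "properties": {
                    "labels": { "type": "array", "items": { "type": "string" } },
                    "codes": { "type": "array", "items": { "type": "string" } }
                  }
                },
                "lookback_days": {
                  "oneOf": [
                    { "type": "number", "minimum": 1 },
                    { "const": "unlimited" }
                  ]
                }
              }
            }
          },
          "additionalProperties": false
        }
      ]
    }
  }
}
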