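{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Contraindication screen report",
  "type": "object",
  "required": ["patient_id", "index", "findings", "advisories"],
  "properties": {
    "patient_id": { "type": "string" },
    "index": { "type": "string", "format": "date-time" },
    "snapshot_time": {
      "oneOf": [{ "type": "string", "format": "date-time" }, { "type": "null" }]
    },
    "findings": {
      "type": "array",
      "minItems": 26,
      "maxItems": 26,
      "items": {
        "type": "object",
        "required": ["item_id", "label", "status", "evidence"],
        "properties": {
          "item_id": { "type": "integer" },
          "label": { "type": "string" },
          "status": { "enum": ["TRIGGERED", "CLEAR", "NOT_EXTRACTABLE"] },
          "evidence": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["source", "hospital_id", "concept", "date"],
              "properties": {
                "source": { "enum": ["diagnosis", "medication", "adr"] },
                "hospital_id": { "type": "string" },
                "concept": { "type": "string" },
                "date": { "type": "string", "format": "date" },
                "end_date": {
                  "oneOf": [{ "type": "string", "format": "date" },
                            { "type": "null" }]
                },
                "code": { "oneOf": [{ "type": "string" }, { "type": "null" }] }
              }
            }
          }
        }
      }
    },
    "advisories": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["label", "evidence"],
        "properties": {
          "label": { "type": "string" },
          "evidence": { "type": "array", "items": { "type": "string" } }
        }
      }
    },
    "recent_labs": { "type": "integer" },
    "recent_imaging": { "type": "integer" }
  }
}
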