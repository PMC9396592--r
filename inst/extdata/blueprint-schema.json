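{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "https://example.org/causalloop/blueprint-schema.json",
  "title": "CLD blueprint document",
  "description": "Two-array blueprint representation of a causal-loop diagram: elements (variables) and connections (signed causal links).",
  "type": "object",
  "required": ["elements", "connections"],
  "properties": {
    "name": { "type": "string" },
    "metadata": { "type": "object" },
    "elements": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["label"],
        "properties": {
          "label": { "type": "string", "minLength": 1 },
          "tags": { "type": "array", "items": { "type": "string" } },
          "sources": {
            "type": "array",
            "items": {
              "enum": ["veteran", "non_va_clinic", "va_system", "vso", "modeler"]
            }
          },
          "subModel": { "type": "string" },
          "note": { "type": "string" }
        }
      }
    },
    "connections": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["from", "to", "polarity"],
        "properties": {
          "from": { "type": "string", "minLength": 1 },
          "to": { "type": "string", "minLength": 1 },
          "polarity": { "enum": ["positive", "negative"] },
          "tags": { "type": "array", "items": { "type": "string" } },
          "sources": {
            "type": "array",
            "items": {
              "enum": ["veteran", "non_va_clinic", "va_system", "vso", "modeler"]
            }
          },
          "proposed": { "type": "boolean" },
          "note": { "type": "string" }
        }
      }
    }
  }
}
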