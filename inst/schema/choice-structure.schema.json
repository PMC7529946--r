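{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "netchoice/choice-structure/1.0",
  "title": "Choice structure document",
  "description": "A cue/alternative network: binary nodes with general appeals, symmetric weighted couplings stored once per undirected pair (source < target lexicographically), and the scaling constants beta (inverse temperature, non-negative) and mu (appeal weight).",
  "type": "object",
  "required": ["schema_version", "nodes", "beta", "mu"],
  "properties": {
    "schema_version": {"const": "1.0"},
    "nodes": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["id", "role"],
        "properties": {
          "id": {"type": "string"},
          "role": {"enum": ["cue", "alternative"]},
          "appeal": {"type": "number", "default": 0}
        }
      }
    },
    "edges": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["source", "target", "weight"],
        "properties": {
          "source": {"type": "string"},
          "target": {"type": "string"},
          "weight": {"type": "number"}
        }
      }
    },
    "beta": {"type": "number", "minimum": 0},
    "mu": {"type": "number"}
  }
}
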