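{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "pairsurv gene-pair signature model",
  "type": "object",
  "required": ["pairs", "cutoff", "provenance"],
  "properties": {
    "pairs": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["gene1", "gene2", "weight"],
        "properties": {
          "gene1": {"type": "string"},
          "gene2": {"type": "string"},
          "weight": {"type": "number"}
        }
      }
    },
    "cutoff": {"type": "number"},
    "provenance": {"type": "string", "enum": ["published", "trained"]},
    "config": {"type": "object"}
  }
}
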