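{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "mircurate curation snippet collection",
  "type": "array",
  "items": {
    "type": "object",
    "required": ["snippet_id", "doc_id", "sentence_index", "mirna_key",
                 "structure_id", "status"],
    "properties": {
      "snippet_id": {"type": "string", "minLength": 1},
      "doc_id": {"type": "string", "minLength": 1},
      "sentence_index": {"type": "integer", "minimum": 0},
      "sentence_text": {"type": ["string", "null"]},
      "mirna_key": {"type": "string", "minLength": 1},
      "effect": {"type": ["string", "null"]},
      "effect_polarity": {
        "type": ["string", "null"],
        "enum": ["positive", "negative", "none", null]
      },
      "target_gene": {"type": ["string", "null"]},
      "sample": {"type": ["string", "null"]},
      "disease": {"type": ["string", "null"]},
      "structure_id": {"type": "string", "enum": ["S1", "S2", "S3"]},
      "status": {"type": "string", "enum": ["AUTO", "CONFIRMED", "REJECTED"]}
    }
  }
}
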