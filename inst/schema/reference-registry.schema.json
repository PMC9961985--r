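{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "scoredrift-reference-registry/1",
  "title": "scoredrift reference registry",
  "description": "Registry of reference score distributions, one entry per (AI version major.minor, modality, manufacturer) key. Each entry carries the 10 bin counts over suspicion scores 1-10, the exam total (which must equal the sum of the bins) and provenance metadata. Keys must be unique after normalization (major.minor version, upper-case modality, case-folded manufacturer).",
  "type": "object",
  "required": ["references"],
  "properties": {
    "schema": { "type": "string" },
    "references": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["ai_version", "modality", "manufacturer", "n_exams", "bins"],
        "properties": {
          "ai_version": { "type": "string", "pattern": "^[0-9]+(\\.[0-9]+)+$" },
          "modality": { "enum": ["FFDM", "DBT"] },
          "manufacturer": { "type": "string", "minLength": 1 },
          "n_exams": { "type": "integer", "minimum": 1 },
          "bins": {
            "type": "array",
            "minItems": 10,
            "maxItems": 10,
            "items": { "type": "integer", "minimum": 0 }
          },
          "provenance": {
            "type": "object",
            "properties": {
              "label": { "type": "string" },
              "date_range": { "type": "string" }
            }
          }
        }
      }
    }
  }
}
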