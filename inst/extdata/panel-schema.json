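{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Gene panel document (one YAML document per panel version)",
  "type": "object",
  "required": ["panel_id", "version_tag", "entries"],
  "properties": {
    "panel_id": { "type": "string" },
    "version_tag": { "enum": ["original", "updated"] },
    "entries": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["gene", "rating", "moi"],
        "properties": {
          "gene": { "type": "string" },
          "rating": { "enum": ["green", "amber", "red"] },
          "moi": { "enum": ["monoallelic", "biallelic", "x_linked", "both"] }
        }
      }
    }
  }
}
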