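{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "helixbind analysis report",
  "type": "object",
  "required": ["stage", "provenance", "results"],
  "properties": {
    "stage": {
      "type": "string",
      "enum": ["triage", "classify", "mmgbsa", "ti", "simulate"]
    },
    "provenance": {
      "type": "object",
      "required": ["config_hash", "package", "package_version"],
      "properties": {
        "config_hash": { "type": "string" },
        "package": { "type": "string" },
        "package_version": { "type": "string" },
        "seed": { "type": ["integer", "number", "null"] },
        "config": { "type": "object" }
      }
    },
    "results": { "type": ["object", "array"] }
  }
}
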