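{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "paleoadmix analysis summary",
  "type": "object",
  "required": ["target", "seed", "stages"],
  "properties": {
    "target": {"type": "string"},
    "seed": {"type": "integer"},
    "stages": {
      "type": "object",
      "required": ["f3_scan", "pca", "d_scan", "pairwise_f3", "qpadm",
                   "transversion_replication", "downsampling", "dating"],
      "additionalProperties": {
        "type": "object",
        "required": ["status"],
        "properties": {
          "status": {"enum": ["ok", "skipped", "error"]},
          "message": {"type": "string"}
        }
      }
    }
  }
}
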