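{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "pirnakit run report",
  "type": "object",
  "required": ["package", "seed", "stages", "parameters", "digests", "run_digest"],
  "properties": {
    "package": {"const": "pirnakit"},
    "seed": {"type": "integer"},
    "stages": {"type": "object", "additionalProperties": {"type": "boolean"}},
    "parameters": {"type": "object"},
    "de_counts": {"type": "object"},
    "targets": {"type": "object"},
    "overlaps": {"type": "object"},
    "integrate": {"type": "object"},
    "motif": {"type": "object"},
    "enrich": {"type": "object"},
    "recovery": {"type": "object"},
    "digests": {"type": "object", "additionalProperties": {"type": "string"}},
    "run_digest": {"type": "string"}
  }
}
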