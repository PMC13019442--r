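{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "dbfe run report",
  "type": "object",
  "required": ["tool", "version", "seed", "legs", "dg_total", "se",
               "diagnostics", "restraint", "config"],
  "properties": {
    "tool": {"const": "dbfe"},
    "version": {"type": "string"},
    "seed": {"type": "integer"},
    "legs": {
      "type": "object",
      "required": ["dg_release", "dg_filter", "dg_mbar"],
      "properties": {
        "dg_release": {"type": "number"},
        "dg_filter": {"type": "number"},
        "dg_mbar": {"type": "number"}
      }
    },
    "dg_total": {"type": "number"},
    "se": {
      "type": "object",
      "required": ["se_release", "se_filter", "se_mbar", "se_total"],
      "additionalProperties": {"type": "number"}
    },
    "diagnostics": {
      "type": "object",
      "required": ["n_p", "n_l", "n_zeta", "n_tested", "alpha", "overlap"],
      "properties": {
        "n_p": {"type": "integer", "minimum": 1},
        "n_l": {"type": "integer", "minimum": 1},
        "n_zeta": {"type": "number", "minimum": 1},
        "n_tested": {"type": "number", "minimum": 1},
        "alpha": {"type": "number", "minimum": 0, "maximum": 1},
        "overlap": {"type": "number", "minimum": 0, "maximum": 1}
      }
    },
    "restraint": {
      "type": "object",
      "required": ["mu", "sigma", "M", "Z"],
      "properties": {
        "mu": {"type": "array", "minItems": 3, "maxItems": 3},
        "Z": {"type": "array", "minItems": 4, "maxItems": 4}
      }
    },
    "config": {"type": "object"},
    "exact_delta_g": {"type": "number"},
    "timestamp": {"type": "string"}
  }
}
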