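{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "fbam fit result",
  "type": "object",
  "required": ["schema_version", "provenance", "selected", "solution",
               "collapsed_measures", "criteria"],
  "properties": {
    "schema_version": {"type": "string"},
    "provenance": {
      "type": "object",
      "required": ["seed", "T", "K", "R", "mode", "control"],
      "properties": {
        "seed": {"type": "integer"},
        "T": {"type": "integer"},
        "K": {"type": "integer"},
        "R": {"type": "integer"},
        "mode": {"enum": ["joint", "bands_only", "subpops_only"]},
        "control": {"type": "object"},
        "sampling_rate": {"type": ["number", "null"]}
      }
    },
    "selected": {
      "type": "object",
      "required": ["J", "L"],
      "properties": {"J": {"type": "integer"}, "L": {"type": "integer"}}
    },
    "solution": {
      "type": "object",
      "required": ["labels", "J", "L", "loss", "groups"],
      "properties": {
        "labels": {"type": "array", "items": {"type": "integer", "minimum": 1}},
        "J": {"type": "integer", "minimum": 1},
        "L": {"type": "integer", "minimum": 1},
        "loss": {"type": "number", "minimum": 0},
        "groups": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["subpopulation", "cut_indices", "cut_frequencies"],
            "properties": {
              "subpopulation": {"type": "integer"},
              "cut_indices": {"type": "array", "items": {"type": "integer"}},
              "cut_frequencies": {"type": "array", "items": {"type": "number"}},
              "cut_frequencies_hz": {"type": "array", "items": {"type": "number"}}
            }
          }
        }
      }
    },
    "collapsed_measures": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["subpopulation", "band_means", "band_sizes"],
        "properties": {
          "subpopulation": {"type": "integer"},
          "band_means": {"type": "array", "items": {"type": "number"}},
          "band_sizes": {"type": "array", "items": {"type": "integer"}}
        }
      }
    },
    "criteria": {
      "type": "object",
      "required": ["a1", "a2", "table"],
      "properties": {
        "a1": {"type": "number"},
        "a2": {"type": "number"},
        "table": {"type": "array"}
      }
    }
  }
}
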