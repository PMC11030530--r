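{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "scbench benchmark results",
  "type": "object",
  "required": ["schema_version", "task", "components", "raw"],
  "properties": {
    "schema_version": {"type": "string"},
    "task": {"type": "string"},
    "seed": {"type": ["integer", "null"]},
    "timestamp": {"type": "string"},
    "components": {
      "type": "object",
      "required": ["methods", "metrics"],
      "properties": {
        "datasets": {"type": "array", "items": {"type": "string"}},
        "methods": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["method", "role"],
            "properties": {
              "method": {"type": "string"},
              "role": {"enum": ["method", "positive_control", "negative_control"]}
            }
          }
        },
        "metrics": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["metric", "orientation"],
            "properties": {
              "metric": {"type": "string"},
              "orientation": {"enum": ["maximize", "minimize"]}
            }
          }
        }
      }
    },
    "raw": {"$ref": "#/definitions/scores"},
    "normalized": {"$ref": "#/definitions/scores"},
    "overall": {
      "type": ["array", "null"],
      "items": {
        "type": "object",
        "required": ["dataset", "method", "overall", "rank"],
        "properties": {
          "dataset": {"type": "string"},
          "method": {"type": "string"},
          "overall": {"type": ["number", "null"]},
          "rank": {"type": "integer"}
        }
      }
    },
    "resources": {
      "type": ["array", "null"],
      "items": {
        "type": "object",
        "properties": {
          "dataset": {"type": "string"},
          "method": {"type": "string"},
          "runtime_s": {"type": "number"},
          "peak_mem_bytes": {"type": "number"}
        }
      }
    }
  },
  "definitions": {
    "scores": {
      "type": ["array", "null"],
      "items": {
        "type": "object",
        "required": ["dataset", "method", "metric"],
        "properties": {
          "dataset": {"type": "string"},
          "method": {"type": "string"},
          "metric": {"type": "string"},
          "value": {"type": ["number", "null"]}
        }
      }
    }
  }
}
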