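{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "polarlasso chart layout",
  "description": "Fully resolved multi-level polar chart geometry. Angles are degrees, counterclockwise, 0 at the positive x-axis; the rank-1 sector starts at 0 and sectors partition [0, 360).",
  "type": "object",
  "required": ["sort_type", "jitter_seed", "sectors", "points"],
  "properties": {
    "sort_type": { "enum": ["max", "mean"] },
    "lambda_used": { "type": ["number", "null"] },
    "jitter_seed": { "type": "integer" },
    "lasso_mode": { "type": "boolean" },
    "sectors": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["group", "rank", "start_deg", "end_deg", "radius",
                     "size", "feature"],
        "properties": {
          "group": { "type": "string" },
          "rank": { "type": "integer", "minimum": 1 },
          "start_deg": { "type": "number", "minimum": 0, "maximum": 360 },
          "end_deg": { "type": "number", "minimum": 0, "maximum": 360 },
          "radius": { "type": "number", "exclusiveMinimum": 0, "maximum": 1 },
          "size": { "type": "integer", "minimum": 1 },
          "feature": { "type": "number", "minimum": 0 },
          "color_value": { "type": "number", "minimum": 0, "maximum": 1 },
          "color": { "type": "string" }
        }
      }
    },
    "points": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["group", "variable", "coefficient", "angle_deg",
                     "rel_radius", "symbol", "tooltip"],
        "properties": {
          "group": { "type": "string" },
          "variable": { "type": "string" },
          "coefficient": { "type": "number" },
          "angle_deg": { "type": "number", "minimum": 0, "maximum": 360 },
          "rel_radius": { "type": "number", "exclusiveMinimum": 0, "maximum": 1 },
          "symbol": { "enum": ["positive", "negative"] },
          "tooltip": { "type": "string" }
        }
      }
    }
  }
}
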