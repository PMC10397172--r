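{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Intervention document",
  "description": "Surgical intervention descriptor: metadata, named sections and tracked annotations (marks) with keyframes. Times are seconds from video start with millisecond precision; pixel coordinates are 0-based, origin top-left, boxes (x, y, w, h) with half-open extents, left-eye frame. Disparity d = x_left - x_right; the right-eye overlay is drawn at x_left - d.",
  "type": "object",
  "required": ["schema_version", "surgery", "sections", "marks"],
  "properties": {
    "schema_version": { "const": "1.0" },
    "surgery": {
      "type": "object",
      "required": ["id", "status"],
      "properties": {
        "id": { "type": "string" },
        "date": { "type": ["string", "null"] },
        "specialty": { "type": ["string", "null"] },
        "organ": { "type": ["string", "null"] },
        "technique": { "type": ["string", "null"] },
        "status": { "enum": ["draft", "published"] },
        "video_ref": { "type": ["string", "null"] }
      }
    },
    "sections": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "t_start", "t_end"],
        "properties": {
          "name": { "type": "string" },
          "description": { "type": ["string", "null"] },
          "t_start": { "type": "number", "minimum": 0 },
          "t_end": { "type": "number", "exclusiveMinimum": 0 }
        }
      }
    },
    "marks": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "label", "t_start", "t_end", "state", "initial_box"],
        "properties": {
          "id": { "type": "string" },
          "label": { "type": "string" },
          "description": { "type": ["string", "null"] },
          "t_start": { "type": "number", "minimum": 0 },
          "t_end": { "type": "number" },
          "update_interval": { "type": "number", "exclusiveMinimum": 0 },
          "state": { "enum": ["unprocessed", "processing", "processed"] },
          "initial_box": { "$ref": "#/$defs/box" },
          "keyframes": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["time", "box", "disparity", "confidence"],
              "properties": {
                "time": { "type": "number" },
                "box": { "$ref": "#/$defs/box" },
                "disparity": { "type": "number" },
                "confidence": { "type": "number", "minimum": 0, "maximum": 1 },
                "low_confidence": { "type": "boolean" }
              }
            }
          }
        }
      }
    }
  },
  "$defs": {
    "box": {
      "type": "object",
      "required": ["x", "y", "w", "h"],
      "properties": {
        "x": { "type": "number" },
        "y": { "type": "number" },
        "w": { "type": "number", "exclusiveMinimum": 0 },
        "h": { "type": "number", "exclusiveMinimum": 0 }
      }
    }
  }
}
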