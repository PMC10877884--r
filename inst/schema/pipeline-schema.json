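{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "fcspipe pipeline description",
  "type": "object",
  "required": ["experimentName", "scaleTransformProcessingSteps",
               "flowFramesPreProcessingSteps"],
  "properties": {
    "experimentName": { "type": "string", "minLength": 1 },
    "seed": { "type": "integer" },
    "sampleFiles": {
      "type": "array",
      "items": { "type": "string" }
    },
    "scaleTransformProcessingSteps": {
      "type": "array",
      "minItems": 1,
      "items": { "$ref": "#/$defs/processingStep" }
    },
    "flowFramesPreProcessingSteps": {
      "type": "array",
      "minItems": 1,
      "items": { "$ref": "#/$defs/processingStep" }
    }
  },
  "$defs": {
    "processingStep": {
      "type": "object",
      "required": ["name", "FUN"],
      "properties": {
        "name": { "type": "string", "minLength": 1 },
        "FUN": { "type": "string", "minLength": 1 },
        "ARGS": { "type": "object" }
      }
    }
  }
}
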