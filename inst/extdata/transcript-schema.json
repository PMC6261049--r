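{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Annotated speech-and-language assessment transcript (one participant)",
  "type": "object",
  "required": ["participant_id", "samples", "comprehension"],
  "additionalProperties": false,
  "properties": {
    "participant_id": {"type": "string", "minLength": 1},
    "samples": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["task", "utterances", "content_elements"],
        "additionalProperties": false,
        "properties": {
          "task": {"enum": ["conv_q1", "conv_q2", "conv_q3", "cookie_theft"]},
          "utterances": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["tokens", "relevance",
                           "repetition_of_utterance", "repair_flag"],
              "additionalProperties": false,
              "properties": {
                "tokens": {
                  "type": "array",
                  "items": {
                    "type": "object",
                    "required": ["text", "annotations"],
                    "additionalProperties": false,
                    "properties": {
                      "text": {"type": "string", "minLength": 1},
                      "annotations": {
                        "type": "array",
                        "uniqueItems": true,
                        "items": {"enum": ["filler", "repetition", "repair",
                                           "grammar_error",
                                           "semantic_paraphasia"]}
                      }
                    }
                  }
                },
                "relevance": {"enum": ["relevant", "irrelevant"]},
                "repetition_of_utterance": {"type": "boolean"},
                "repair_flag": {"type": "boolean"}
              }
            }
          },
          "content_elements": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["label", "relevant"],
              "additionalProperties": false,
              "properties": {
                "label": {"type": "string", "minLength": 1},
                "relevant": {"type": "boolean"}
              }
            }
          }
        }
      }
    },
    "comprehension": {
      "type": "array",
      "maxItems": 8,
      "items": {
        "type": "object",
        "required": ["modality", "command_id", "correct"],
        "additionalProperties": false,
        "properties": {
          "modality": {"enum": ["verbal", "written"]},
          "command_id": {"type": "integer", "minimum": 1, "maximum": 4},
          "correct": {"type": "boolean"}
        }
      }
    }
  }
}
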