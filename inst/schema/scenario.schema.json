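{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "qcog scenario file",
  "type": "object",
  "required": ["schema_version", "kind", "name"],
  "properties": {
    "schema_version": {"type": "string"},
    "kind": {"enum": ["order", "disjunction"]},
    "name": {"type": "string", "minLength": 1},
    "template": {"type": "boolean"},
    "provenance": {"type": "string"},
    "fitted": {"type": "object"},
    "probabilities": {
      "type": "object",
      "properties": {
        "p_first_solo": {"type": "number", "minimum": 0, "maximum": 1},
        "p_second_solo": {"type": "number", "minimum": 0, "maximum": 1},
        "p_second_comparative_observed": {"type": "number", "minimum": 0, "maximum": 1},
        "p_first_comparative_observed": {"type": "number", "minimum": 0, "maximum": 1},
        "p_A": {"type": "number", "minimum": 0, "maximum": 1},
        "p_B_given_A": {"type": "number", "minimum": 0, "maximum": 1},
        "p_B_given_notA": {"type": "number", "minimum": 0, "maximum": 1},
        "p_B_unknown_observed": {"type": "number", "minimum": 0, "maximum": 1}
      }
    }
  },
  "allOf": [
    {
      "if": {"properties": {"template": {"const": true}}, "required": ["template"]},
      "else": {"required": ["probabilities"]}
    },
    {
      "if": {"properties": {"kind": {"const": "order"}}, "not": {"required": ["template"]}},
      "then": {"properties": {"probabilities": {"required": ["p_first_solo", "p_second_solo", "p_second_comparative_observed"]}}}
    },
    {
      "if": {"properties": {"kind": {"const": "disjunction"}}, "not": {"required": ["template"]}},
      "then": {"properties": {"probabilities": {"required": ["p_A", "p_B_given_A", "p_B_given_notA", "p_B_unknown_observed"]}}}
    }
  ]
}
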