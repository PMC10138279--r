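{
  "schema_version": "1.0",
  "kind": "disjunction",
  "name": "two_stage_gamble",
  "template": true,
  "provenance": "Two-stage gamble of Tversky & Shafir (1992): participants are likelier to accept a second gamble when the first outcome is known (win or lose) than when it is unknown. No event rates are published for this template; fill in probabilities before use."
}
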