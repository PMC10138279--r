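{
  "schema_version": "1.0",
  "kind": "disjunction",
  "name": "vacation",
  "template": true,
  "provenance": "Vacation problem of Tversky & Shafir (1992): participants are likelier to book a vacation when an exam outcome is known (pass or fail) than when it is unknown. No event rates are published for this template; fill in probabilities before use."
}
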