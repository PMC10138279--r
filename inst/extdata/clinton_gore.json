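{
  "schema_version": "1.0",
  "kind": "order",
  "name": "clinton_gore",
  "probabilities": {
    "p_first_solo": 0.68,
    "p_second_solo": 0.50,
    "p_second_comparative_observed": 0.57,
    "p_first_comparative_observed": 0.60
  },
  "provenance": "Gallup poll of 6-7 September 1997 (Moore 2002; discussed by Wang & Busemeyer 2013): non-comparative agreement rates 50% (Clinton honest) and 68% (Gore honest); in the comparative context Clinton rose to 57% and Gore fell to 60%. The reversed-order Gore rate (0.60) is informational only."
}
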