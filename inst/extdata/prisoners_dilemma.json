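{
  "schema_version": "1.0",
  "kind": "disjunction",
  "name": "prisoners_dilemma",
  "probabilities": {
    "p_A": 0.5,
    "p_B_given_A": 0.82,
    "p_B_given_notA": 0.72,
    "p_B_unknown_observed": 0.64
  },
  "provenance": "Meta-analytic averages across Prisoner's Dilemma experiments (Busemeyer & Bruza 2012, Table 9.4): defection rate 82% when the partner is known to have betrayed, 72% when known to have cooperated, 64% when the partner's choice is unknown. Some hardware reports quote 73% for the cooperate-known condition; the 72% meta-analytic value is carried here. The 0.5 prior on the partner's defection reflects the absence of any stated prior."
}
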