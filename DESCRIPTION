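Package: qcog
Title: Quantum Circuit Models of Cognitive Decision-Making
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exact statevector simulation of small quantum circuits together
    with the closed-form quantum-probability laws used in cognitive modeling.
    Question-order effects are modeled by sequential projection on the Bloch
    sphere and realized as one- and two-qubit circuits with an ancilla-swap
    protocol standing in for mid-circuit measurement; disjunction effects
    (sure-thing-principle violations such as the Prisoner's Dilemma paradox)
    are modeled by an interference phase inside a quantum law of total
    probability and realized as a four-qubit circuit. Includes phase fitting
    against observed rates, seeded shot sampling with conditional-probability
    reconstruction from counts, scenario JSON input/output, and OpenQASM 2.0
    export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
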