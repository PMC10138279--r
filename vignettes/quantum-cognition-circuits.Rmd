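---
title: "Quantum circuit models of order and disjunction effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum circuit models of order and disjunction effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcog)
```

## The modeling problem

Two robust behavioral findings violate classical probability:

* **Question-order effects.** In the 1997 Gallup poll on the honesty of
  Clinton and Gore, Clinton's agreement rate was 50% when his question came
  first but 57% after the Gore question (whose solo rate was 68%). No fixed
  subsets of a population can produce this: membership of a set does not
  change because another membership question was asked first.
* **Disjunction effects.** In Prisoner's Dilemma experiments, 82% of
  participants defect when told their partner defected and 72% when told the
  partner cooperated — yet only 64% defect when the partner's choice is
  unknown. The classical law of total probability
  $P(B) = P(B|A)P(A) + P(B|A')P(A')$ makes $P(B)$ a convex combination of
  the conditionals, so 0.64 is unreachable for any prior
  (`classical_feasibility()` returns `FALSE` for this triple).

Quantum probability accommodates both by replacing subsets with subspaces:
answers are projections of a state vector, whose order matters because
projectors need not commute, and uncertain events can interfere before they
are resolved. `qcog` implements these models twice over, deliberately: once
as closed-form laws, and once as explicit small quantum circuits evaluated
by exact statevector simulation. The redundancy is the point — every circuit
is testable against an analytic expression it was not derived from.

## The order-effect model

Both questions live on a single qubit. The respondent starts at the Bloch
pole $|0\rangle$; each question is an axis whose "yes" state sits at polar
angle $\theta$ with $\cos^2\theta = P(\text{yes})$, so
$\theta = \arccos\sqrt{p}$ (`prob_to_angle()`). The solo rates fix
$\theta_G = \arccos\sqrt{0.68} \approx 0.601$ and
$\theta_C = \arccos\sqrt{0.50} \approx 0.785$.

A planar model (phase 0) predicts a comparative Clinton rate of
$0.68\cos^2(\theta_C-\theta_G) + 0.32\sin^2(\theta_C-\theta_G) \approx
0.668$ — too high. The Bloch sphere's azimuthal degree of freedom supplies
the missing parameter: with relative phase $\delta$ between the two axes,
the axis-to-axis transition probability becomes

$$x(\delta) = \cos^2\theta_1\cos^2\theta_2 + \sin^2\theta_1\sin^2\theta_2
  + 2\cos\theta_1\cos\theta_2\sin\theta_1\sin\theta_2\cos\delta ,$$

and the unconditional comparative rate is the two-path mixture
$p_1 x + (1-p_1)(1-x)$. `fit_order_model()` solves $\delta$ by 1-D
root-finding (`stats::uniroot`, tolerance $10^{-13}$, bracket $[0,\pi]$ —
the mirrored root $-\delta$ is equivalent because only $\cos\delta$ enters).
For the poll rates this gives $\delta \approx 1.141$ and an exact 57%.

```{r order}
fit <- fit_order_model(load_scenario(
  system.file("extdata", "clinton_gore.json", package = "qcog")))
summary(fit)
```

**Circuits.** Measuring along an arbitrary axis is realized by applying the
inverse question-frame unitary and measuring in the computational basis.
Frames are realized in a Y/Z Euler form,
$U(\theta,\varphi) = R_Z(\varphi)R_Y(2\theta)R_Z(-\varphi)$ — the narrated
circuits use X-rotations, but no complete gate list is published, so any
decomposition equal up to global phase is acceptable; ours keeps amplitudes
real when the phase vanishes, and every circuit is verified against a dense
Kronecker-product matrix oracle and an explicit projector-and-renormalize
oracle in the test suite. Asking the first question *and remembering the
answer* would require mid-circuit measurement; instead the comparative
circuit swaps in an ancilla prepared in the answer state ($|0\rangle$ for
"yes", X-flipped for "no") and conditions, after the fact, on the displaced
qubit agreeing with the inserted answer — the conditioning ratio
$\#|01\rangle/(\#|01\rangle + \#|11\rangle)$ for the "no" variant. A third
qubit can gate the swap (`build_bias_circuit()`), smoothly interpolating
between never asking the first question (`activation = 0`) and always
asking it (`activation = 1`).

**What is not fitted.** The reversed-order Gore rate (60%) is surfaced in
`summary()` and `residuals()` but never fitted: because the Clinton solo
rate is exactly one half, the model's reversed comparative rate is pinned at
$p_2 x + (1-p_2)(1-x) = 1/2$ for *every* phase. The single-qubit model
simply has no parameter left for that number, and we prefer an honest
residual to a silent refit. For the same reason `fit_order_model()` refuses
scenarios whose *first* solo rate is one half: $\delta$ would then be
unidentifiable from the comparative rate.

## The disjunction-effect model

The quantum law of total probability appends an interference term,

$$P(B) = P(B|A)P(A) + P(B|A')P(A') +
  2\sqrt{P(B|A)P(A)P(B|A')P(A')}\cos\varphi ,$$

so an observed $P(B)$ below both conditionals corresponds to a phase with
$\cos\varphi < 0$ (`solve_phase()` gives $\varphi \approx 1.741$ for the
Prisoner's Dilemma triple).

The circuit realization uses four qubits: event 1 (partner's choice,
$|0\rangle$ = betray), event 2 (participant's choice), and two ancillas.
Four components compose in order:

1. **Event preparation** — one rotation with angle $2\arccos\sqrt{p}$.
2. **Interference kernel** — a Mach–Zehnder analogue on the event-2 qubit:
   splitter, $R_Z(\varphi)$ controlled by event 1, inverse splitter. With
   the Hadamard splitter and a uniformly uncertain control, the kernel alone
   yields $P(\text{target}=1) = \tfrac12\sin^2(\varphi/2) \in [0, 1/2]$.
3. **Measurement component** — for known conditions only: a fresh ancilla
   (X-flipped for "cooperate") is swapped into the event-1 wire, and a
   $|0\rangle$ ancilla into the event-2 wire (a reset). This destroys the
   interference exactly, which is why the known-condition outputs are
   phase-invariant.
4. **Conditional component** — a white-circle (on-$|0\rangle$) controlled
   rotation with angle $2\arccos\sqrt{P(B|A)}$ and a black-circle controlled
   rotation with $2\arccos\sqrt{P(B|A')}$.

For the Hadamard splitter the unknown-condition output has the closed form

$$P(B) = p_A\,P(B|A) + (1-p_A)\left[\cos^2(\varphi/2)P(B|A') +
  \sin^2(\varphi/2)(1-P(B|A'))\right],$$

linear in $\cos^2(\varphi/2)$, so `fit_phase()` inverts it exactly
($\varphi \approx 1.754$ reproduces 64%; note this kernel phase is a
different parameterization from the $\varphi$ of the total-probability law —
both are reported by `summary()`).

```{r disjunction}
dfit <- fit_phase(load_scenario(
  system.file("extdata", "prisoners_dilemma.json", package = "qcog")))
summary(dfit)
predict(dfit, type = "circuit")
```

## Design choices in the open

* **Which branch interferes.** The published kernel diagram does not state
  the control polarity. The default modulates the $P(B|A')$ ('Cooperate')
  branch; `control_polarity = 0` mirrors it. Both satisfy the same
  contracts and both are exercised in tests.
* **Kernel wiring.** The diagram's exact wiring is likewise unpublished;
  the normative contract here is (a) range $[0, 1/2]$ with the Hadamard
  splitter, (b) reduction to the classical law at $\varphi = 0$, both
  enforced against the statevector oracle.
* **Angle conventions.** One source passage prints
  $\theta = \arccos(P(B|A))$; read literally this fails to reproduce the
  0.82/0.72 branch rates, so it is interpreted under the package-wide
  convention $\cos^2\theta = P$, which does.
* **Rotation axes.** Event preparation defaults to $R_Y$ (real amplitudes);
  an $R_X$ mode exists and provably changes nothing, because the event-1
  qubit only ever serves as a control. The conditional component is fixed
  to $R_Y$: on the event-2 qubit, which the kernel has already placed in a
  complex-amplitude state, an $R_X$ there *would* change the output, so it
  is not offered as an option.
* **72% vs 73%.** Published sources disagree on the cooperate-known rate
  (72% in the meta-analytic table, 73% in one hardware report); the shipped
  fixture carries 72% with a provenance note recording both.
* **On-zero controls** are native in the simulator (mirroring the
  white-circle notation); the OpenQASM 2.0 exporter lowers them to
  X-conjugated on-one controls, swaps to three CNOTs, and controlled
  rotations to `crz`/`cu3`, so the emitted text uses stock `qelib1.inc`
  gates only.

## Numerical policy

* Exact statevector assertions use an absolute tolerance of $10^{-9}$;
  probabilities are validated to $[0,1]$ with explicit errors, never
  silently clamped (`quantum_total_probability()` treats an out-of-range
  result as a parameter error).
* Unattainable fitting targets raise range errors that name the attainable
  interval, for both `fit_order_model()` and `fit_phase()`.
* Global phase is ignored everywhere; states are compared through
  probabilities or up-to-phase amplitudes.
* Sampled assertions use five shot-noise levels,
  $5\sqrt{p(1-p)/\text{shots}}$, at the conventional 10,000 shots.
  `sample_counts()` is a seeded multinomial draw from the exact
  distribution; identical seeds give identical tables, and the caller's RNG
  stream is restored afterwards.
* The register cap is 12 qubits — far above the four these models need, but
  enough to keep the dense amplitude vector trivially cheap.

## The random-scenario generator

`generate_random_scenario()` exists for property testing, not realism: it
draws solo/branch rates uniformly from $[0.15, 0.85]$, keeps order
scenarios at least 0.05 away from the unidentifiable first-rate-of-one-half
point, and rejection-samples the "observed" rate into the middle 80% of the
attainable interval so that fitting always succeeds by construction. What
it emulates is the *algebraic* shape of the published experiments —
marginals, conditionals, one observed rate to invert. What it does not
emulate: sampling noise in the observed rates themselves, respondent
heterogeneity, or any claim that real experiments scatter uniformly over
parameter space. Passing these property suites therefore shows internal
consistency (circuits ≡ closed forms ≡ oracles over ~100 seeded scenarios
per suite, a size chosen to keep the whole test run a few seconds), not
empirical adequacy; the empirical content lives entirely in the two
packaged scenarios.

## Limitations

* Only 2-outcome, single-qubit question models: no subspace intersections
  or commuting-projector logic, no chains of more than two questions.
* The single-qubit order model cannot fit the reversed comparative rate
  when a solo rate equals one half (see above) — a property of the model
  class, reported rather than hidden.
* No density matrices, noise channels or hardware error models: the
  simulator is exact, and sampled runs model shot noise only.
* Figure-only curves from the source literature (phase-sweep plots for
  non-Hadamard splitters) are reproduced qualitatively by
  `phase_sweep()`, not point-for-point.
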