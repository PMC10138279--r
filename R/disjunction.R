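# Disjunction-effect circuits (Prisoner's Dilemma and friends).
#
# Encoding: the event-1 qubit holds the partner's decision, |0> = 'Betray'
# (event A), |1> = 'Cooperate'; the event-2 qubit holds the participant's
# decision with the same encoding. Event preparation uses Y-rotations by
# default (real amplitudes); X-rotations are equivalent here because the
# event-1 qubit is only ever used as a control and never re-mixed, so only
# its branch magnitudes matter.

#' Describe a disjunction-effect scenario
#'
#' Holds the rates of a two-event decision experiment: the prior of event 1
#' (partner betrays), the two known-condition rates of event 2 (participant
#' betrays), and the observed unknown-condition rate whose departure from
#' the classical law of total probability is the disjunction effect.
#'
#' @param name Scenario label.
#' @param p_A Probability of event 1 ('Betray'); 0.5 is the conventional
#'   uninformed prior.
#' @param p_B_given_A Rate of event 2 given event 1 known true (0.82 in the
#'   Prisoner's Dilemma meta-analysis).
#' @param p_B_given_notA Rate given event 1 known false (0.72).
#' @param p_B_unknown_observed Observed rate with event 1 unknown (0.64).
#' @return An object of class `disjunction_scenario`.
#' @examples
#' disjunction_scenario("pd", 0.5, 0.82, 0.72, 0.64)
#' @export
disjunction_scenario <- function(name, p_A, p_B_given_A, p_B_given_notA,
                                 p_B_unknown_observed) {
  stopifnot(is.character(name), length(name) == 1L)
  structure(list(name = name,
                 p_A = check_prob(p_A),
                 p_B_given_A = check_prob(p_B_given_A),
                 p_B_given_notA = check_prob(p_B_given_notA),
                 p_B_unknown_observed = check_prob(p_B_unknown_observed)),
            class = "disjunction_scenario")
}

#' @export
print.disjunction_scenario <- function(x, ...) {
  cat(sprintf("<disjunction_scenario '%s'>\n", x$name))
  cat(sprintf("  P(A) = %.4g;  P(B|A) = %.4g;  P(B|A') = %.4g\n",
              x$p_A, x$p_B_given_A, x$p_B_given_notA))
  cat(sprintf("  P(B) observed, A unknown: %.4g  (classical law gives %.4g)\n",
              x$p_B_unknown_observed,
              classical_total_probability(x)))
  invisible(x)
}

#' Event-preparation gates
#'
#' A single rotation setting P(target = 0) = `p`, with gate angle
#' `2 * prob_to_angle(p)` (the probability-to-angle map composed with the
#' half-angle gate convention).
#'
#' @param p Desired probability of outcome 0.
#' @param target Qubit index.
#' @param axis `"Y"` (default, real amplitudes) or `"X"`.
#' @return A list of `qc_gate`s.
#' @examples
#' state_probabilities(run_circuit(qc_circuit(1, build_event_prep(0.82, 0))))
#' @export
build_event_prep <- function(p, target, axis = c("Y", "X")) {
  axis <- match.arg(axis)
  p <- check_prob(p)
  list(qc_gate(paste0("R", axis), as.integer(target),
               angle = 2 * prob_to_angle(p)))
}

#' Conditional-probability component
#'
#' Two controlled rotations on the target: an on-zero ("white circle")
#' control applying angle `2 * prob_to_angle(p_B_given_A)` and an on-one
#' ("black circle") control applying `2 * prob_to_angle(p_B_given_notA)`.
#' Acting on a target in \eqn{|0\rangle}: the control-\eqn{|0\rangle} branch
#' ends with P(target = 0) = `p_B_given_A`, the control-\eqn{|1\rangle}
#' branch with `p_B_given_notA`.
#'
#' @param p_B_given_A,p_B_given_notA Branch probabilities.
#' @param control,target Distinct qubit indices.
#' @param axis Rotation axis, as in [build_event_prep()].
#' @return A list of `qc_gate`s.
#' @export
build_conditional_component <- function(p_B_given_A, p_B_given_notA,
                                        control, target,
                                        axis = c("Y", "X")) {
  axis <- match.arg(axis)
  control <- as.integer(control); target <- as.integer(target)
  if (control == target) stop("'control' and 'target' must differ",
                              call. = FALSE)
  kind <- paste0("R", axis)
  list(qc_gate(kind, target, angle = 2 * prob_to_angle(check_prob(p_B_given_A)),
               controls = control, polarity = 0L),
       qc_gate(kind, target,
               angle = 2 * prob_to_angle(check_prob(p_B_given_notA)),
               controls = control, polarity = 1L))
}

#' Classical Bayesian-network circuit
#'
#' Event preparation followed by the conditional component on two qubits.
#' The exact probability of event 2 obeys the classical law of total
#' probability — this circuit cannot show a disjunction effect.
#'
#' @param scenario A [disjunction_scenario()].
#' @param axis Rotation axis for event preparation (both branches start the
#'   target at \eqn{|0\rangle}, so the choice never changes a probability
#'   here).
#' @return A `qc_circuit` on two qubits.
#' @examples
#' pd <- disjunction_scenario("pd", 0.5, 0.82, 0.72, 0.64)
#' state_probabilities(run_circuit(build_bayes_circuit(pd)), 1)  # 0.77 at "0"
#' @export
build_bayes_circuit <- function(scenario, axis = c("Y", "X")) {
  stopifnot(inherits(scenario, "disjunction_scenario"))
  axis <- match.arg(axis)
  qc_circuit(2L, c(build_event_prep(scenario$p_A, 0L, axis),
                   build_conditional_component(scenario$p_B_given_A,
                                               scenario$p_B_given_notA,
                                               0L, 1L, axis)),
             measure = c(0L, 1L))
}

splitter_gates <- function(splitter, target) {
  switch(splitter,
         H = list(qc_gate("H", target)),
         Y = list(qc_gate("RY", target, angle = pi / 2)),
         X = list(qc_gate("RX", target, angle = pi / 2)),
         stop("unknown splitter '", splitter, "'", call. = FALSE))
}

#' Interference kernel
#'
#' The Mach–Zehnder-style sub-circuit coupling the uncertainty of the
#' control event to the target's outcome probability: splitter on the
#' target, a phase rotation `RZ(phi)` on the target controlled by the
#' control qubit, then the inverse splitter. With the Hadamard splitter, a
#' uniformly uncertain control and a target in \eqn{|0\rangle}, the kernel
#' alone gives \eqn{P(\mathrm{target}=1) = \tfrac12\sin^2(\varphi/2) \in
#' [0, 1/2]}; when the control sits in the inactive polarity the kernel is
#' the identity.
#'
#' @param phi Phase angle in radians.
#' @param control,target Distinct qubit indices.
#' @param splitter `"H"` (Hadamard), `"Y"` (half Y-rotation) or `"X"`
#'   (half X-rotation).
#' @param control_polarity 1 (default): the phase acts on the
#'   control-\eqn{|1\rangle} ('Cooperate') branch; 0 for the mirrored choice.
#' @return A list of `qc_gate`s.
#' @export
build_interference_kernel <- function(phi, control, target,
                                      splitter = c("H", "Y", "X"),
                                      control_polarity = 1L) {
  splitter <- match.arg(splitter)
  control <- as.integer(control); target <- as.integer(target)
  if (control == target) stop("'control' and 'target' must differ",
                              call. = FALSE)
  control_polarity <- as.integer(control_polarity)
  stopifnot(control_polarity %in% c(0L, 1L))
  fwd <- splitter_gates(splitter, target)
  bwd <- lapply(rev(fwd), qc_gate_inverse)
  c(fwd,
    list(qc_gate("RZ", target, angle = phi, controls = control,
                 polarity = control_polarity)),
    bwd)
}

#' Closed-form unknown-condition probability (Hadamard splitter)
#'
#' The analytic value of P(event 2 = 0) from the full circuit when event 1
#' is unknown:
#' \deqn{P(A)P(B|A) + (1-P(A))\left[\cos^2(\varphi/2)P(B|A') +
#'       \sin^2(\varphi/2)(1 - P(B|A'))\right]}
#' for the default control polarity (the phase modulates the
#' \eqn{P(B|A')} branch); the mirrored polarity exchanges the roles of the
#' two branches. `phi = 0` reduces to the classical law of total
#' probability.
#'
#' @inheritParams build_bayes_circuit
#' @param phi Phase angle in radians.
#' @param control_polarity As in [build_interference_kernel()].
#' @return A probability.
#' @examples
#' pd <- disjunction_scenario("pd", 0.5, 0.82, 0.72, 0.64)
#' closed_form_unknown(pd, 0)            # 0.77
#' closed_form_unknown(pd, pi)           # 0.55
#' @export
closed_form_unknown <- function(scenario, phi, control_polarity = 1L) {
  stopifnot(inherits(scenario, "disjunction_scenario"))
  cc <- cos(phi / 2)^2; ss <- 1 - cc
  mix <- function(p) cc * p + ss * (1 - p)
  if (control_polarity == 1L) {
    scenario$p_A * scenario$p_B_given_A +
      (1 - scenario$p_A) * mix(scenario$p_B_given_notA)
  } else {
    scenario$p_A * mix(scenario$p_B_given_A) +
      (1 - scenario$p_A) * scenario$p_B_given_notA
  }
}

#' Fit the interference phase to the observed unknown-condition rate
#'
#' With the Hadamard splitter the unknown-condition probability is linear in
#' \eqn{\cos^2(\varphi/2)}, so the fit is a closed-form inversion; the
#' canonical root in \[0, pi\] is returned. Rates outside the attainable
#' interval (the values at `phi = pi` and `phi = 0`) raise a range error
#' naming it.
#'
#' @inheritParams closed_form_unknown
#' @return An object of class `disjunction_fit` with components `scenario`,
#'   `phi`, `control_polarity`, `splitter` and `attainable`.
#' @examples
#' fit <- fit_phase(disjunction_scenario("pd", 0.5, 0.82, 0.72, 0.64))
#' coef(fit)["phi"]  # about 1.753
#' predict(fit)
#' @export
fit_phase <- function(scenario, control_polarity = 1L) {
  stopifnot(inherits(scenario, "disjunction_scenario"))
  target <- scenario$p_B_unknown_observed
  at0 <- closed_form_unknown(scenario, 0, control_polarity)
  atpi <- closed_form_unknown(scenario, pi, control_polarity)
  rng <- sort(c(atpi, at0))
  if (abs(at0 - atpi) < 1e-12) {
    if (abs(target - at0) < 1e-9) {
      phi <- 0
    } else {
      stop(sprintf("target %.6f unattainable: only %.6f is reachable",
                   target, at0), call. = FALSE)
    }
  } else {
    cc <- (target - atpi) / (at0 - atpi)   # = cos^2(phi/2)
    if (cc < -1e-9 || cc > 1 + 1e-9) {
      stop(sprintf(paste0("observed unknown-condition rate %.6f ",
                          "unattainable: attainable interval is ",
                          "[%.6f, %.6f]"), target, rng[1], rng[2]),
           call. = FALSE)
    }
    phi <- 2 * acos(sqrt(min(max(cc, 0), 1)))
  }
  structure(list(scenario = scenario, phi = phi,
                 control_polarity = as.integer(control_polarity),
                 splitter = "H", attainable = rng),
            class = "disjunction_fit")
}

#' @export
print.disjunction_fit <- function(x, ...) {
  cat(sprintf("Disjunction-effect model fit: '%s'\n", x$scenario$name))
  cat(sprintf("  phi = %.6f rad  (splitter %s, phase on control=%d branch)\n",
              x$phi, x$splitter, x$control_polarity))
  cat(sprintf("  unknown-condition rate: fitted %.6f (observed %.4g)\n",
              closed_form_unknown(x$scenario, x$phi, x$control_polarity),
              x$scenario$p_B_unknown_observed))
  invisible(x)
}

#' @export
coef.disjunction_fit <- function(object, ...) {
  sc <- object$scenario
  c(phi = object$phi,
    theta_A = prob_to_angle(sc$p_A),
    theta_B_given_A = prob_to_angle(sc$p_B_given_A),
    theta_B_given_notA = prob_to_angle(sc$p_B_given_notA))
}

#' Model probabilities of a disjunction fit
#'
#' `type = "closed_form"` uses the analytic expressions; `type = "circuit"`
#' rebuilds and runs the three full four-qubit circuits exactly.
#'
#' @param object A `disjunction_fit`.
#' @param type `"closed_form"` or `"circuit"`.
#' @param ... Unused.
#' @return Named vector of P(event 2 = 0) under conditions `betray`,
#'   `cooperate`, `unknown`.
#' @export
predict.disjunction_fit <- function(object,
                                    type = c("closed_form", "circuit"), ...) {
  type <- match.arg(type)
  sc <- object$scenario
  if (type == "closed_form") {
    c(betray = sc$p_B_given_A, cooperate = sc$p_B_given_notA,
      unknown = closed_form_unknown(sc, object$phi, object$control_polarity))
  } else {
    vapply(c(betray = "betray", cooperate = "cooperate", unknown = "unknown"),
           function(cond) {
             circ <- build_full_circuit(object, cond)
             state_probabilities(run_circuit(circ), 1L)[["0"]]
           }, numeric(1))
  }
}

#' @export
summary.disjunction_fit <- function(object, ...) {
  sc <- object$scenario
  out <- list(fit = object, predictions = predict(object),
              classical = classical_total_probability(sc),
              feasible_classically =
                classical_feasibility(sc$p_B_unknown_observed,
                                      sc$p_B_given_A, sc$p_B_given_notA),
              equivalent_total_phase =
                tryCatch(solve_phase(sc, sc$p_B_unknown_observed),
                         error = function(e) NA_real_))
  class(out) <- "summary.disjunction_fit"
  out
}

#' @export
print.summary.disjunction_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  classical law of total probability: %.6f\n", x$classical))
  cat(sprintf("  observed rate classically feasible: %s\n",
              x$feasible_classically))
  if (!is.na(x$equivalent_total_phase)) {
    cat(sprintf("  equivalent phase in the quantum total-probability law: %.6f rad\n",
                x$equivalent_total_phase))
  }
  cat(sprintf("  attainable unknown-condition interval: [%.6f, %.6f]\n",
              x$fit$attainable[1], x$fit$attainable[2]))
  invisible(x)
}

#' Measurement-and-reset component via ancilla swaps
#'
#' Swapping a fresh ancilla into the event-1 wire inserts a known outcome
#' (the ancilla is X-flipped first to insert 'Cooperate'); swapping a
#' \eqn{|0\rangle} ancilla into the event-2 wire resets it. `known = "none"`
#' emits no gates.
#'
#' @param known `"none"`, `"betray"` or `"cooperate"`.
#' @param event1,event2,ancilla1,ancilla2 Four distinct qubit indices.
#' @return A (possibly empty) list of `qc_gate`s.
#' @export
build_measurement_component <- function(known = c("none", "betray",
                                                  "cooperate"),
                                        event1 = 0L, event2 = 1L,
                                        ancilla1 = 2L, ancilla2 = 3L) {
  known <- match.arg(known)
  idx <- as.integer(c(event1, event2, ancilla1, ancilla2))
  if (anyDuplicated(idx)) stop("qubit indices must be distinct", call. = FALSE)
  if (known == "none") return(list())
  gates <- list()
  if (known == "cooperate") gates <- list(qc_gate("X", idx[3]))
  c(gates,
    list(qc_gate("SWAP", c(idx[1], idx[3])),
         qc_gate("SWAP", c(idx[2], idx[4]))))
}

#' Full disjunction-effect circuit
#'
#' Four qubits (q0 event 1, q1 event 2, q2/q3 ancillas): event preparation,
#' the interference kernel (q0 controlling q1), the measurement/reset
#' component for the requested condition, then the conditional-probability
#' component. Exactly, P(event 2 = 0) is `p_B_given_A` (betray known),
#' `p_B_given_notA` (cooperate known) — both independent of the phase, since
#' the reset destroys the interference — or [closed_form_unknown()] at the
#' circuit's phase (unknown).
#'
#' @param x A `disjunction_fit` (phase taken from the fit) or a
#'   `disjunction_scenario` (then `phi` must be given for the unknown
#'   condition).
#' @param condition `"betray"`, `"cooperate"` or `"unknown"`.
#' @param phi Phase override in radians (required for the unknown condition
#'   when `x` is a bare scenario; defaults to 0 for known conditions).
#' @param splitter,control_polarity Kernel options, as in
#'   [build_interference_kernel()].
#' @param axis Rotation axis for the event-1 preparation, as in
#'   [build_event_prep()]; since event 1 only ever acts as a control, the
#'   choice leaves every output probability unchanged. The conditional
#'   component always uses Y-rotations, whose real amplitudes compose
#'   correctly with the kernel's phase on the event-2 qubit.
#' @return A `qc_circuit` on four qubits, measuring q0 and q1.
#' @examples
#' fit <- fit_phase(disjunction_scenario("pd", 0.5, 0.82, 0.72, 0.64))
#' state_probabilities(run_circuit(build_full_circuit(fit, "unknown")), 1)
#' @export
build_full_circuit <- function(x, condition = c("betray", "cooperate",
                                                "unknown"),
                               phi = NULL, splitter = c("H", "Y", "X"),
                               control_polarity = NULL, axis = c("Y", "X")) {
  condition <- match.arg(condition)
  splitter <- match.arg(splitter)
  axis <- match.arg(axis)
  if (inherits(x, "disjunction_fit")) {
    scenario <- x$scenario
    if (is.null(phi)) phi <- x$phi
    if (is.null(control_polarity)) control_polarity <- x$control_polarity
  } else if (inherits(x, "disjunction_scenario")) {
    scenario <- x
    if (is.null(control_polarity)) control_polarity <- 1L
    if (is.null(phi)) {
      if (condition == "unknown") {
        stop("the unknown condition needs a fitted phase: pass a ",
             "disjunction_fit or an explicit 'phi'", call. = FALSE)
      }
      phi <- 0
    }
  } else {
    stop("'x' must be a disjunction_scenario or disjunction_fit",
         call. = FALSE)
  }
  known <- switch(condition, betray = "betray", cooperate = "cooperate",
                  unknown = "none")
  gates <- c(build_event_prep(scenario$p_A, 0L, axis),
             build_interference_kernel(phi, control = 0L, target = 1L,
                                       splitter = splitter,
                                       control_polarity = control_polarity),
             build_measurement_component(known, 0L, 1L, 2L, 3L),
             build_conditional_component(scenario$p_B_given_A,
                                         scenario$p_B_given_notA,
                                         0L, 1L, axis = "Y"))
  qc_circuit(4L, gates, measure = c(0L, 1L))
}

#' Phase sweep of the unknown-condition probability
#'
#' Runs the full circuit exactly at each phase on the grid and tabulates
#' P(event 2 = 0) in the unknown condition.
#'
#' @inheritParams build_full_circuit
#' @param scenario A `disjunction_scenario`.
#' @param phis Nonempty numeric grid of phases (radians).
#' @return Data frame with columns `phi` and `probability`.
#' @examples
#' pd <- disjunction_scenario("pd", 0.5, 0.82, 0.72, 0.64)
#' phase_sweep(pd, phis = c(0, pi / 2, pi))
#' @export
phase_sweep <- function(scenario, phis, splitter = c("H", "Y", "X"),
                        control_polarity = 1L, axis = c("Y", "X")) {
  stopifnot(inherits(scenario, "disjunction_scenario"))
  if (!is.numeric(phis) || length(phis) == 0L) {
    stop("'phis' must be a nonempty numeric grid", call. = FALSE)
  }
  splitter <- match.arg(splitter)
  axis <- match.arg(axis)
  prob <- vapply(phis, function(phi) {
    circ <- build_full_circuit(scenario, "unknown", phi = phi,
                               splitter = splitter,
                               control_polarity = control_polarity,
                               axis = axis)
    state_probabilities(run_circuit(circ), 1L)[["0"]]
  }, numeric(1))
  data.frame(phi = as.numeric(phis), probability = prob)
}

#' Plot the phase-response curve of a disjunction fit
#'
#' Sweeps the unknown-condition probability over \[0, 2 pi\] and marks the
#' fitted phase, the classical value and the observed rate.
#'
#' @param x A `disjunction_fit`.
#' @param n Grid resolution.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.disjunction_fit <- function(x, n = 181, ...) {
  grid <- seq(0, 2 * pi, length.out = n)
  sw <- phase_sweep(x$scenario, grid, control_polarity = x$control_polarity)
  graphics::plot(sw$phi, sw$probability, type = "l",
                 xlab = expression(phi), ylab = "P(event 2 = 0)",
                 main = sprintf("Unknown-condition phase response: %s",
                                x$scenario$name), ...)
  graphics::abline(h = classical_total_probability(x$scenario), lty = 3)
  graphics::abline(h = x$scenario$p_B_unknown_observed, lty = 2)
  graphics::points(x$phi, closed_form_unknown(x$scenario, x$phi,
                                              x$control_polarity), pch = 19)
  invisible(x)
}

#' Simulate shot-sampled condition rates from a disjunction fit
#'
#' Samples the three full circuits and returns the frequency of event 2 = 0
#' per condition for each replicate.
#'
#' @param object A `disjunction_fit`.
#' @param nsim Number of replicates.
#' @param seed Integer seed (replicate i uses `seed + i - 1`).
#' @param shots Shots per circuit.
#' @param ... Unused.
#' @return Data frame with columns `seed`, `shots`, `condition`, `rate`.
#' @export
simulate.disjunction_fit <- function(object, nsim = 1, seed = 1L,
                                     shots = 10000L, ...) {
  conds <- c("betray", "cooperate", "unknown")
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    s <- seed + i - 1L
    rate <- vapply(seq_along(conds), function(k) {
      cts <- sample_counts(build_full_circuit(object, conds[k]), shots,
                           seed = s + 1000L * k)
      conditional_from_counts(cts, condition = "..", outcome = ".0")
    }, numeric(1))
    out[[i]] <- data.frame(seed = s, shots = shots, condition = conds,
                           rate = rate)
  }
  do.call(rbind, out)
}
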