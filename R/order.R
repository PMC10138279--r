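# Question-order effect model and circuits.
#
# Both questions live on one qubit: the respondent starts at the Bloch pole
# |0>, the first question's "yes" axis sits at polar angle theta_first
# (azimuthal phase 0, wlog) and the second question's at theta_second with
# relative phase delta. The question-frame unitary for an axis (theta, phase)
# is U = RZ(phase) RY(2 theta) RZ(-phase), so measuring "yes" along the axis
# equals applying U-dagger and measuring |0> in the computational basis.
# A Y/Z Euler decomposition is used for readability; any decomposition equal
# up to global phase gives identical statistics.

#' Describe a two-question order-effect scenario
#'
#' Holds the observed rates of a survey order experiment: the two solo
#' (non-comparative) agreement rates, and the agreement rate of the second
#' question when it follows the first (the comparative context). The reverse
#' comparative rate is informational only: with the first solo rate at 1/2
#' the single-qubit model pins that rate at 1/2, so it is never fitted (see
#' [residuals.order_fit()]).
#'
#' @param name Scenario label.
#' @param p_first_solo Solo agreement rate of the question asked first in
#'   the comparative context (e.g. Gore, 0.68).
#' @param p_second_solo Solo agreement rate of the second question
#'   (e.g. Clinton, 0.50).
#' @param p_second_comparative_observed Observed agreement rate of the
#'   second question in the comparative context (e.g. 0.57).
#' @param p_first_comparative_observed Optional observed rate of the first
#'   question in the reversed comparative context (e.g. 0.60), informational.
#' @return An object of class `order_scenario`.
#' @examples
#' order_scenario("clinton_gore", 0.68, 0.50, 0.57, 0.60)
#' @export
order_scenario <- function(name, p_first_solo, p_second_solo,
                           p_second_comparative_observed,
                           p_first_comparative_observed = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  structure(list(
    name = name,
    p_first_solo = check_prob(p_first_solo),
    p_second_solo = check_prob(p_second_solo),
    p_second_comparative_observed = check_prob(p_second_comparative_observed),
    p_first_comparative_observed =
      if (!is.null(p_first_comparative_observed)) {
        check_prob(p_first_comparative_observed)
      }),
    class = "order_scenario")
}

#' @export
print.order_scenario <- function(x, ...) {
  cat(sprintf("<order_scenario '%s'>\n", x$name))
  cat(sprintf("  solo rates: first %.4g, second %.4g\n",
              x$p_first_solo, x$p_second_solo))
  cat(sprintf("  comparative second (observed): %.4g\n",
              x$p_second_comparative_observed))
  if (!is.null(x$p_first_comparative_observed)) {
    cat(sprintf("  comparative first (informational): %.4g\n",
                x$p_first_comparative_observed))
  }
  invisible(x)
}

# attainable range of the comparative rate over delta in [0, pi]
comparative_range <- function(theta1, theta2, p_first) {
  x_ends <- c(bloch_transition_probability(theta1, theta2, 0),
              bloch_transition_probability(theta1, theta2, pi))
  range(comparative_probability(p_first, x_ends[1]),
        comparative_probability(p_first, x_ends[2]))
}

#' Fit the single-qubit order-effect model
#'
#' The polar angles are fixed by the solo rates through the mapping
#' \eqn{\theta = \arccos\sqrt{p}}; the relative Bloch phase `delta` is then
#' solved by one-dimensional root-finding so that the two-path comparative
#' rate ([comparative_probability()]) matches the observed comparative rate
#' of the second question. An observed rate outside the attainable interval
#' raises a range error naming that interval.
#'
#' @param scenario An [order_scenario()].
#' @return An object of class `order_fit` with components `scenario`,
#'   `theta_first`, `theta_second`, `delta`, `x` (the fitted axis-to-axis
#'   transition probability) and `attainable` (comparative-rate interval).
#' @examples
#' fit <- fit_order_model(order_scenario("cg", 0.68, 0.50, 0.57, 0.60))
#' coef(fit)
#' predict(fit)
#' @export
fit_order_model <- function(scenario) {
  stopifnot(inherits(scenario, "order_scenario"))
  p1 <- scenario$p_first_solo
  theta1 <- prob_to_angle(p1)
  theta2 <- prob_to_angle(scenario$p_second_solo)
  target <- scenario$p_second_comparative_observed
  rng <- comparative_range(theta1, theta2, p1)
  if (abs(p1 - 0.5) < 1e-9) {
    stop(paste0("delta is not identifiable when the first solo rate is 1/2: ",
                "the comparative rate is then 1/2 for every phase"),
         call. = FALSE)
  }
  f <- function(delta) {
    comparative_probability(p1, bloch_transition_probability(theta1, theta2,
                                                             delta)) - target
  }
  if (target < rng[1] - 1e-9 || target > rng[2] + 1e-9) {
    stop(sprintf(paste0("observed comparative rate %.6f unattainable: ",
                        "attainable interval is [%.6f, %.6f]"),
                 target, rng[1], rng[2]), call. = FALSE)
  }
  delta <- if (abs(f(0)) < 1e-10) 0 else if (abs(f(pi)) < 1e-10) pi else
    stats::uniroot(f, c(0, pi), tol = 1e-13)$root
  structure(list(scenario = scenario, theta_first = theta1,
                 theta_second = theta2, delta = delta,
                 x = bloch_transition_probability(theta1, theta2, delta),
                 attainable = rng),
            class = "order_fit")
}

#' @export
print.order_fit <- function(x, ...) {
  cat(sprintf("Order-effect model fit: '%s'\n", x$scenario$name))
  cat(sprintf("  theta_first  = %.6f rad  (solo rate %.4g)\n",
              x$theta_first, x$scenario$p_first_solo))
  cat(sprintf("  theta_second = %.6f rad  (solo rate %.4g)\n",
              x$theta_second, x$scenario$p_second_solo))
  cat(sprintf("  delta        = %.6f rad\n", x$delta))
  cat(sprintf("  comparative second: fitted %.6f (observed %.4g)\n",
              comparative_probability(x$scenario$p_first_solo, x$x),
              x$scenario$p_second_comparative_observed))
  invisible(x)
}

#' @export
coef.order_fit <- function(object, ...) {
  c(theta_first = object$theta_first, theta_second = object$theta_second,
    delta = object$delta)
}

#' Model probabilities of an order-effect fit
#'
#' `type = "closed_form"` evaluates the analytic model; `type = "circuit"`
#' rebuilds the one- and two-qubit circuits, extracts exact statevector
#' conditionals via the conditioning-ratio protocol and combines them —
#' the two routes agree to numerical precision.
#'
#' @param object An `order_fit`.
#' @param type `"closed_form"` or `"circuit"`.
#' @param ... Unused.
#' @return Named vector: solo rates, the per-answer conditionals, and the
#'   comparative rate of the second question.
#' @export
predict.order_fit <- function(object, type = c("closed_form", "circuit"),
                              ...) {
  type <- match.arg(type)
  p1 <- object$scenario$p_first_solo
  if (type == "closed_form") {
    x <- object$x
    c(p_first_solo = p1,
      p_second_solo = angle_to_prob(object$theta_second),
      conditional_yes = x, conditional_no = 1 - x,
      p_second_comparative = comparative_probability(p1, x))
  } else {
    solo2 <- state_probabilities(
      run_circuit(build_noncomparative_circuit(object)), 0)[["0"]]
    solo1 <- state_probabilities(
      run_circuit(build_noncomparative_circuit(object, "first")), 0)[["0"]]
    cy <- comparative_conditional(object, "yes")
    cn <- comparative_conditional(object, "no")
    c(p_first_solo = solo1, p_second_solo = solo2,
      conditional_yes = cy, conditional_no = cn,
      p_second_comparative = p1 * cy + (1 - p1) * cn)
  }
}

#' @export
summary.order_fit <- function(object, ...) {
  out <- list(fit = object, predictions = predict(object),
              residual_first_comparative =
                if (!is.null(object$scenario$p_first_comparative_observed)) {
                  object$scenario$p_first_comparative_observed -
                    comparative_probability(object$scenario$p_second_solo,
                                            object$x)
                })
  class(out) <- "summary.order_fit"
  out
}

#' @export
print.summary.order_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  attainable comparative interval: [%.6f, %.6f]\n",
              x$fit$attainable[1], x$fit$attainable[2]))
  if (!is.null(x$residual_first_comparative)) {
    cat(sprintf(paste0("  reversed-order comparative (informational): ",
                       "model %.4f, residual %+.4f\n"),
                x$fit$scenario$p_first_comparative_observed -
                  x$residual_first_comparative,
                x$residual_first_comparative))
  }
  invisible(x)
}

#' Residuals of an order-effect fit
#'
#' The three fitted quantities have zero residual by construction; the
#' reversed-order comparative rate (if observed) is reported as an
#' informational residual, since the single-qubit model cannot fit it
#' independently when the second solo rate is one-half.
#'
#' @param object An `order_fit`.
#' @param ... Unused.
#' @return Named numeric vector of observed minus fitted values.
#' @export
residuals.order_fit <- function(object, ...) {
  sc <- object$scenario
  pr <- predict(object)
  out <- c(p_first_solo = sc$p_first_solo - pr[["p_first_solo"]],
           p_second_solo = sc$p_second_solo - pr[["p_second_solo"]],
           p_second_comparative = sc$p_second_comparative_observed -
             pr[["p_second_comparative"]])
  if (!is.null(sc$p_first_comparative_observed)) {
    out <- c(out, p_first_comparative = sc$p_first_comparative_observed -
               comparative_probability(sc$p_second_solo, object$x))
  }
  out
}

# gate list for the question-frame unitary U(theta, phase) (Y/Z Euler form),
# in circuit order (first gate applied first)
frame_gates <- function(theta, phase, qubit) {
  if (abs(phase) < 1e-15) return(list(qc_gate("RY", qubit, angle = 2 * theta)))
  list(qc_gate("RZ", qubit, angle = -phase),
       qc_gate("RY", qubit, angle = 2 * theta),
       qc_gate("RZ", qubit, angle = phase))
}

frame_gates_dagger <- function(theta, phase, qubit) {
  lapply(rev(frame_gates(theta, phase, qubit)), qc_gate_inverse)
}

# first -> second frame change on one qubit: apply U_first then U_second^dag
frame_change_gates <- function(fit, qubit) {
  c(frame_gates(fit$theta_first, 0, qubit),
    frame_gates_dagger(fit$theta_second, fit$delta, qubit))
}

#' Single-question (non-comparative) circuit
#'
#' One qubit: the inverse question-frame unitary of the requested question
#' is applied to \eqn{|0\rangle} and the qubit measured, so P(outcome 0)
#' equals that question's solo rate — independent of the Bloch phase.
#'
#' @param fit An [fit_order_model()] result.
#' @param question `"second"` (default; the headline non-comparative
#'   question) or `"first"`.
#' @return A `qc_circuit` on one qubit.
#' @examples
#' fit <- fit_order_model(order_scenario("cg", 0.68, 0.50, 0.57))
#' state_probabilities(run_circuit(build_noncomparative_circuit(fit)))
#' @export
build_noncomparative_circuit <- function(fit, question = c("second", "first")) {
  stopifnot(inherits(fit, "order_fit"))
  question <- match.arg(question)
  gates <- if (question == "second") {
    frame_gates_dagger(fit$theta_second, fit$delta, 0L)
  } else {
    frame_gates_dagger(fit$theta_first, 0, 0L)
  }
  qc_circuit(1L, gates, measure = 0L)
}

#' Comparative (ask-first-then-second) circuit via ancilla swap
#'
#' Two qubits stand in for mid-circuit measurement. q0 receives the inverse
#' first-question frame unitary (measuring it now would answer the first
#' question); the ancilla q1 is prepared \eqn{|0\rangle} (`first_answer =
#' "yes"`) or X-flipped to \eqn{|1\rangle} (`"no"`); the qubits are swapped;
#' q0 then receives the first-to-second frame-change unitary and both qubits
#' are measured. Conditioning on q1 equalling the inserted answer, the exact
#' conditional P(q0 = 0 | q1 = answer) equals the axis-to-axis transition
#' probability (yes) or its complement (no).
#'
#' @inheritParams build_noncomparative_circuit
#' @param first_answer `"yes"` or `"no"` — the answer inserted for the
#'   first question.
#' @return A `qc_circuit` on two qubits, both measured (q0 -> bit 0,
#'   q1 -> bit 1).
#' @export
build_comparative_circuit <- function(fit, first_answer = c("yes", "no")) {
  stopifnot(inherits(fit, "order_fit"))
  first_answer <- match.arg(first_answer)
  gates <- frame_gates_dagger(fit$theta_first, 0, 0L)
  if (first_answer == "no") gates <- c(gates, list(qc_gate("X", 1L)))
  gates <- c(gates, list(qc_gate("SWAP", c(0L, 1L))),
             frame_change_gates(fit, 0L))
  qc_circuit(2L, gates, measure = c(0L, 1L))
}

# exact statevector conditional for one comparative variant:
# P(q0 = 0 | q1 = inserted answer)
comparative_conditional <- function(fit, first_answer) {
  circ <- build_comparative_circuit(fit, first_answer)
  p <- state_probabilities(run_circuit(circ), circ$measure)
  cond <- if (first_answer == "yes") ".0" else ".1"
  conditional_from_counts(p, condition = cond, outcome = "0.")
}

#' Reconstruct the comparative rate from the two swap-circuit count tables
#'
#' Applies the conditioning-ratio protocol: from the yes-variant table, the
#' conditional P(q0 = 0 | q1 = 0); from the no-variant table,
#' P(q0 = 0 | q1 = 1) (the printed ratio #|01>/(#|01> + #|11>)); the two are
#' mixed with weights `p_first_solo` and `1 - p_first_solo`. With exact
#' probability tables instead of counts this equals
#' [comparative_probability()] at the fitted phase.
#'
#' @param fit An `order_fit`.
#' @param counts_yes,counts_no `qc_counts` tables from the matching
#'   [build_comparative_circuit()] variants (or named exact-probability
#'   vectors over bitstrings `q0q1`).
#' @return The reconstructed comparative agreement rate of the second
#'   question.
#' @examples
#' fit <- fit_order_model(order_scenario("cg", 0.68, 0.50, 0.57))
#' cy <- sample_counts(build_comparative_circuit(fit, "yes"), 10000, seed = 7)
#' cn <- sample_counts(build_comparative_circuit(fit, "no"), 10000, seed = 8)
#' reconstruct_comparative_rate(fit, cy, cn)
#' @export
reconstruct_comparative_rate <- function(fit, counts_yes, counts_no) {
  stopifnot(inherits(fit, "order_fit"))
  cond_yes <- conditional_from_counts(counts_yes, ".0", "0.")
  cond_no <- conditional_from_counts(counts_no, ".1", "0.")
  p1 <- fit$scenario$p_first_solo
  p1 * cond_yes + (1 - p1) * cond_no
}

#' Bias-activation variant of the comparative circuit
#'
#' Adds a third qubit q2 that controls the swap: q2 is prepared with
#' P(q2 = 1) = `activation`, and the swap becomes a controlled swap active
#' on q2 = 1. `activation = 1` reproduces [build_comparative_circuit()];
#' `activation = 0` leaves the swap inert so q0 reproduces the
#' non-comparative rate of the second question; intermediate activations
#' entangle the two behaviours.
#'
#' @inheritParams build_comparative_circuit
#' @param activation Probability in \[0, 1\] that the intermediate question
#'   is "asked" (the swap fires).
#' @return A `qc_circuit` on three qubits (q0, q1, q2 all measured).
#' @export
build_bias_circuit <- function(fit, first_answer = c("yes", "no"),
                               activation) {
  stopifnot(inherits(fit, "order_fit"))
  first_answer <- match.arg(first_answer)
  activation <- check_prob(activation, "activation")
  gates <- list(qc_gate("RY", 2L, angle = 2 * asin(sqrt(activation))))
  gates <- c(gates, frame_gates_dagger(fit$theta_first, 0, 0L))
  if (first_answer == "no") gates <- c(gates, list(qc_gate("X", 1L)))
  gates <- c(gates,
             list(qc_gate("SWAP", c(0L, 1L), controls = 2L, polarity = 1L)),
             frame_change_gates(fit, 0L))
  qc_circuit(3L, gates, measure = c(0L, 1L, 2L))
}

#' Simulate shot-sampled reconstructions from an order-effect fit
#'
#' Each simulation samples both comparative circuit variants with a fresh
#' derived seed and reconstructs the comparative rate from the counts.
#'
#' @param object An `order_fit`.
#' @param nsim Number of reconstructions.
#' @param seed Integer seed (each replicate uses `seed + i - 1`).
#' @param shots Shots per circuit (default 10000).
#' @param ... Unused.
#' @return Data frame with columns `seed`, `shots`,
#'   `p_second_comparative`.
#' @export
simulate.order_fit <- function(object, nsim = 1, seed = 1L, shots = 10000L,
                               ...) {
  vals <- numeric(nsim)
  seeds <- seed + seq_len(nsim) - 1L
  for (i in seq_len(nsim)) {
    cy <- sample_counts(build_comparative_circuit(object, "yes"), shots,
                        seed = seeds[i])
    cn <- sample_counts(build_comparative_circuit(object, "no"), shots,
                        seed = seeds[i] + 10000L)
    vals[i] <- reconstruct_comparative_rate(object, cy, cn)
  }
  data.frame(seed = seeds, shots = shots, p_second_comparative = vals)
}
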