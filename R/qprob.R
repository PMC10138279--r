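# Closed-form quantum-probability laws.
#
# The probability <-> angle convention used throughout is cos^2(theta) = P,
# i.e. theta = arccos(sqrt(P)) in [0, pi/2]. Rotation GATES use the standard
# half-angle convention, so a question axis at projection angle theta maps to
# a gate parameter 2*theta; that conversion happens in the circuit builders,
# never here.

check_prob <- function(p, what = deparse(substitute(p)), tol = 1e-12) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) ||
      p < -tol || p > 1 + tol) {
    stop(sprintf("'%s' must be a probability in [0, 1]", what), call. = FALSE)
  }
  min(max(p, 0), 1)
}

#' Probability/angle maps for projective yes-no questions
#'
#' `prob_to_angle()` returns the projection angle \eqn{\theta =
#' \arccos\sqrt{p} \in [0, \pi/2]} between a question axis and the state it
#' is asked of; `angle_to_prob()` is its inverse \eqn{\cos^2\theta}.
#'
#' @param p Probability in \[0, 1\].
#' @param theta Angle in radians, in \[0, pi/2\].
#' @return An angle in radians, or a probability.
#' @examples
#' prob_to_angle(0.50)  # 0.785
#' prob_to_angle(0.68)  # 0.601
#' angle_to_prob(pi / 4)
#' @export
prob_to_angle <- function(p) {
  p <- check_prob(p)
  acos(sqrt(p))
}

#' @rdname prob_to_angle
#' @export
angle_to_prob <- function(theta) {
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) ||
      theta < -1e-12 || theta > pi / 2 + 1e-12) {
    stop("'theta' must lie in [0, pi/2]", call. = FALSE)
  }
  cos(theta)^2
}

#' Conditional-probability specification for a two-event scenario
#'
#' Bundles \eqn{P(A)}, \eqn{P(B|A)} and \eqn{P(B|A')} — the ingredients of
#' the (classical or quantum) law of total probability for event B given a
#' binary event A.
#'
#' @param p_A Probability of event A.
#' @param p_B_given_A Probability of B given A.
#' @param p_B_given_notA Probability of B given not-A.
#' @return An object of class `conditional_spec`.
#' @examples
#' conditional_spec(0.5, 0.82, 0.72)
#' @export
conditional_spec <- function(p_A, p_B_given_A, p_B_given_notA) {
  structure(list(p_A = check_prob(p_A),
                 p_B_given_A = check_prob(p_B_given_A),
                 p_B_given_notA = check_prob(p_B_given_notA)),
            class = "conditional_spec")
}

#' @export
print.conditional_spec <- function(x, ...) {
  cat(sprintf("<conditional_spec: P(A)=%.4g  P(B|A)=%.4g  P(B|A')=%.4g>\n",
              x$p_A, x$p_B_given_A, x$p_B_given_notA))
  invisible(x)
}

as_conditional_spec <- function(x) {
  if (inherits(x, "conditional_spec")) return(x)
  if (inherits(x, "disjunction_scenario")) {
    return(conditional_spec(x$p_A, x$p_B_given_A, x$p_B_given_notA))
  }
  stop("expected a conditional_spec or disjunction_scenario", call. = FALSE)
}

#' Classical law of total probability
#'
#' \eqn{P(B) = P(B|A)P(A) + P(B|A')P(A')}.
#'
#' @param spec A [conditional_spec()] (or a disjunction scenario).
#' @return A probability.
#' @examples
#' classical_total_probability(conditional_spec(0.5, 0.82, 0.72))  # 0.77
#' @export
classical_total_probability <- function(spec) {
  s <- as_conditional_spec(spec)
  s$p_B_given_A * s$p_A + s$p_B_given_notA * (1 - s$p_A)
}

#' Can a total probability arise classically?
#'
#' Under the classical law of total probability, \eqn{P(B)} is a convex
#' combination of the two conditionals, so it must lie between them. Returns
#' `TRUE` iff `min(conditionals) <= p_B <= max(conditionals)`. The observed
#' Prisoner's Dilemma rates (0.64 against conditionals 0.82 and 0.72) fail
#' this test: no prior on the partner's choice can produce them.
#'
#' @param p_B Observed total probability of B.
#' @param p_B_given_A,p_B_given_notA The two conditionals.
#' @return Logical.
#' @examples
#' classical_feasibility(0.64, 0.82, 0.72)  # FALSE
#' classical_feasibility(0.77, 0.82, 0.72)  # TRUE
#' @export
classical_feasibility <- function(p_B, p_B_given_A, p_B_given_notA) {
  p_B <- check_prob(p_B)
  a <- check_prob(p_B_given_A, "p_B_given_A")
  b <- check_prob(p_B_given_notA, "p_B_given_notA")
  p_B >= min(a, b) && p_B <= max(a, b)
}

#' Interference term of the quantum law of total probability
#'
#' \eqn{\partial(A,B) = 2\sqrt{P(B|A)P(A)P(B|A')P(A')}\cos\varphi}, the
#' signed cross term by which quantum probability departs from the classical
#' law. \eqn{\varphi = \pi/2} switches interference off.
#'
#' @inheritParams classical_total_probability
#' @param phi Phase angle in radians.
#' @return A signed real in \[-1, 1\].
#' @examples
#' interference_term(conditional_spec(0.5, 0.82, 0.72), 0)
#' @export
interference_term <- function(spec, phi) {
  s <- as_conditional_spec(spec)
  2 * sqrt(s$p_B_given_A * s$p_A * s$p_B_given_notA * (1 - s$p_A)) * cos(phi)
}

#' Quantum law of total probability
#'
#' \eqn{P(B) = P(B|A)P(A) + P(B|A')P(A') + \partial(A,B)}. Parameter
#' combinations that push the result outside \[0, 1\] raise an error rather
#' than being clamped.
#'
#' @inheritParams interference_term
#' @return A probability.
#' @examples
#' s <- conditional_spec(0.5, 0.82, 0.72)
#' quantum_total_probability(s, pi / 2)  # classical value 0.77
#' @export
quantum_total_probability <- function(spec, phi) {
  p <- classical_total_probability(spec) + interference_term(spec, phi)
  if (p < -1e-9 || p > 1 + 1e-9) {
    stop(sprintf(paste0("invalid parameters: quantum total probability %.6f ",
                        "falls outside [0, 1]"), p), call. = FALSE)
  }
  min(max(p, 0), 1)
}

#' Solve the interference phase from an observed total probability
#'
#' Inverts the quantum law of total probability for \eqn{\varphi}:
#' \eqn{\cos\varphi = (P(B) - P_{cl}(B)) / 2\sqrt{P(B|A)P(A)P(B|A')P(A')}}.
#' The canonical root in \[0, pi\] is returned (the mirrored root
#' \eqn{-\varphi} is equivalent because cosine is even).
#'
#' @inheritParams classical_total_probability
#' @param target_p_B The observed total probability to be reproduced.
#' @return Phase in radians, in \[0, pi\].
#' @examples
#' solve_phase(conditional_spec(0.5, 0.82, 0.72), 0.64)  # about 1.741
#' @export
solve_phase <- function(spec, target_p_B) {
  s <- as_conditional_spec(spec)
  target_p_B <- check_prob(target_p_B)
  classical <- classical_total_probability(s)
  amp <- 2 * sqrt(s$p_B_given_A * s$p_A * s$p_B_given_notA * (1 - s$p_A))
  lo <- max(classical - amp, 0); hi <- min(classical + amp, 1)
  if (amp == 0) {
    if (abs(target_p_B - classical) < 1e-9) return(pi / 2)
    stop(sprintf("target %.6f unattainable: only %.6f is reachable",
                 target_p_B, classical), call. = FALSE)
  }
  co <- (target_p_B - classical) / amp
  if (co < -1 - 1e-9 || co > 1 + 1e-9) {
    stop(sprintf("target %.6f unattainable: attainable interval is [%.6f, %.6f]",
                 target_p_B, lo, hi), call. = FALSE)
  }
  acos(min(max(co, -1), 1))
}

#' Sequential-projection ("&then") probability
#'
#' Probability of affirming a first question and then a second:
#' the product \eqn{P(A)\,P(B|A)}, which can never exceed \eqn{P(A)} but can
#' exceed \eqn{P(B)} — the signature of non-commuting projections. With
#' \eqn{P(B) = 1/2} and \eqn{P(A|B) = 1/2} the chained value is exactly 1/4
#' (the "quarter law").
#'
#' @param p_first Probability of affirming the first question.
#' @param p_second_given_first Probability of then affirming the second.
#' @return A probability, at most `p_first`.
#' @examples
#' and_then(0.5, 0.5)  # 0.25
#' @export
and_then <- function(p_first, p_second_given_first) {
  check_prob(p_first) * check_prob(p_second_given_first)
}

# single-qubit axis state at polar projection angle theta, azimuthal phase
# phase: cos(theta)|0> + e^{i phase} sin(theta)|1>
bloch_axis_state <- function(theta, phase = 0) {
  c(cos(theta) + 0i, exp(1i * phase) * sin(theta))
}

check_polar <- function(theta, what) {
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) ||
      theta < -1e-12 || theta > pi / 2 + 1e-12) {
    stop(sprintf("'%s' must lie in [0, pi/2]", what), call. = FALSE)
  }
  theta
}

#' Transition probability between two question axes on the Bloch sphere
#'
#' For axes at polar projection angles `theta1`, `theta2` with relative
#' azimuthal phase `delta`, the squared overlap of the corresponding
#' single-qubit states:
#' \deqn{x = \cos^2\theta_1\cos^2\theta_2 + \sin^2\theta_1\sin^2\theta_2
#'       + 2\cos\theta_1\cos\theta_2\sin\theta_1\sin\theta_2\cos\delta.}
#' `delta = 0` collapses to the planar \eqn{\cos^2(\theta_2-\theta_1)};
#' `delta = pi` to \eqn{\cos^2(\theta_2+\theta_1)}.
#'
#' @param theta1,theta2 Polar projection angles in \[0, pi/2\].
#' @param delta Relative phase in radians.
#' @return A probability.
#' @examples
#' bloch_transition_probability(0.601, 0.785, 0)  # cos^2 of the angle gap
#' @export
bloch_transition_probability <- function(theta1, theta2, delta) {
  check_polar(theta1, "theta1"); check_polar(theta2, "theta2")
  c1 <- cos(theta1); s1 <- sin(theta1)
  c2 <- cos(theta2); s2 <- sin(theta2)
  c1^2 * c2^2 + s1^2 * s2^2 + 2 * c1 * c2 * s1 * s2 * cos(delta)
}

#' Two-path comparative answer probability
#'
#' Unconditional probability of affirming the second question after the
#' first has been asked (and answered either way):
#' \eqn{p_1 x + (1-p_1)(1-x)}, where `x` is the axis-to-axis transition
#' probability and the complement path uses the single-qubit rule
#' \eqn{|\langle B|A'\rangle|^2 = 1 - |\langle B|A\rangle|^2}.
#' Note the identity `comparative_probability(0.5, x) = 0.5` for every `x`:
#' a first question answered at rate one-half pins the comparative rate of
#' the second question, whatever the phase.
#'
#' @param p_first Solo probability of affirming the first question.
#' @param x Transition probability between the two question axes.
#' @return A probability.
#' @examples
#' comparative_probability(0.68, bloch_transition_probability(0.601, 0.785, 0))
#' @export
comparative_probability <- function(p_first, x) {
  p_first <- check_prob(p_first); x <- check_prob(x)
  p_first * x + (1 - p_first) * (1 - x)
}

#' Question-order symmetry gap (QQ-equality)
#'
#' The difference \eqn{[P(A\,\mathrm{yes\,\&then}\,B\,\mathrm{yes}) +
#' P(A\,\mathrm{no\,\&then}\,B\,\mathrm{no})]} minus the same sum with the
#' questions asked in the reverse order, computed from explicit single-qubit
#' axis states. For this model the gap is identically zero — the QQ-equality
#' that holds with striking accuracy in survey data.
#'
#' @inheritParams bloch_transition_probability
#' @return A signed real (0 up to rounding for this model).
#' @examples
#' qq_gap(0.601, 0.785, 1.14)
#' @export
qq_gap <- function(theta1, theta2, delta) {
  check_polar(theta1, "theta1"); check_polar(theta2, "theta2")
  start <- c(1 + 0i, 0i)
  a_yes <- bloch_axis_state(theta1, 0)
  a_no <- c(-sin(theta1) + 0i, cos(theta1) + 0i)
  b_yes <- bloch_axis_state(theta2, delta)
  b_no <- c(-exp(-1i * delta) * sin(theta2), cos(theta2) + 0i)
  ov <- function(u, v) Mod(sum(Conj(u) * v))^2
  fwd <- ov(a_yes, start) * ov(b_yes, a_yes) + ov(a_no, start) * ov(b_no, a_no)
  rev <- ov(b_yes, start) * ov(a_yes, b_yes) + ov(b_no, start) * ov(a_no, b_no)
  fwd - rev
}
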