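# Disjunction-effect circuits: Bayesian baseline, interference kernel,
# phase fitting, and the full four-qubit circuit.

pd <- function() disjunction_scenario("pd", 0.5, 0.82, 0.72, 0.64)

test_that("event preparation and the conditional component hit their branch rates", {
  expect_equal(state_probabilities(
    run_circuit(qc_circuit(1, build_event_prep(0.82, 0))), 0)[["0"]],
    0.82, tolerance = 1e-12)
  expect_equal(state_probabilities(
    run_circuit(qc_circuit(1, build_event_prep(0.5, 0))), 0)[["0"]],
    0.5, tolerance = 1e-12)
  # p = 1 is an identity-equivalent rotation (angle 0)
  prep1 <- build_event_prep(1, 0)
  expect_equal(prep1[[1]]$angle, 0)

  comp <- build_conditional_component(0.82, 0.72, 0, 1)
  # control |0> branch
  p0 <- state_probabilities(run_circuit(qc_circuit(2, comp)), 1)[["0"]]
  expect_equal(p0, 0.82, tolerance = 1e-12)
  # control |1> branch
  p1 <- state_probabilities(run_circuit(
    qc_circuit(2, c(list(qc_gate("X", 0)), comp))), 1)[["0"]]
  expect_equal(p1, 0.72, tolerance = 1e-12)
  expect_error(build_conditional_component(0.8, 0.7, 1, 1), "must differ")
})

test_that("the Bayesian circuit obeys the classical law of total probability", {
  expect_equal(state_probabilities(run_circuit(build_bayes_circuit(pd())),
                                   1)[["0"]],
               0.77, tolerance = 1e-9)
  sure <- disjunction_scenario("sure", 1, 0.82, 0.72, 0.8)
  expect_equal(state_probabilities(run_circuit(build_bayes_circuit(sure)),
                                   1)[["0"]],
               0.82, tolerance = 1e-9)
  for (seed in 1:100) {
    sc <- generate_random_scenario("disjunction", seed)
    got <- state_probabilities(run_circuit(build_bayes_circuit(sc)), 1)[["0"]]
    expect_equal(got, classical_total_probability(sc), tolerance = 1e-9)
  }
})

test_that("the Hadamard interference kernel spans [0, 1/2] and idles correctly", {
  kernel_p1 <- function(phi, control_state = "uniform") {
    prep <- switch(control_state,
                   uniform = list(qc_gate("H", 0)),
                   zero = list(),
                   one = list(qc_gate("X", 0)))
    circ <- qc_circuit(2, c(prep, build_interference_kernel(phi, 0, 1)))
    state_probabilities(run_circuit(circ), 1)[["1"]]
  }
  expect_equal(kernel_p1(0), 0, tolerance = 1e-12)          # H then H = I
  expect_equal(kernel_p1(pi), 0.5, tolerance = 1e-12)       # half sin^2(pi/2)
  for (phi in seq(0, 2 * pi, length.out = 17)) {
    p <- kernel_p1(phi)
    expect_equal(p, 0.5 * sin(phi / 2)^2, tolerance = 1e-9)
    expect_lte(p, 0.5 + 1e-12)
    # inactive control polarity: the kernel is the identity for every phase
    expect_equal(kernel_p1(phi, "zero"), 0, tolerance = 1e-12)
  }
  expect_error(build_interference_kernel(1, 0, 0), "must differ")
})

test_that("the full circuit reproduces the closed form for the unknown condition", {
  expect_equal(closed_form_unknown(pd(), 0), 0.77, tolerance = 1e-12)
  expect_equal(closed_form_unknown(pd(), pi), 0.55, tolerance = 1e-12)
  set.seed(77)
  for (seed in 101:200) {
    sc <- generate_random_scenario("disjunction", seed)
    phi <- stats::runif(1, 0, 2 * pi)
    circ <- build_full_circuit(sc, "unknown", phi = phi)
    got <- state_probabilities(run_circuit(circ), 1)[["0"]]
    expect_equal(got, closed_form_unknown(sc, phi), tolerance = 1e-9)
  }
  # mirrored control polarity modulates the other branch
  sc <- pd()
  circ <- build_full_circuit(sc, "unknown", phi = 1.3, control_polarity = 0L)
  expect_equal(state_probabilities(run_circuit(circ), 1)[["0"]],
               closed_form_unknown(sc, 1.3, control_polarity = 0L),
               tolerance = 1e-9)
})

test_that("phase fitting inverts the closed form and flags unattainable rates", {
  fit <- fit_phase(pd())
  expect_equal(fit$phi, 1.75363146379, tolerance = 1e-9)
  expect_equal(closed_form_unknown(pd(), fit$phi), 0.64, tolerance = 1e-9)
  # observing the classical value means no interference
  fit0 <- fit_phase(disjunction_scenario("cl", 0.5, 0.82, 0.72, 0.77))
  expect_equal(fit0$phi, 0, tolerance = 1e-9)
  expect_error(fit_phase(disjunction_scenario("bad", 0.5, 0.82, 0.72, 0.50)),
               "attainable interval")
  for (seed in 201:240) {
    sc <- generate_random_scenario("disjunction", seed)
    f <- fit_phase(sc)
    expect_gte(f$phi, 0); expect_lte(f$phi, pi)
    expect_equal(closed_form_unknown(sc, f$phi), sc$p_B_unknown_observed,
                 tolerance = 1e-9)
  }
})

test_that("the measurement component inserts pure outcomes and resets event 2", {
  expect_length(build_measurement_component("none"), 0)
  expect_error(build_measurement_component("betray", 0, 1, 2, 2), "distinct")
  fit <- fit_phase(pd())
  for (known in c("betray", "cooperate")) {
    circ <- build_full_circuit(fit, known)
    # strip the trailing conditional component: after the swaps, event 1
    # must be exactly the inserted pure state and event 2 exactly |0>
    trimmed <- qc_circuit(4, circ$gates[seq_len(length(circ$gates) - 2L)],
                          measure = circ$measure)
    p <- state_probabilities(run_circuit(trimmed), c(0L, 1L))
    want <- if (known == "betray") "00" else "10"
    expect_equal(p[[want]], 1, tolerance = 1e-9)
  }
})

test_that("the full Prisoner's Dilemma circuit reproduces all three conditions", {
  fit <- fit_phase(pd())
  pr <- predict(fit, type = "circuit")
  expect_equal(unname(pr), c(0.82, 0.72, 0.64), tolerance = 1e-9)
  # phi = 0 limit of the unknown condition equals the classical circuit
  circ0 <- build_full_circuit(pd(), "unknown", phi = 0)
  expect_equal(state_probabilities(run_circuit(circ0), 1)[["0"]], 0.77,
               tolerance = 1e-9)
  # the fitted scenario shows a genuine sure-thing violation
  expect_lt(pr[["unknown"]], min(pr[["betray"]], pr[["cooperate"]]))
  expect_false(classical_feasibility(0.64, 0.82, 0.72))
})

test_that("known-condition outputs are phase-invariant (reset kills interference)", {
  sc <- pd()
  for (phi in seq(0, 2 * pi, length.out = 9)) {
    expect_equal(state_probabilities(
      run_circuit(build_full_circuit(sc, "betray", phi = phi)), 1)[["0"]],
      0.82, tolerance = 1e-9)
    expect_equal(state_probabilities(
      run_circuit(build_full_circuit(sc, "cooperate", phi = phi)), 1)[["0"]],
      0.72, tolerance = 1e-9)
  }
})

test_that("event preparation axis (X vs Y) leaves every output unchanged", {
  fit <- fit_phase(pd())
  for (cond in c("betray", "cooperate", "unknown")) {
    py <- state_probabilities(
      run_circuit(build_full_circuit(fit, cond, axis = "Y")), 1)[["0"]]
    px <- state_probabilities(
      run_circuit(build_full_circuit(fit, cond, axis = "X")), 1)[["0"]]
    expect_equal(px, py, tolerance = 1e-9)
  }
  expect_equal(state_probabilities(
    run_circuit(build_bayes_circuit(pd(), axis = "X")), 1)[["0"]],
    0.77, tolerance = 1e-9)
})

test_that("phase sweeps are periodic, even, and CSV-able", {
  sc <- pd()
  sw <- phase_sweep(sc, c(0, pi / 2, pi))
  expect_equal(sw$probability, c(0.77, 0.66, 0.55), tolerance = 1e-9)
  # 2*pi-periodic and even in phi (cos^2 dependence)
  grid <- seq(0.3, 2.9, length.out = 7)
  expect_equal(phase_sweep(sc, grid)$probability,
               phase_sweep(sc, grid + 2 * pi)$probability, tolerance = 1e-9)
  expect_equal(phase_sweep(sc, grid)$probability,
               phase_sweep(sc, -grid)$probability, tolerance = 1e-9)
  # flat when the two branch rates coincide
  # P(B|A') = 1/2 makes the modulated branch inert: a flat sweep
  flat <- disjunction_scenario("flat", 0.5, 0.6, 0.5, 0.57)
  expect_lt(stats::sd(phase_sweep(flat, grid)$probability), 1e-12)
  expect_error(phase_sweep(sc, numeric(0)), "nonempty")
})

test_that("simulated condition rates stay within five shot-noise levels", {
  fit <- fit_phase(pd())
  sim <- simulate(fit, nsim = 1, seed = 9L, shots = 10000L)
  expected <- c(betray = 0.82, cooperate = 0.72, unknown = 0.64)
  for (k in seq_len(nrow(sim))) {
    e <- expected[[sim$condition[k]]]
    expect_lt(abs(sim$rate[k] - e), 5 * sqrt(e * (1 - e) / 10000))
  }
})
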