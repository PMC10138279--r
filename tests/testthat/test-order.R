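# Order-effect model: fitting, circuits, ancilla-swap reconstruction.

cg_fit <- function() fit_order_model(order_scenario("cg", 0.68, 0.50, 0.57,
                                                    0.60))

test_that("fitting recovers the printed angles and the comparative phase", {
  fit <- cg_fit()
  expect_equal(unname(coef(fit)),
               c(0.601264216679, 0.785398163397, 1.14083369151),
               tolerance = 1e-6)
  expect_equal(predict(fit)[["p_second_comparative"]], 0.57,
               tolerance = 1e-9)
  # an observed rate equal to the zero-phase prediction fits delta = 0
  fit0 <- fit_order_model(order_scenario("cg0", 0.68, 0.50, 0.667931414572))
  expect_equal(fit0$delta, 0, tolerance = 1e-6)
  # unattainable observed rate: range error naming the interval
  expect_error(fit_order_model(order_scenario("bad", 0.68, 0.50, 0.99)),
               "attainable interval")
  # first solo rate of one-half leaves the phase unidentified
  expect_error(fit_order_model(order_scenario("deg", 0.50, 0.68, 0.60)),
               "not identifiable")
})

test_that("solo circuits reproduce the solo rates independently of the phase", {
  fit <- cg_fit()
  expect_equal(state_probabilities(
    run_circuit(build_noncomparative_circuit(fit)), 0)[["0"]], 0.50,
    tolerance = 1e-9)
  expect_equal(state_probabilities(
    run_circuit(build_noncomparative_circuit(fit, "first")), 0)[["0"]], 0.68,
    tolerance = 1e-9)
  # vary delta with the same thetas: the solo rate must not move
  for (delta in c(0, 0.7, 2.1)) {
    f2 <- fit
    f2$delta <- delta
    expect_equal(state_probabilities(
      run_circuit(build_noncomparative_circuit(f2)), 0)[["0"]], 0.50,
      tolerance = 1e-9)
  }
  # degenerate scenario: certain agreement (comparative rate is then pinned
  # at the classical two-path value 0.8*0.8 + 0.2*0.2 = 0.68)
  fsure <- fit_order_model(order_scenario("sure", 0.8, 1, 0.68))
  expect_equal(state_probabilities(
    run_circuit(build_noncomparative_circuit(fsure)), 0)[["0"]], 1,
    tolerance = 1e-9)
})

test_that("swap-circuit conditionals equal the Bloch transition law", {
  fit <- cg_fit()
  expect_equal(qcog:::comparative_conditional(fit, "yes"), 0.694444444444,
               tolerance = 1e-9)
  expect_equal(qcog:::comparative_conditional(fit, "no"), 0.305555555556,
               tolerance = 1e-9)
  # property sweep over random fitted scenarios
  for (seed in 1:30) {
    sc <- generate_random_scenario("order", seed)
    f <- fit_order_model(sc)
    x <- bloch_transition_probability(f$theta_first, f$theta_second, f$delta)
    expect_equal(qcog:::comparative_conditional(f, "yes"), x,
                 tolerance = 1e-9)
    expect_equal(qcog:::comparative_conditional(f, "no"), 1 - x,
                 tolerance = 1e-9)
  }
  # identical questions answered yes: certainty
  fid <- fit_order_model(order_scenario("same", 0.68, 0.68, 0.68))
  expect_equal(fid$delta, 0, tolerance = 1e-6)
  expect_equal(qcog:::comparative_conditional(fid, "yes"), 1,
               tolerance = 1e-9)
})

test_that("the swap protocol matches a projective mid-measurement oracle", {
  for (seed in 31:55) {
    sc <- generate_random_scenario("order", seed)
    f <- fit_order_model(sc)
    for (ans in c("yes", "no")) {
      expect_equal(qcog:::comparative_conditional(f, ans),
                   projective_oracle_conditional(f$theta_first,
                                                 f$theta_second, f$delta,
                                                 ans),
                   tolerance = 1e-9)
    }
  }
})

test_that("the reconstructed comparative rate recovers the observed value", {
  fit <- cg_fit()
  # exact-probability route
  exact_tab <- function(ans) {
    circ <- build_comparative_circuit(fit, ans)
    state_probabilities(run_circuit(circ), circ$measure)
  }
  expect_equal(reconstruct_comparative_rate(fit, exact_tab("yes"),
                                            exact_tab("no")),
               0.57, tolerance = 1e-9)
  # forcing delta = 0 recovers the planar two-path prediction
  f0 <- fit
  f0$delta <- 0
  exact0 <- function(ans) {
    circ <- build_comparative_circuit(f0, ans)
    state_probabilities(run_circuit(circ), circ$measure)
  }
  expect_equal(reconstruct_comparative_rate(f0, exact0("yes"), exact0("no")),
               0.667931414572, tolerance = 1e-9)
  # sampled route at 10,000 shots stays within five shot-noise levels
  cy <- sample_counts(build_comparative_circuit(fit, "yes"), 10000, seed = 1)
  cn <- sample_counts(build_comparative_circuit(fit, "no"), 10000, seed = 2)
  rate <- reconstruct_comparative_rate(fit, cy, cn)
  expect_lt(abs(rate - 0.57), 5 * sqrt(0.57 * 0.43 / 10000))
})

test_that("question order matters: A-then-B differs from B-then-A generically", {
  fit <- cg_fit()
  # asking first shifts the second question's rate away from its solo value
  # for every phase except the one where the transition probability is 1/2
  for (delta in seq(0, pi, length.out = 21)) {
    x <- bloch_transition_probability(fit$theta_first, fit$theta_second,
                                      delta)
    comp <- comparative_probability(fit$scenario$p_first_solo, x)
    if (abs(x - 0.5) > 1e-3) {
      expect_gt(abs(comp - fit$scenario$p_second_solo), 1e-5)
    } else {
      expect_lt(abs(comp - fit$scenario$p_second_solo), 1e-2)
    }
    # while the both-yes-plus-both-no sums still satisfy QQ-equality
    expect_lt(abs(qq_gap(fit$theta_first, fit$theta_second, delta)), 1e-9)
  }
})

test_that("bias activation interpolates between solo and comparative behaviour", {
  fit <- cg_fit()
  # activation 0: swap inert, q0 shows the solo second-question rate
  c0 <- build_bias_circuit(fit, "yes", activation = 0)
  expect_equal(state_probabilities(run_circuit(c0), 0)[["0"]], 0.50,
               tolerance = 1e-9)
  # activation 1: reduces to the plain comparative circuit on (q0, q1)
  c1 <- build_bias_circuit(fit, "no", activation = 1)
  ref <- build_comparative_circuit(fit, "no")
  expect_equal(state_probabilities(run_circuit(c1), c(0L, 1L)),
               state_probabilities(run_circuit(ref), c(0L, 1L)),
               tolerance = 1e-9)
  # intermediate activation: no closed form asserted; dense oracle instead
  ch <- build_bias_circuit(fit, "yes", activation = 0.5)
  expect_equal(run_circuit(ch)$amplitudes, oracle_run(ch), tolerance = 1e-9)
  expect_error(build_bias_circuit(fit, "yes", activation = 1.2),
               "probability")
})

test_that("simulate() returns seeded reconstructions near the target", {
  fit <- cg_fit()
  sims <- simulate(fit, nsim = 3, seed = 100L, shots = 5000L)
  expect_equal(nrow(sims), 3L)
  expect_true(all(abs(sims$p_second_comparative - 0.57) <
                    5 * sqrt(0.25 / 5000) + 0.01))
  sims2 <- simulate(fit, nsim = 3, seed = 100L, shots = 5000L)
  expect_identical(sims, sims2)
})
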