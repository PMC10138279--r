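# Closed-form quantum-probability laws.

test_that("probability/angle maps invert each other and hit the printed angles", {
  expect_equal(prob_to_angle(0.50), 0.785398163397, tolerance = 1e-9)
  expect_equal(prob_to_angle(0.68), 0.601264216679, tolerance = 1e-9)
  expect_equal(prob_to_angle(1), 0)
  expect_equal(prob_to_angle(0), pi / 2)
  expect_equal(angle_to_prob(pi / 4), 0.5, tolerance = 1e-12)
  expect_equal(angle_to_prob(0), 1)
  for (p in seq(0, 1, by = 0.05)) {
    expect_equal(angle_to_prob(prob_to_angle(p)), p, tolerance = 1e-12)
  }
  expect_error(prob_to_angle(1.2), "probability")
  expect_error(angle_to_prob(2), "pi/2")
})

test_that("classical law of total probability and feasibility behave", {
  s <- conditional_spec(0.5, 0.82, 0.72)
  expect_equal(classical_total_probability(s), 0.77, tolerance = 1e-12)
  expect_equal(classical_total_probability(conditional_spec(1, 0.3, 0.9)),
               0.3)
  expect_equal(classical_total_probability(conditional_spec(0.37, 0.6, 0.6)),
               0.6)
  # the observed unknown-condition rate lies outside both conditionals:
  # infeasible under any prior
  expect_false(classical_feasibility(0.64, 0.82, 0.72))
  expect_true(classical_feasibility(0.77, 0.82, 0.72))
  expect_true(classical_feasibility(0.82, 0.82, 0.72))  # boundary
})

test_that("interference term and quantum total probability follow the phase", {
  s <- conditional_spec(0.5, 0.82, 0.72)
  expect_equal(interference_term(s, pi / 2), 0, tolerance = 1e-12)
  expect_equal(interference_term(s, 0), 0.768374908492, tolerance = 1e-9)
  expect_equal(interference_term(conditional_spec(0, 0.4, 0.6), 0), 0)
  expect_equal(quantum_total_probability(s, pi / 2),
               classical_total_probability(s), tolerance = 1e-12)
  expect_equal(quantum_total_probability(s, 1.74080230597), 0.64,
               tolerance = 1e-9)
  # phi = 0 would push P(B) to 0.77 + 0.768...: an error, never a clamp
  expect_error(quantum_total_probability(s, 0), "outside")
})

test_that("solve_phase inverts the law and reports attainable ranges", {
  s <- conditional_spec(0.5, 0.82, 0.72)
  expect_equal(solve_phase(s, 0.64), 1.74080230597, tolerance = 1e-9)
  expect_equal(solve_phase(s, classical_total_probability(s)), pi / 2,
               tolerance = 1e-12)
  expect_error(solve_phase(s, 0.0), "attainable")
  # round trip over random feasible targets
  set.seed(42)
  for (i in 1:50) {
    sp <- conditional_spec(runif(1), runif(1), runif(1))
    cl <- classical_total_probability(sp)
    amp <- interference_term(sp, 0)
    lo <- max(cl - amp, 0); hi <- min(cl + amp, 1)
    target <- runif(1, lo, hi)
    phi <- solve_phase(sp, target)
    expect_gte(phi, 0); expect_lte(phi, pi)
    expect_equal(quantum_total_probability(sp, phi), target,
                 tolerance = 1e-9)
  }
})

test_that("sequential projection obeys the quarter law and its inequalities", {
  # orthogonal start and target with a 45-degree stepping stone: exactly 1/4
  expect_identical(and_then(0.5, 0.5), 0.25)
  expect_equal(and_then(0, 0.9), 0)
  expect_equal(and_then(0.3, 1), 0.3)
  # P(A &then B) <= P(A), always
  set.seed(7)
  for (i in 1:100) {
    pa <- runif(1); pba <- runif(1)
    expect_lte(and_then(pa, pba), pa)
  }
  # ...but P(A &then B) can exceed P(B): start |0>, B = |1>, A at 45 degrees
  p_b_direct <- 0                      # |<1|0>|^2
  p_a <- angle_to_prob(pi / 4)         # 1/2
  p_b_given_a <- sin(pi / 4)^2         # 1/2
  expect_gt(and_then(p_a, p_b_given_a), p_b_direct)
  # stepping-stone inequality: the chained projection is never smaller
  for (i in 1:100) {
    th <- sort(runif(2, 0, pi / 2))
    expect_gte(cos(th[1])^2 * cos(th[2] - th[1])^2 + 1e-12, cos(th[2])^2)
  }
})

test_that("Bloch transition probability matches single-qubit overlaps", {
  # planar limits via double-angle identities
  expect_equal(bloch_transition_probability(0.3, 0.9, 0), cos(0.6)^2,
               tolerance = 1e-12)
  expect_equal(bloch_transition_probability(0.3, 0.9, pi), cos(1.2)^2,
               tolerance = 1e-12)
  # general case equals |<b|a>|^2 of the explicit axis states
  set.seed(13)
  for (i in 1:50) {
    th1 <- runif(1, 0, pi / 2); th2 <- runif(1, 0, pi / 2)
    dl <- runif(1, 0, 2 * pi)
    a <- c(cos(th1), sin(th1)) + 0i
    b <- c(cos(th2) + 0i, exp(1i * dl) * sin(th2))
    expect_equal(bloch_transition_probability(th1, th2, dl),
                 Mod(sum(Conj(b) * a))^2, tolerance = 1e-9)
  }
})

test_that("comparative probability mixes the two paths and pins 1/2", {
  x0 <- bloch_transition_probability(0.601264216679, 0.785398163397, 0)
  expect_equal(comparative_probability(0.68, x0), 0.667931414572,
               tolerance = 1e-9)
  expect_equal(comparative_probability(0.9, 1), 0.9)
  # algebraic identity: a first rate of one-half pins the comparative rate
  for (x in seq(0, 1, by = 0.1)) {
    expect_equal(comparative_probability(0.5, x), 0.5, tolerance = 1e-12)
  }
})

test_that("the question-order symmetry gap vanishes identically", {
  expect_equal(qq_gap(0.601, 0.785, 0), 0, tolerance = 1e-9)
  expect_equal(qq_gap(0.4, 0.4, 1.3), 0, tolerance = 1e-9)
  set.seed(21)
  for (i in 1:100) {
    expect_lt(abs(qq_gap(runif(1, 0, pi / 2), runif(1, 0, pi / 2),
                         runif(1, 0, 2 * pi))), 1e-9)
  }
})
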