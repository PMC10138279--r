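# Independent oracles and fixture generators for the test suite.

# ---- dense-matrix oracle -------------------------------------------------
# Full 2^n x 2^n gate matrices built from Kronecker products, independent of
# the simulator's stride-update path. Qubit 0 is the first (most
# significant) Kronecker factor, matching the package's bit ordering.

oracle_single_matrix <- function(kind, angle = NULL) {
  switch(kind,
    H  = matrix(c(1, 1, 1, -1), 2, 2) / sqrt(2) + 0i,
    X  = matrix(c(0, 1, 1, 0), 2, 2) + 0i,
    RX = matrix(c(cos(angle / 2), -1i * sin(angle / 2),
                  -1i * sin(angle / 2), cos(angle / 2)), 2, 2, byrow = TRUE),
    RY = matrix(c(cos(angle / 2), -sin(angle / 2),
                  sin(angle / 2), cos(angle / 2)), 2, 2, byrow = TRUE) + 0i,
    RZ = diag(c(exp(-1i * angle / 2), exp(1i * angle / 2))))
}

# I + kron-factors trick: identity off the control-matching subspace,
# (M - I) on the target within it
oracle_controlled_single <- function(n, m2, target, controls = integer(0),
                                     polarity = integer(0)) {
  p0 <- matrix(c(1, 0, 0, 0), 2, 2) + 0i
  p1 <- matrix(c(0, 0, 0, 1), 2, 2) + 0i
  factors <- rep(list(diag(2) + 0i), n)
  for (k in seq_along(controls)) {
    factors[[controls[k] + 1L]] <- if (polarity[k] == 1L) p1 else p0
  }
  factors[[target + 1L]] <- m2 - diag(2)
  diag(2^n) + Reduce(kronecker, factors)
}

oracle_gate_matrix <- function(n, gate) {
  if (gate$kind == "SWAP") {
    t1 <- gate$targets[1]; t2 <- gate$targets[2]
    x <- oracle_single_matrix("X")
    cnot <- function(ctrl, tgt) {
      oracle_controlled_single(n, x, tgt,
                               controls = c(ctrl, gate$controls),
                               polarity = c(1L, gate$polarity))
    }
    cnot(t1, t2) %*% cnot(t2, t1) %*% cnot(t1, t2)
  } else {
    oracle_controlled_single(n, oracle_single_matrix(gate$kind, gate$angle),
                             gate$targets, gate$controls, gate$polarity)
  }
}

oracle_run <- function(circuit) {
  v <- complex(2^circuit$n_qubits)
  v[1] <- 1
  for (g in circuit$gates) v <- oracle_gate_matrix(circuit$n_qubits, g) %*% v
  as.vector(v)
}

# ---- random circuit generator -------------------------------------------
pick <- function(x, k = 1L) x[sample.int(length(x), k)]

random_circuit <- function(seed, n_qubits = NULL, n_gates = NULL) {
  set.seed(seed)
  if (is.null(n_qubits)) n_qubits <- pick(1:3)
  if (is.null(n_gates)) n_gates <- pick(3:8)
  gates <- vector("list", n_gates)
  for (i in seq_len(n_gates)) {
    kinds <- c("RX", "RY", "RZ", "H", "X", if (n_qubits >= 2) "SWAP")
    kind <- pick(kinds)
    n_targ <- if (kind == "SWAP") 2L else 1L
    targets <- pick(0:(n_qubits - 1L), n_targ)
    free <- setdiff(0:(n_qubits - 1L), targets)
    n_ctl <- if (length(free)) pick(0:1) else 0L
    controls <- if (n_ctl) pick(free, n_ctl) else integer(0)
    gates[[i]] <- qc_gate(kind, targets,
                          angle = if (kind %in% c("RX", "RY", "RZ")) {
                            stats::runif(1, -pi, pi)
                          },
                          controls = controls,
                          polarity = if (n_ctl) pick(c(0L, 1L)) else
                                     integer(0))
  }
  qc_circuit(n_qubits, gates)
}

# ---- mid-circuit projective-measurement oracle ---------------------------
# Measure the first question by explicit projection + renormalisation on a
# single qubit, then measure the second; no circuits involved.
projective_oracle_conditional <- function(theta1, theta2, delta,
                                          first_answer) {
  first_yes <- c(cos(theta1), sin(theta1)) + 0i
  first_no <- c(-sin(theta1), cos(theta1)) + 0i
  second_yes <- c(cos(theta2) + 0i, exp(1i * delta) * sin(theta2))
  answer_state <- if (first_answer == "yes") first_yes else first_no
  # collapse: the post-measurement state IS the answer axis (renormalised
  # projection of any state with nonzero overlap)
  start <- c(1 + 0i, 0i)
  proj <- sum(Conj(answer_state) * start) * answer_state
  norm <- sqrt(sum(Mod(proj)^2))
  if (norm < 1e-14) return(NA_real_)
  post <- proj / norm
  Mod(sum(Conj(second_yes) * post))^2
}

# ---- minimal OpenQASM 2.0 structural validator ---------------------------
# Token-level check: header, register declarations, and every statement a
# known qelib1 gate applied to in-range qubits.
qasm_structurally_valid <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines[nzchar(trimws(lines))])
  if (lines[1] != "OPENQASM 2.0;") return(FALSE)
  if (lines[2] != "include \"qelib1.inc\";") return(FALSE)
  m <- regmatches(lines[3], regexec("^qreg q\\[([0-9]+)\\];$", lines[3]))[[1]]
  if (length(m) != 2) return(FALSE)
  nq <- as.integer(m[2])
  body <- lines[-(1:4)]
  gate_re <- paste0("^(h|x|y|z|cx|ch|ccx|rx|ry|rz|crz|cu1|cu3|u3)",
                    "(\\([^)]*\\))? q\\[[0-9]+\\](,q\\[[0-9]+\\])*;$")
  meas_re <- "^measure q\\[[0-9]+\\] -> c\\[[0-9]+\\];$"
  for (ln in body) {
    if (!grepl(gate_re, ln) && !grepl(meas_re, ln)) return(FALSE)
    idx <- as.integer(unlist(regmatches(ln, gregexpr("(?<=q\\[)[0-9]+", ln,
                                                     perl = TRUE))))
    if (any(idx >= nq)) return(FALSE)
  }
  TRUE
}

# packaged fixture paths
cg_path <- function() system.file("extdata", "clinton_gore.json",
                                  package = "qcog")
pd_path <- function() system.file("extdata", "prisoners_dilemma.json",
                                  package = "qcog")
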