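# Statevector core.
#
# Qubit indices are 0-based throughout, matching circuit-diagram labels
# q0, q1, ...  Basis states are labelled |q0 q1 ... q_{n-1}> with q0 the
# LEFTMOST (most significant) bit, so the amplitude at R index i belongs to
# the basis number b = i - 1 and qubit q carries bit (b >> (n-1-q)) & 1.
# Global phase is never meaningful; states are compared via probabilities or
# up-to-phase amplitude comparison.

# register cap: 2^12 amplitudes is still instantaneous, and far above the
# <= 4 qubits these cognitive circuits actually use.
QC_MAX_QUBITS <- 12L

QC_GATE_KINDS <- c("RX", "RY", "RZ", "H", "X", "SWAP")
QC_ROTATIONS <- c("RX", "RY", "RZ")

#' Create a fresh quantum register in the ground state
#'
#' Returns an `n_qubits` register with amplitude 1 on \eqn{|0\ldots0\rangle}
#' and 0 elsewhere.
#'
#' @param n_qubits Number of qubits (between 1 and 12).
#' @return An object of class `qc_state` with fields `n_qubits` and
#'   `amplitudes` (complex vector of length `2^n_qubits`, indexed by basis
#'   bitstring with qubit 0 as the leftmost bit).
#' @examples
#' s <- new_state(2)
#' state_probabilities(s)
#' @export
new_state <- function(n_qubits) {
  if (!is.numeric(n_qubits) || length(n_qubits) != 1L || is.na(n_qubits) ||
      n_qubits != as.integer(n_qubits)) {
    stop("'n_qubits' must be a single integer", call. = FALSE)
  }
  n_qubits <- as.integer(n_qubits)
  if (n_qubits < 1L || n_qubits > QC_MAX_QUBITS) {
    stop(sprintf("'n_qubits' must be in 1..%d", QC_MAX_QUBITS), call. = FALSE)
  }
  amp <- complex(2^n_qubits)
  amp[1L] <- 1 + 0i
  structure(list(n_qubits = n_qubits, amplitudes = amp), class = "qc_state")
}

#' @export
print.qc_state <- function(x, digits = 4, ...) {
  cat(sprintf("<qc_state: %d qubit%s>\n", x$n_qubits,
              if (x$n_qubits == 1L) "" else "s"))
  labs <- qc_basis_labels(x$n_qubits)
  nz <- which(Mod(x$amplitudes) > 1e-12)
  for (i in nz) {
    cat(sprintf("  |%s>  %s\n", labs[i],
                format(signif(x$amplitudes[i], digits))))
  }
  invisible(x)
}

# bitstring labels for every basis state, restricted to `qubits` if given
# (marginal label order follows the order of `qubits`)
qc_basis_labels <- function(n, qubits = NULL) {
  if (is.null(qubits)) qubits <- 0:(n - 1L)
  b <- 0:(2^n - 1L)
  cols <- vapply(qubits,
                 function(q) bitwAnd(bitwShiftR(b, n - 1L - q), 1L),
                 integer(2^n))
  apply(matrix(cols, nrow = 2^n), 1L, paste0, collapse = "")
}

#' Specify a quantum gate
#'
#' Builds a validated gate specification. Supported kinds are the rotations
#' `RX`, `RY`, `RZ` (standard half-angle convention: `RX(a)` maps
#' \eqn{|0\rangle} to \eqn{\cos(a/2)|0\rangle - i\sin(a/2)|1\rangle}, and
#' `RZ(a) = diag(e^{-ia/2}, e^{ia/2})`), the Hadamard `H`, the bit flip `X`,
#' and the two-qubit `SWAP`. Any gate may carry controls; a control with
#' polarity 1 (a "black circle" in circuit diagrams) activates the gate when
#' that qubit is \eqn{|1\rangle}, polarity 0 (a "white circle") when it is
#' \eqn{|0\rangle}. On-zero controls are native in the simulator; the QASM
#' exporter lowers them to X-conjugated on-one controls.
#'
#' @param kind One of `"RX"`, `"RY"`, `"RZ"`, `"H"`, `"X"`, `"SWAP"`.
#' @param targets Target qubit index (two indices for `SWAP`), 0-based.
#' @param angle Rotation angle in radians (rotation kinds only).
#' @param controls Optional integer vector of control qubit indices.
#' @param polarity Integer vector of 0/1, one per control (default all 1).
#' @return An object of class `qc_gate`.
#' @examples
#' qc_gate("H", 0)
#' qc_gate("X", 1, controls = 0)          # CNOT
#' qc_gate("SWAP", c(0, 1), controls = 2) # Fredkin
#' @export
qc_gate <- function(kind, targets, angle = NULL, controls = integer(0),
                    polarity = NULL) {
  kind <- match.arg(kind, QC_GATE_KINDS)
  targets <- as.integer(targets)
  controls <- as.integer(controls)
  n_targ <- if (kind == "SWAP") 2L else 1L
  if (length(targets) != n_targ) {
    stop(sprintf("'%s' takes exactly %d target(s)", kind, n_targ),
         call. = FALSE)
  }
  if (anyDuplicated(targets)) stop("duplicate target qubits", call. = FALSE)
  if (kind %in% QC_ROTATIONS) {
    if (is.null(angle) || !is.numeric(angle) || length(angle) != 1L ||
        is.na(angle)) {
      stop(sprintf("rotation '%s' requires a single numeric 'angle'", kind),
           call. = FALSE)
    }
  } else if (!is.null(angle)) {
    stop(sprintf("'%s' takes no angle", kind), call. = FALSE)
  }
  if (is.null(polarity)) polarity <- rep(1L, length(controls))
  polarity <- as.integer(polarity)
  if (length(polarity) != length(controls) || !all(polarity %in% c(0L, 1L))) {
    stop("'polarity' must be a 0/1 vector matching 'controls'", call. = FALSE)
  }
  if (anyDuplicated(controls)) stop("duplicate control qubits", call. = FALSE)
  if (any(controls %in% targets)) {
    stop("control and target qubits must be disjoint", call. = FALSE)
  }
  if (any(c(targets, controls) < 0L)) {
    stop("qubit indices must be non-negative", call. = FALSE)
  }
  structure(list(kind = kind, targets = targets,
                 angle = if (kind %in% QC_ROTATIONS) as.numeric(angle),
                 controls = controls, polarity = polarity),
            class = "qc_gate")
}

#' @export
print.qc_gate <- function(x, ...) {
  ang <- if (!is.null(x$angle)) sprintf("(%.6g)", x$angle) else ""
  ctl <- if (length(x$controls)) {
    paste0(" ctrl ", paste0("q", x$controls,
                            ifelse(x$polarity == 1L, "=1", "=0"),
                            collapse = ","))
  } else ""
  cat(sprintf("<qc_gate %s%s on q%s%s>\n", x$kind, ang,
              paste(x$targets, collapse = ",q"), ctl))
  invisible(x)
}

# 2x2 matrix of a single-qubit kind
qc_gate_matrix <- function(kind, angle = NULL) {
  switch(kind,
    H  = matrix(c(1, 1, 1, -1), 2, 2) / sqrt(2) + 0i,
    X  = matrix(c(0, 1, 1, 0), 2, 2) + 0i,
    RX = {
      c2 <- cos(angle / 2); s2 <- sin(angle / 2)
      matrix(c(c2, -1i * s2, -1i * s2, c2), 2, 2, byrow = TRUE)
    },
    RY = {
      c2 <- cos(angle / 2); s2 <- sin(angle / 2)
      matrix(c(c2, -s2, s2, c2), 2, 2, byrow = TRUE) + 0i
    },
    RZ = diag(c(exp(-1i * angle / 2), exp(1i * angle / 2))),
    stop("no matrix for kind ", kind)
  )
}

# inverse gate (rotations: negate angle; H, X, SWAP are self-inverse)
qc_gate_inverse <- function(gate) {
  if (gate$kind %in% QC_ROTATIONS) {
    qc_gate(gate$kind, gate$targets, angle = -gate$angle,
            controls = gate$controls, polarity = gate$polarity)
  } else {
    gate
  }
}

#' Apply a gate to a statevector
#'
#' Unitary action on the register; controlled gates act on the target
#' subspace only where every control qubit matches its polarity. The norm is
#' preserved to numerical precision.
#'
#' @param state A `qc_state`.
#' @param gate A `qc_gate` whose qubit indices all lie within the register.
#' @return The transformed `qc_state`.
#' @examples
#' s <- apply_gate(new_state(1), qc_gate("H", 0))
#' state_probabilities(s)
#' @export
apply_gate <- function(state, gate) {
  stopifnot(inherits(state, "qc_state"), inherits(gate, "qc_gate"))
  n <- state$n_qubits
  if (any(c(gate$targets, gate$controls) >= n)) {
    stop("gate qubit index out of range for this register", call. = FALSE)
  }
  a <- state$amplitudes
  b <- 0:(length(a) - 1L)
  ctrl_ok <- rep(TRUE, length(a))
  for (k in seq_along(gate$controls)) {
    bit <- bitwAnd(bitwShiftR(b, n - 1L - gate$controls[k]), 1L)
    ctrl_ok <- ctrl_ok & (bit == gate$polarity[k])
  }
  if (gate$kind == "SWAP") {
    t1 <- gate$targets[1L]; t2 <- gate$targets[2L]
    s1 <- 2^(n - 1L - t1); s2 <- 2^(n - 1L - t2)
    b1 <- bitwAnd(bitwShiftR(b, n - 1L - t1), 1L)
    b2 <- bitwAnd(bitwShiftR(b, n - 1L - t2), 1L)
    sel <- which(b1 == 1L & b2 == 0L & ctrl_ok)
    if (length(sel)) {
      partner <- sel - s1 + s2   # R indices shift with basis number
      tmp <- a[sel]; a[sel] <- a[partner]; a[partner] <- tmp
    }
  } else {
    t <- gate$targets
    s <- 2^(n - 1L - t)
    tbit <- bitwAnd(bitwShiftR(b, n - 1L - t), 1L)
    i0 <- which(tbit == 0L & ctrl_ok)
    i1 <- i0 + s
    m <- qc_gate_matrix(gate$kind, gate$angle)
    a0 <- a[i0]; a1 <- a[i1]
    a[i0] <- m[1, 1] * a0 + m[1, 2] * a1
    a[i1] <- m[2, 1] * a0 + m[2, 2] * a1
  }
  state$amplitudes <- a
  state
}

#' Measurement probabilities of a statevector
#'
#' Exact Born-rule probabilities, marginalised onto a subset of qubits by
#' summing over the rest. The result sums to 1 to numerical precision.
#'
#' @param state A `qc_state`.
#' @param qubits Optional 0-based qubit indices; default all, in register
#'   order. The marginal bitstring follows the order given here.
#' @return Named numeric vector: bitstring over the chosen qubits -> probability.
#' @examples
#' bell <- run_circuit(qc_circuit(2, list(qc_gate("H", 0),
#'                                        qc_gate("X", 1, controls = 0))))
#' state_probabilities(bell)
#' state_probabilities(bell, qubits = 1)
#' @export
state_probabilities <- function(state, qubits = NULL) {
  stopifnot(inherits(state, "qc_state"))
  n <- state$n_qubits
  if (is.null(qubits)) qubits <- 0:(n - 1L)
  qubits <- as.integer(qubits)
  if (anyDuplicated(qubits) || any(qubits < 0L) || any(qubits >= n)) {
    stop("'qubits' must be distinct indices within the register", call. = FALSE)
  }
  p <- Mod(state$amplitudes)^2
  keys <- qc_basis_labels(n, qubits)
  out <- vapply(split(p, keys), sum, numeric(1))
  out[order(names(out))]
}
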