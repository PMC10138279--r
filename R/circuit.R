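# Circuits, seeded shot sampling, counts, and OpenQASM 2.0 export.

#' Assemble a quantum circuit
#'
#' A circuit is an ordered gate list over a fixed register plus the subset of
#' qubits that are measured (in order) into classical bits.
#'
#' @param n_qubits Register size.
#' @param gates List of [qc_gate()] specifications, applied in order.
#' @param measure 0-based qubit indices measured into classical bits 0,1,...;
#'   default: every qubit in register order.
#' @return An object of class `qc_circuit`.
#' @examples
#' qc_circuit(2, list(qc_gate("H", 0), qc_gate("X", 1, controls = 0)))
#' @export
qc_circuit <- function(n_qubits, gates = list(), measure = NULL) {
  n_qubits <- as.integer(n_qubits)
  if (n_qubits < 1L || n_qubits > QC_MAX_QUBITS) {
    stop(sprintf("'n_qubits' must be in 1..%d", QC_MAX_QUBITS), call. = FALSE)
  }
  if (inherits(gates, "qc_gate")) gates <- list(gates)
  if (!all(vapply(gates, inherits, logical(1), "qc_gate"))) {
    stop("'gates' must be a list of qc_gate objects", call. = FALSE)
  }
  for (g in gates) {
    if (any(c(g$targets, g$controls) >= n_qubits)) {
      stop("gate qubit index out of range for this register", call. = FALSE)
    }
  }
  if (is.null(measure)) measure <- 0:(n_qubits - 1L)
  measure <- as.integer(measure)
  if (anyDuplicated(measure) || any(measure < 0L) || any(measure >= n_qubits)) {
    stop("'measure' must be distinct qubit indices within the register",
         call. = FALSE)
  }
  structure(list(n_qubits = n_qubits, gates = gates, measure = measure),
            class = "qc_circuit")
}

#' @export
print.qc_circuit <- function(x, ...) {
  cat(sprintf("<qc_circuit: %d qubits, %d gates, measure [%s]>\n",
              x$n_qubits, length(x$gates),
              paste0("q", x$measure, collapse = " ")))
  for (g in x$gates) print(g)
  invisible(x)
}

#' Run a circuit exactly
#'
#' Applies the gate list in order to the ground state and returns the final
#' statevector (deterministic; no measurement collapse).
#'
#' @param circuit A `qc_circuit`.
#' @return A `qc_state`.
#' @export
run_circuit <- function(circuit) {
  stopifnot(inherits(circuit, "qc_circuit"))
  state <- new_state(circuit$n_qubits)
  for (g in circuit$gates) state <- apply_gate(state, g)
  state
}

# evaluate a block of R code under a fixed seed without clobbering the
# caller's RNG stream
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Sample measurement shots from a circuit
#'
#' Draws `shots` outcomes from the exact measurement distribution of the
#' circuit's measured qubits (a multinomial draw). The same seed always
#' yields the identical table; the caller's RNG stream is left untouched.
#'
#' @param circuit A `qc_circuit`.
#' @param shots Number of repetitions (>= 1).
#' @param seed Integer seed.
#' @return An object of class `qc_counts`: list with `counts` (named integer
#'   vector, bitstring over measured qubits -> count), `shots`, `seed`.
#' @examples
#' sample_counts(qc_circuit(1, list(qc_gate("H", 0))), shots = 100, seed = 1)
#' @export
sample_counts <- function(circuit, shots, seed) {
  stopifnot(inherits(circuit, "qc_circuit"))
  if (!is.numeric(shots) || length(shots) != 1L || shots < 1) {
    stop("'shots' must be a positive integer", call. = FALSE)
  }
  shots <- as.integer(shots)
  p <- state_probabilities(run_circuit(circuit), circuit$measure)
  draw <- with_seed(seed, as.vector(stats::rmultinom(1L, shots, p)))
  structure(list(counts = stats::setNames(as.integer(draw), names(p)),
                 shots = shots, seed = as.integer(seed)),
            class = "qc_counts")
}

#' @export
print.qc_counts <- function(x, ...) {
  cat(sprintf("<qc_counts: %d shots, seed %d>\n", x$shots, x$seed))
  nz <- x$counts[x$counts > 0L]
  for (k in names(nz)) cat(sprintf("  %s: %d\n", k, nz[[k]]))
  invisible(x)
}

# shared worker: `table` is a named nonnegative numeric vector (integer
# counts or exact probabilities); masks use '.' as a wildcard per bit.
mask_match <- function(keys, mask) {
  width <- unique(nchar(keys))
  if (length(width) != 1L || nchar(mask) != width) {
    stop("mask length must equal the measured bitstring length", call. = FALSE)
  }
  ok <- rep(TRUE, length(keys))
  for (i in seq_len(width)) {
    mc <- substr(mask, i, i)
    if (mc == ".") next
    if (!mc %in% c("0", "1")) stop("mask characters must be 0, 1 or '.'",
                                   call. = FALSE)
    ok <- ok & substr(keys, i, i) == mc
  }
  ok
}

#' Conditional probability from a counts table
#'
#' Computes (shots matching `condition` and `outcome`) / (shots matching
#' `condition`). Both are partial bit assignments written as masks over the
#' measured bitstring, e.g. `".1"` fixes the second classical bit to 1 and
#' leaves the first free. A condition that matches no shots raises an
#' explicit undefined-conditional error rather than returning 0. A named
#' numeric vector of exact probabilities may be supplied in place of counts.
#'
#' @param counts A `qc_counts` object, or a named nonnegative numeric vector.
#' @param condition Mask string for the conditioning event.
#' @param outcome Mask string for the outcome event.
#' @return A probability.
#' @examples
#' cts <- structure(list(counts = c("00" = 3000, "01" = 3000,
#'                                  "10" = 2500, "11" = 1500),
#'                       shots = 10000L, seed = 0L), class = "qc_counts")
#' conditional_from_counts(cts, condition = ".1", outcome = "0.")  # 2/3
#' @export
conditional_from_counts <- function(counts, condition, outcome) {
  tab <- if (inherits(counts, "qc_counts")) counts$counts else counts
  if (is.null(names(tab)) || !is.numeric(tab) || any(tab < 0)) {
    stop("'counts' must be a qc_counts object or a named nonnegative vector",
         call. = FALSE)
  }
  keys <- names(tab)
  cond <- mask_match(keys, condition)
  denom <- sum(tab[cond])
  if (denom <= 0) {
    stop("undefined conditional: no shots match the condition", call. = FALSE)
  }
  num <- sum(tab[cond & mask_match(keys, outcome)])
  num / denom
}

#' Serialize a counts table
#'
#' `write_counts_json()` writes `{"shots":..., "seed":..., "counts":{...}}`;
#' `write_counts_csv()` writes two columns `bitstring,count`.
#'
#' @param counts A `qc_counts` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_counts_json <- function(counts, path) {
  stopifnot(inherits(counts, "qc_counts"))
  jsonlite::write_json(
    list(shots = counts$shots, seed = counts$seed,
         counts = as.list(counts$counts)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_counts_json
#' @export
write_counts_csv <- function(counts, path) {
  stopifnot(inherits(counts, "qc_counts"))
  utils::write.csv(
    data.frame(bitstring = names(counts$counts),
               count = as.integer(counts$counts)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- OpenQASM 2.0 export -------------------------------------------------

qasm_num <- function(x) sprintf("%.12g", x)

# emit one gate as qelib1-compatible statements; on-zero controls are
# lowered by conjugating the control with x, and swaps are lowered to CNOTs
# so that only stock qelib1 gates appear.
qasm_gate_lines <- function(g) {
  wrap <- character(0)
  for (k in seq_along(g$controls)) {
    if (g$polarity[k] == 0L) wrap <- c(wrap, sprintf("x q[%d];", g$controls[k]))
  }
  nctl <- length(g$controls)
  q <- function(i) sprintf("q[%d]", i)
  body <- if (g$kind == "SWAP") {
    t1 <- g$targets[1L]; t2 <- g$targets[2L]
    if (nctl == 0L) {
      c(sprintf("cx %s,%s;", q(t1), q(t2)),
        sprintf("cx %s,%s;", q(t2), q(t1)),
        sprintf("cx %s,%s;", q(t1), q(t2)))
    } else if (nctl == 1L) {
      cc <- g$controls[1L]
      c(sprintf("cx %s,%s;", q(t2), q(t1)),
        sprintf("ccx %s,%s,%s;", q(cc), q(t1), q(t2)),
        sprintf("cx %s,%s;", q(t2), q(t1)))
    } else {
      stop("QASM export supports at most one control on SWAP", call. = FALSE)
    }
  } else if (nctl == 0L) {
    t <- g$targets
    switch(g$kind,
      H  = sprintf("h %s;", q(t)),
      X  = sprintf("x %s;", q(t)),
      RX = sprintf("rx(%s) %s;", qasm_num(g$angle), q(t)),
      RY = sprintf("ry(%s) %s;", qasm_num(g$angle), q(t)),
      RZ = sprintf("rz(%s) %s;", qasm_num(g$angle), q(t)))
  } else if (nctl == 1L) {
    t <- g$targets; cc <- g$controls[1L]
    switch(g$kind,
      H  = sprintf("ch %s,%s;", q(cc), q(t)),
      X  = sprintf("cx %s,%s;", q(cc), q(t)),
      # controlled rotations via the standard qelib1 decompositions
      RX = sprintf("cu3(%s,-pi/2,pi/2) %s,%s;", qasm_num(g$angle), q(cc), q(t)),
      RY = sprintf("cu3(%s,0,0) %s,%s;", qasm_num(g$angle), q(cc), q(t)),
      RZ = sprintf("crz(%s) %s,%s;", qasm_num(g$angle), q(cc), q(t)))
  } else {
    stop("QASM export supports at most one control per gate", call. = FALSE)
  }
  c(wrap, body, rev(wrap))
}

#' Export a circuit as OpenQASM 2.0 text
#'
#' Emits a program using only `qelib1.inc` gates: on-zero ("white circle")
#' controls are lowered as X-conjugated on-one controls, swaps become three
#' CNOTs, controlled swaps a CNOT/Toffoli/CNOT sandwich, and controlled
#' rotations use the standard `crz`/`cu3` decompositions. Parsing the text
#' back therefore requires no custom gate definitions.
#'
#' @param circuit A `qc_circuit`.
#' @return A single string of OpenQASM 2.0 source.
#' @examples
#' cat(export_qasm(qc_circuit(2, list(qc_gate("H", 0),
#'                                    qc_gate("X", 1, controls = 0)))))
#' @export
export_qasm <- function(circuit) {
  stopifnot(inherits(circuit, "qc_circuit"))
  lines <- c("OPENQASM 2.0;",
             "include \"qelib1.inc\";",
             sprintf("qreg q[%d];", circuit$n_qubits),
             sprintf("creg c[%d];", length(circuit$measure)))
  for (g in circuit$gates) lines <- c(lines, qasm_gate_lines(g))
  for (k in seq_along(circuit$measure)) {
    lines <- c(lines, sprintf("measure q[%d] -> c[%d];",
                              circuit$measure[k], k - 1L))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}
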