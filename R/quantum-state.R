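#' Quantum statevector objects
#'
#' A `quantum_state` is a dense complex amplitude vector over `n_qubits`
#' qubits in little-endian order (qubit 0 is the least significant bit of
#' the amplitude index). The squared amplitudes always sum to one.
#'
#' @param n_qubits Integer number of qubits (1 to 8 supported).
#' @param amplitudes Optional complex vector of length `2^n_qubits`; defaults
#'   to the computational ground state `|0...0>`.
#' @return An object of class `quantum_state`.
#' @examples
#' s <- quantum_state(2)
#' s <- apply_rotation(s, qubit = 0, axis = "X", angle = pi)
#' state_probabilities(s)
#' @export
quantum_state <- function(n_qubits, amplitudes = NULL) {
  n_qubits <- as.integer(n_qubits)
  if (length(n_qubits) != 1L || is.na(n_qubits) || n_qubits < 1L ||
      n_qubits > 8L) {
    stop("n_qubits must be a single integer between 1 and 8")
  }
  dim <- 2L^n_qubits
  if (is.null(amplitudes)) {
    amplitudes <- complex(dim)
    amplitudes[1L] <- 1 + 0i
  }
  amplitudes <- as.complex(amplitudes)
  if (length(amplitudes) != dim) {
    stop("amplitudes must have length 2^n_qubits = ", dim)
  }
  nrm <- sum(Mod(amplitudes)^2)
  if (abs(nrm - 1) > 1e-10) {
    stop("state is not normalized: sum |amplitude|^2 = ", format(nrm))
  }
  structure(list(n_qubits = n_qubits, amplitudes = amplitudes),
            class = "quantum_state")
}

#' @export
print.quantum_state <- function(x, ...) {
  cat("<quantum_state> ", x$n_qubits, " qubit(s), ",
      length(x$amplitudes), " amplitudes\n", sep = "")
  invisible(x)
}

#' @rdname quantum_state
#' @param state A `quantum_state`.
#' @return `state_probabilities()`: numeric vector of measurement
#'   probabilities in the computational basis.
#' @export
state_probabilities <- function(state) {
  stopifnot(inherits(state, "quantum_state"))
  Mod(state$amplitudes)^2
}

#' Construct a computational basis state
#'
#' @param n_qubits Number of qubits.
#' @param bits Integer vector of 0/1 values, `bits[q + 1]` for qubit `q`
#'   (little-endian), or a single basis index in `0:(2^n_qubits - 1)`.
#' @return A `quantum_state` with all amplitude on the requested basis state.
#' @export
basis_state <- function(n_qubits, bits = 0L) {
  n_qubits <- as.integer(n_qubits)
  if (length(bits) == n_qubits && n_qubits > 1L) {
    idx <- sum(as.integer(bits) * 2L^(seq_len(n_qubits) - 1L))
  } else {
    idx <- as.integer(bits)
  }
  if (idx < 0L || idx >= 2L^n_qubits) stop("basis index out of range")
  amp <- complex(2L^n_qubits)
  amp[idx + 1L] <- 1 + 0i
  quantum_state(n_qubits, amp)
}

#' Apply a single-qubit rotation gate
#'
#' Uses the convention `R_A(phi) = exp(-i * phi * A / 2)` for
#' `A` in `X`, `Y`, `Z`.
#'
#' @param state A `quantum_state`.
#' @param qubit Zero-based qubit index.
#' @param axis One of `"X"`, `"Y"`, `"Z"`.
#' @param angle Rotation angle in radians.
#' @return The rotated `quantum_state`.
#' @export
apply_rotation <- function(state, qubit, axis, angle) {
  stopifnot(inherits(state, "quantum_state"))
  axis <- match.arg(axis, c("X", "Y", "Z"))
  amp <- cpp_apply_rotation(state$amplitudes, state$n_qubits,
                            as.integer(qubit), axis, as.numeric(angle))
  quantum_state(state$n_qubits, amp)
}

#' Apply a controlled-NOT gate
#'
#' @inheritParams apply_rotation
#' @param control,target Zero-based control and target qubit indices
#'   (must differ).
#' @return The entangled `quantum_state`.
#' @export
apply_cnot <- function(state, control, target) {
  stopifnot(inherits(state, "quantum_state"))
  amp <- cpp_apply_cnot(state$amplitudes, state$n_qubits,
                        as.integer(control), as.integer(target))
  quantum_state(state$n_qubits, amp)
}

#' Expectation value of a single-qubit Pauli observable
#'
#' @inheritParams apply_rotation
#' @param observable One of `"X"`, `"Y"`, `"Z"`.
#' @return Real expectation value in `[-1, 1]`.
#' @export
expectation_pauli <- function(state, qubit, observable) {
  stopifnot(inherits(state, "quantum_state"))
  observable <- match.arg(observable, c("X", "Y", "Z"))
  cpp_expectation_pauli(state$amplitudes, state$n_qubits,
                        as.integer(qubit), observable)
}

#' Readout basis change of the depth-infused circuit
#'
#' Before measurement every qubit except qubit 0 acts as the control of a
#' CNOT targeting qubit 0 (controls applied in ascending order). This
#' spreads the subsequent Pauli-Y measurement across all qubits and turns
#' the final state into the classical n-neuron output of the quantum head.
#'
#' @param state A `quantum_state`.
#' @return The transformed `quantum_state`.
#' @export
readout_transform <- function(state) {
  stopifnot(inherits(state, "quantum_state"))
  amp <- cpp_readout_transform(state$amplitudes, state$n_qubits)
  quantum_state(state$n_qubits, amp)
}
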