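# Independent brute-force oracle for the statevector simulator: builds every
# gate as an explicit dense matrix (kronecker products over the full
# register, little-endian order) and multiplies out the whole circuit.
# Deliberately shares no code with the package's C++ kernels.

oracle_gate_1q <- function(axis, angle) {
  I2 <- diag(2)
  P <- switch(axis,
    X = matrix(c(0, 1, 1, 0), 2, 2),
    Y = matrix(c(0, 1i, -1i, 0), 2, 2), # column-major: Y = [[0,-i],[i,0]]
    Z = diag(c(1, -1))
  )
  cos(angle / 2) * I2 - 1i * sin(angle / 2) * P
}

# Embed a 2x2 gate on qubit q of n (q zero-based, little-endian): with
# kronecker(A, B) acting as A on the *high* bits, the single-qubit slot q
# counts from the right of the kron chain.
oracle_embed_1q <- function(U, qubit, n) {
  M <- matrix(1, 1, 1)
  for (q in seq(n - 1, 0)) {
    M <- kronecker(M, if (q == qubit) U else diag(2))
  }
  M
}

oracle_cnot <- function(control, target, n) {
  dim <- 2^n
  M <- matrix(0, dim, dim)
  for (i in 0:(dim - 1)) {
    j <- if (bitwAnd(i, bitwShiftL(1, control)) > 0) {
      bitwXor(i, bitwShiftL(1, target))
    } else {
      i
    }
    M[j + 1, i + 1] <- 1
  }
  M
}

oracle_entangler <- function(n, ring = FALSE) {
  M <- diag(2^n)
  if (n >= 2) {
    for (q in 0:(n - 2)) M <- oracle_cnot(q, q + 1, n) %*% M
    if (ring && n > 2) M <- oracle_cnot(n - 1, 0, n) %*% M
  }
  M
}

oracle_variational_row <- function(theta_row, n, ring = FALSE) {
  M <- diag(2^n)
  for (q in 0:(n - 1)) {
    M <- oracle_embed_1q(oracle_gate_1q("X", theta_row[q + 1]), q, n) %*% M
  }
  oracle_entangler(n, ring) %*% M
}

# Full circuit unitary for the depth-infused layer; theta is
# (n_blocks + 1) x n, features has length n * n_blocks.
oracle_qdi_unitary <- function(features, theta, n, n_blocks, ring = FALSE) {
  M <- oracle_variational_row(theta[1, ], n, ring)
  for (b in seq_len(n_blocks)) {
    for (q in 0:(n - 1)) {
      ang <- features[(b - 1) * n + q + 1]
      M <- oracle_embed_1q(oracle_gate_1q("Z", ang), q, n) %*% M
    }
    M <- oracle_variational_row(theta[b + 1, ], n, ring) %*% M
  }
  for (q in seq_len(n - 1)) M <- oracle_cnot(q, 0, n) %*% M
  M
}

oracle_expect_pauli <- function(psi, qubit, axis, n) {
  P <- oracle_embed_1q(switch(axis,
                              X = matrix(c(0, 1, 1, 0), 2, 2),
                              Y = matrix(c(0, 1i, -1i, 0), 2, 2),
                              Z = diag(c(1, -1))),
                       qubit, n)
  psi <- as.vector(psi)
  Re(sum(Conj(psi) * (P %*% psi)))
}

oracle_qdi_forward <- function(features, theta, n, n_blocks, ring = FALSE) {
  U <- oracle_qdi_unitary(features, theta, n, n_blocks, ring)
  psi0 <- complex(2^n)
  psi0[1] <- 1
  psi <- U %*% psi0
  vapply(0:(n - 1), function(q) oracle_expect_pauli(psi, q, "Y", n),
         numeric(1))
}

# Central finite-difference gradient of the simulator's own forward map
# (independent of the parameter-shift route).
oracle_fd_gradient <- function(features, theta, config, h = 1e-5) {
  n <- config$n_qubits
  rows <- nrow(theta)
  gt <- array(0, c(rows, n, n))
  for (b in seq_len(rows)) {
    for (q in seq_len(n)) {
      tp <- theta; tp[b, q] <- tp[b, q] + h
      tm <- theta; tm[b, q] <- tm[b, q] - h
      gt[b, q, ] <- (qdi_forward(features, tp, config) -
                       qdi_forward(features, tm, config)) / (2 * h)
    }
  }
  gf <- matrix(0, length(features), n)
  for (j in seq_along(features)) {
    fp <- features; fp[j] <- fp[j] + h
    fm <- features; fm[j] <- fm[j] - h
    gf[j, ] <- (qdi_forward(fp, theta, config) -
                  qdi_forward(fm, theta, config)) / (2 * h)
  }
  list(theta = gt, features = gf)
}
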