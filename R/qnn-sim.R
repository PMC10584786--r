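# dense state-vector simulator; basis index = sum_j b_j 2^(n-j), i.e.
# qubit 1 is the most significant bit

gate_ry <- function(theta) {
  matrix(c(cos(theta / 2), sin(theta / 2),
           -sin(theta / 2), cos(theta / 2)), 2, 2)
}

gate_rz <- function(theta) {
  diag(c(exp(-1i * theta / 2), exp(1i * theta / 2)))
}

gate_x <- function() matrix(c(0, 1, 1, 0), 2, 2)

# arbitrary single-qubit rotation RZ(omega) RY(theta) RZ(phi)
gate_rot <- function(phi, theta, omega) {
  gate_rz(omega) %*% gate_ry(theta) %*% gate_rz(phi)
}

# full 2^n x 2^n operator applying U on qubit `q` of an n-qubit register
single_qubit_op <- function(U, q, n) {
  left <- diag(2^(q - 1))
  right <- diag(2^(n - q))
  kronecker(kronecker(left, U), right)
}

# CNOT with control qubit c and target qubit t
cnot_op <- function(c, t, n) {
  P0 <- diag(c(1, 0)); P1 <- diag(c(0, 1))
  op_term <- function(Pc, Ut) {
    mats <- rep(list(diag(2)), n)
    mats[[c]] <- Pc
    mats[[t]] <- Ut
    Reduce(kronecker, mats)
  }
  op_term(P0, diag(2)) + op_term(P1, gate_x())
}

apply_single <- function(state, U, q, n) {
  as.vector(single_qubit_op(U, q, n) %*% state)
}

apply_cnot <- function(state, c, t, n) {
  as.vector(cnot_op(c, t, n) %*% state)
}

state_norm_check <- function(state, tol = 1e-8) {
  abs(sqrt(sum(Mod(state)^2)) - 1) <= tol
}
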