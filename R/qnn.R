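#' Reduce 10 features to a 4-dimensional amplitude vector
#'
#' Centers on the fit rows, projects onto the top three principal
#' directions (each component's largest-magnitude loading is made
#' positive), min-max scales each component to `[0, 1]` using fit-row
#' ranges (transform rows are clipped into the same range), appends a
#' constant padding term that carries the normalization information, and
#' normalizes every row to unit Euclidean norm — producing valid
#' non-negative amplitude vectors for a 2-qubit register.
#'
#' @param X Numeric n x p matrix (p >= 3, typically 10).
#' @param fit_idx Rows used to fit the projection (>= 4, rank >= 3).
#' @param pad Padding constant, default 0.3.
#' @return List: `alpha` (n x 4 matrix of unit-norm non-negative rows) and
#'   `transform` (an `amplitude_transform` reusable via
#'   [apply_amplitude_transform()]).
#' @export
reduce_and_pad <- function(X, fit_idx = seq_len(nrow(X)), pad = 0.3) {
  X <- as.matrix(X)
  if (length(fit_idx) < 4L) stop("need at least 4 fit rows", call. = FALSE)
  if (pad <= 0) stop("`pad` must be positive", call. = FALSE)
  Xf <- X[fit_idx, , drop = FALSE]
  pc <- prcomp(Xf, center = TRUE, scale. = FALSE)
  if (length(pc$sdev) < 3L || pc$sdev[3] < 1e-10 * max(pc$sdev[1], 1e-300)) {
    stop("fit rows have rank < 3", call. = FALSE)
  }
  rot <- pc$rotation[, 1:3, drop = FALSE]
  # sign convention: largest-|loading| coordinate positive
  for (j in 1:3) {
    big <- which.max(abs(rot[, j]))
    if (rot[big, j] < 0) rot[, j] <- -rot[, j]
  }
  scores_fit <- sweep(Xf, 2, pc$center) %*% rot
  rng_lo <- apply(scores_fit, 2, min)
  rng_hi <- apply(scores_fit, 2, max)
  if (any(rng_hi - rng_lo < 1e-12)) {
    stop("degenerate component range on fit rows", call. = FALSE)
  }
  transform <- structure(
    list(center = pc$center, rotation = rot,
         range_lo = rng_lo, range_hi = rng_hi, pad = pad),
    class = "amplitude_transform"
  )
  list(alpha = apply_amplitude_transform(transform, X),
       transform = transform)
}

#' Apply a fitted amplitude transform to new rows
#'
#' @param transform An `amplitude_transform` from [reduce_and_pad()].
#' @param X Numeric matrix with the same columns the transform was fit on.
#' @return n x 4 matrix of non-negative unit-norm amplitude vectors.
#' @export
apply_amplitude_transform <- function(transform, X) {
  stopifnot(inherits(transform, "amplitude_transform"))
  X <- as.matrix(X)
  sc <- sweep(X, 2, transform$center) %*% transform$rotation
  sc <- sweep(sc, 2, transform$range_lo)
  sc <- sweep(sc, 2, transform$range_hi - transform$range_lo, `/`)
  sc <- pmin(pmax(sc, 0), 1)
  out <- cbind(sc, transform$pad)
  out / sqrt(rowSums(out^2))
}

#' Amplitude-encoding rotation angles for a 2-qubit state
#'
#' For a non-negative unit amplitude vector `alpha = (a1, a2, a3, a4)` in
#' basis order `|q1 q2> = 00, 01, 10, 11`, the controlled-Y rotation angles
#' of the reversed state-preparation scheme are
#' `beta1_2 = 2 asin(sqrt(a3^2 + a4^2))`,
#' `beta1_1 = 2 asin(a2 / sqrt(a1^2 + a2^2))`,
#' `beta2_1 = 2 asin(a4 / sqrt(a3^2 + a4^2))`, with `0/0` branches defined
#' as 0.
#'
#' @param alpha Numeric length-4 non-negative vector with unit norm.
#' @return Named list `beta1_2`, `beta1_1`, `beta2_1` (radians, in
#'   `[0, pi]`).
#' @export
encoding_angles <- function(alpha) {
  if (length(alpha) != 4L || any(alpha < -1e-12)) {
    stop("`alpha` must be 4 non-negative amplitudes", call. = FALSE)
  }
  if (abs(sqrt(sum(alpha^2)) - 1) > 1e-8) {
    stop("`alpha` must have unit norm", call. = FALSE)
  }
  alpha <- pmax(alpha, 0)
  n_hi <- sqrt(alpha[3]^2 + alpha[4]^2)   # weight of the q1 = 1 branch
  n_lo <- sqrt(alpha[1]^2 + alpha[2]^2)
  safe_asin <- function(num, den) if (den < 1e-150) 0 else asin(min(1, num / den))
  list(beta1_2 = 2 * asin(min(1, n_hi)),
       beta1_1 = 2 * safe_asin(alpha[2], n_lo),
       beta2_1 = 2 * safe_asin(alpha[4], n_hi))
}

# controlled-Ry decomposed into CNOTs and half-angle Ry gates;
# control_value 0 conjugates the control with X gates
apply_cry <- function(state, beta, control, target, n, control_value = 1L) {
  if (control_value == 0L) state <- apply_single(state, gate_x(), control, n)
  state <- apply_cnot(state, control, target, n)
  state <- apply_single(state, gate_ry(-beta / 2), target, n)
  state <- apply_cnot(state, control, target, n)
  state <- apply_single(state, gate_ry(beta / 2), target, n)
  if (control_value == 0L) state <- apply_single(state, gate_x(), control, n)
  state
}

#' Prepare a 2-qubit state by amplitude encoding
#'
#' Runs the gate-level encoding circuit: `Ry(beta1_2)` on qubit 1, then a
#' controlled `Ry(beta1_1)` on qubit 2 conditioned on qubit 1 being 0, and
#' a controlled `Ry(beta2_1)` on qubit 2 conditioned on qubit 1 being 1,
#' with each controlled rotation realized by the standard
#' two-CNOT/half-angle decomposition. The resulting state reproduces
#' `alpha` exactly (up to floating point).
#'
#' @param alpha Non-negative unit-norm length-4 amplitude vector.
#' @return Complex length-4 state vector in basis order `00, 01, 10, 11`.
#' @export
prepare_state <- function(alpha) {
  angles <- encoding_angles(alpha)
  state <- c(1 + 0i, 0i, 0i, 0i)
  state <- apply_single(state, gate_ry(angles$beta1_2), 1, 2)
  state <- apply_cry(state, angles$beta1_1, control = 1, target = 2, n = 2,
                     control_value = 0L)
  state <- apply_cry(state, angles$beta2_1, control = 1, target = 2, n = 2,
                     control_value = 1L)
  state
}

#' Construct circuit parameters
#'
#' @param angles `layers x qubits x 3` array of Rot angles
#'   (`phi, theta, omega`), or `NULL` for zeros.
#' @param bias Classical additive bias on the readout, default 0.
#' @param layers,qubits Circuit size, defaults 6 layers on 2 qubits.
#' @return A `circuit_params` list.
#' @export
circuit_params <- function(angles = NULL, bias = 0, layers = 6L,
                           qubits = 2L) {
  if (is.null(angles)) angles <- array(0, c(layers, qubits, 3))
  stopifnot(length(dim(angles)) == 3L, dim(angles)[3] == 3L)
  structure(list(angles = angles, bias = bias,
                 layers = dim(angles)[1], qubits = dim(angles)[2]),
            class = "circuit_params")
}

# 4x4 unitary of the full variational ansatz (2 qubits): per layer a Rot on
# each qubit followed by CNOT(1 -> 2); cached building block for training
circuit_unitary <- function(params) {
  stopifnot(params$qubits == 2L)
  U <- diag(4) + 0i
  CN <- cnot_op(1, 2, 2)
  for (l in seq_len(params$layers)) {
    R1 <- gate_rot(params$angles[l, 1, 1], params$angles[l, 1, 2],
                   params$angles[l, 1, 3])
    R2 <- gate_rot(params$angles[l, 2, 1], params$angles[l, 2, 2],
                   params$angles[l, 2, 3])
    U <- CN %*% kronecker(R1, R2) %*% U
  }
  U
}

#' Variational circuit expectation value
#'
#' Applies the layered ansatz (a Rot gate on each qubit then CNOT with
#' qubit 1 as control, repeated `layers` times) to the state and returns
#' the expectation of Pauli Z on qubit 1, a value in `[-1, 1]`.
#'
#' @param state Complex length-4 state vector (unit norm).
#' @param params A [circuit_params()].
#' @return Scalar expectation of `Z (x) I`.
#' @export
circuit_expectation <- function(state, params) {
  stopifnot(inherits(params, "circuit_params"))
  if (!state_norm_check(state)) stop("`state` must be unit norm", call. = FALSE)
  psi <- circuit_unitary(params) %*% state
  pr <- Mod(psi)^2
  sum(pr[1:2]) - sum(pr[3:4])
}

# expectations for a matrix of amplitude rows (n x 4), vectorized
batch_expectation <- function(alpha_mat, params) {
  U <- circuit_unitary(params)
  psi <- alpha_mat %*% t(U)
  pr <- Mod(psi)^2
  rowSums(pr[, 1:2, drop = FALSE]) - rowSums(pr[, 3:4, drop = FALSE])
}

#' Predict with a trained quantum classifier
#'
#' The score is the circuit expectation of the amplitude-encoded reduced
#' feature vector plus the classical bias. A negative score predicts class
#' -1 (metastasis-like); otherwise +1 (glioma-like) — a score of exactly 0
#' maps to +1.
#'
#' @param X Numeric matrix of raw feature rows (same columns as training).
#' @param params A trained [circuit_params()].
#' @param transform The `amplitude_transform` fitted during training.
#' @return List: `score` (numeric) and `label` (-1/+1).
#' @export
predict_qnn <- function(X, params, transform) {
  if (!inherits(transform, "amplitude_transform")) {
    stop("`transform` must be a fitted amplitude_transform", call. = FALSE)
  }
  X <- as.matrix(X)
  alpha <- apply_amplitude_transform(transform, X)
  score <- batch_expectation(alpha, params) + params$bias
  list(score = score, label = ifelse(score < 0, -1, 1))
}

#' Train the 2-qubit variational classifier
#'
#' Minimizes the mean squared error between the label (-1/+1) and the
#' score (circuit expectation plus bias) with Adam
#' (`beta1 = 0.9, beta2 = 0.999, eps = 1e-8`). Rotation-angle gradients use
#' the exact parameter-shift rule (shifts of pi/2); the bias gradient is
#' analytic. Angles start from a seeded `N(0, 0.01^2)` draw; the amplitude
#' transform is fitted on the training rows only.
#'
#' @param X Numeric n x p matrix of training rows.
#' @param y Labels in -1/+1, at least 2 per class.
#' @param layers Ansatz depth, default 6.
#' @param lr Adam learning rate, default 0.01.
#' @param epochs Training epochs, default 100.
#' @param batch Mini-batch size; `NULL` (default) uses full batches.
#' @param pad Amplitude padding constant, default 0.3.
#' @param seed Integer seed for initialization and batch shuffling.
#' @return List: `params` (trained `circuit_params`), `transform`, and
#'   `history` (data frame with per-epoch loss and training balanced
#'   accuracy).
#' @export
train_qnn <- function(X, y, layers = 6L, lr = 0.01, epochs = 100L,
                      batch = NULL, pad = 0.3, seed = 1L) {
  X <- as.matrix(X)
  if (!all(y %in% c(-1, 1)) || min(table(y)) < 2L) {
    stop("labels must be -1/+1 with at least 2 per class", call. = FALSE)
  }
  enc <- reduce_and_pad(X, fit_idx = seq_len(nrow(X)), pad = pad)
  A <- enc$alpha
  n <- nrow(A)
  with_seed(seed, {
    angles <- array(rnorm(layers * 2 * 3, sd = 0.01), c(layers, 2, 3))
    bias <- 0
    n_par <- length(angles) + 1L
    m_adam <- numeric(n_par); v_adam <- numeric(n_par)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    history <- data.frame(epoch = integer(0), loss = numeric(0),
                          bacc = numeric(0))
    step <- 0L
    for (ep in seq_len(epochs)) {
      idx_all <- if (is.null(batch)) list(seq_len(n)) else {
        sh <- sample(n)
        split(sh, ceiling(seq_along(sh) / batch))
      }
      for (bidx in idx_all) {
        Ab <- A[bidx, , drop = FALSE]
        yb <- y[bidx]
        params <- circuit_params(angles, bias)
        e0 <- batch_expectation(Ab, params)
        score <- e0 + bias
        resid <- score - yb
        grad <- numeric(n_par)
        for (j in seq_along(angles)) {
          sh_angles <- angles
          sh_angles[j] <- sh_angles[j] + pi / 2
          ep_plus <- batch_expectation(Ab, circuit_params(sh_angles, bias))
          sh_angles[j] <- sh_angles[j] - pi
          ep_minus <- batch_expectation(Ab, circuit_params(sh_angles, bias))
          de <- (ep_plus - ep_minus) / 2
          grad[j] <- mean(2 * resid * de)
        }
        grad[n_par] <- mean(2 * resid)
        step <- step + 1L
        m_adam <- b1 * m_adam + (1 - b1) * grad
        v_adam <- b2 * v_adam + (1 - b2) * grad^2
        m_hat <- m_adam / (1 - b1^step)
        v_hat <- v_adam / (1 - b2^step)
        upd <- lr * m_hat / (sqrt(v_hat) + eps)
        angles <- angles - array(upd[seq_along(angles)], dim(angles))
        bias <- bias - upd[n_par]
      }
      params <- circuit_params(angles, bias)
      score <- batch_expectation(A, params) + bias
      loss <- mean((score - y)^2)
      if (!is.finite(loss)) {
        stop(sprintf("non-finite loss at epoch %d", ep), call. = FALSE)
      }
      pred <- ifelse(score < 0, -1, 1)
      rec <- vapply(c(-1, 1), function(cl) mean(pred[y == cl] == cl),
                    numeric(1))
      history <- rbind(history,
                       data.frame(epoch = ep, loss = loss,
                                  bacc = mean(rec)))
    }
    list(params = circuit_params(angles, bias), transform = enc$transform,
         history = history)
  })
}
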