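# equal-frequency discretization for continuous variables; vectors that
# already take few distinct values are used as-is
discretize_ef <- function(x, bins = 4L) {
  ux <- unique(x)
  if (length(ux) <= bins) {
    return(match(x, sort(ux)))
  }
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(bins * r / length(x)))
}

#' Plug-in mutual information estimate (bits)
#'
#' Discretizes a continuous `x` into equal-frequency bins, forms the joint
#' histogram with `y`, and returns the plug-in estimate of `I(X;Y)` with
#' base-2 logarithms, clipped at 0.
#'
#' @param x Numeric or discrete vector.
#' @param y Outcome vector (typically binary labels).
#' @param bins Number of bins for continuous `x`, default 4.
#' @return Estimated mutual information in bits (>= 0).
#' @export
estimate_mi <- function(x, y, bins = 4L) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ", call. = FALSE)
  if (length(x) < 10L) stop("need at least 10 observations", call. = FALSE)
  xb <- discretize_ef(x, bins)
  yb <- discretize_ef(y, bins)
  n <- length(x)
  joint <- table(xb, yb) / n
  px <- rowSums(joint); py <- colSums(joint)
  ref <- outer(px, py)
  pos <- joint > 0
  max(0, sum(joint[pos] * log2(joint[pos] / ref[pos])))
}

#' Plug-in conditional mutual information estimate (bits)
#'
#' Estimates `I(X;Y|Z)` from the three-way histogram after equal-frequency
#' discretization of continuous `x` and `z`, base-2 logarithms, clipped at
#' 0. Conditioning on a constant `z` reduces exactly to [estimate_mi()].
#'
#' @param x,y,z Equal-length vectors.
#' @param bins Bins for continuous variables, default 4.
#' @return Estimated conditional mutual information in bits (>= 0).
#' @export
estimate_cmi <- function(x, y, z, bins = 4L) {
  n <- length(x)
  if (length(y) != n || length(z) != n) {
    stop("`x`, `y`, `z` lengths differ", call. = FALSE)
  }
  xb <- discretize_ef(x, bins)
  yb <- discretize_ef(y, bins)
  zb <- discretize_ef(z, bins)
  pxyz <- table(xb, yb, zb) / n
  pxz <- apply(pxyz, c(1, 3), sum)
  pyz <- apply(pxyz, c(2, 3), sum)
  pz <- apply(pxyz, 3, sum)
  total <- 0
  for (k in seq_along(pz)) {
    pj <- pxyz[, , k]
    pos <- pj > 0
    if (!any(pos)) next
    ref <- outer(pxz[, k], pyz[, k]) / pz[k]
    total <- total + sum(pj[pos] * log2(pj[pos] / ref[pos]))
  }
  max(0, total)
}

#' Build the QUBO matrix from mutual-information scores
#'
#' `Q[i, i] = I(X_i; Y)` and `Q[i, j] = I(X_i; Y | X_j)` for `i != j`
#' (row = candidate feature, column = conditioned feature), all in bits.
#'
#' @param X Numeric n x p matrix.
#' @param y Labels.
#' @param bins Bins for the estimators.
#' @return p x p numeric matrix.
#' @export
build_q_matrix <- function(X, y, bins = 4L) {
  X <- as.matrix(X)
  p <- ncol(X)
  Q <- matrix(0, p, p)
  for (i in seq_len(p)) {
    Q[i, i] <- estimate_mi(X[, i], y, bins)
    for (j in seq_len(p)) {
      if (i != j) Q[i, j] <- estimate_cmi(X[, i], y, X[, j], bins)
    }
  }
  dimnames(Q) <- list(colnames(X), colnames(X))
  Q
}
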