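#' Kernel SHAP coalition weight
#'
#' The Shapley kernel weight for a coalition of size `s` out of `M`
#' features: `(M - 1) / (choose(M, s) * s * (M - s))`. The empty and full
#' coalitions have infinite weight and are imposed as hard constraints by
#' the solver rather than sampled.
#'
#' @param M Number of features.
#' @param s Coalition size with `0 < s < M`.
#' @return Positive weight, symmetric in `s` and `M - s`.
#' @export
shapley_kernel_weight <- function(M, s) {
  if (any(s <= 0 | s >= M)) {
    stop("`s` must satisfy 0 < s < M (boundary coalitions are constraints)",
         call. = FALSE)
  }
  (M - 1) / (choose(M, s) * s * (M - s))
}

# value function: background-averaged masked prediction. `coalitions` is a
# logical matrix (rows = coalitions); returns one value per row.
coalition_values <- function(model, x, background, coalitions) {
  M <- length(x)
  bg <- as.matrix(background)
  nb <- nrow(bg)
  nc <- nrow(coalitions)
  # rows: coalition-major blocks of the background
  Z <- coalitions[rep(seq_len(nc), each = nb), , drop = FALSE]
  B <- bg[rep(seq_len(nb), times = nc), , drop = FALSE]
  Xm <- B
  Xm[Z] <- matrix(rep(x, each = nb * nc), ncol = M)[Z]
  preds <- model(Xm)
  colMeans(matrix(preds, nrow = nb))  # coalition-major blocks
}

new_shapley_attribution <- function(phi, base_value, fx, residual = 0) {
  structure(list(phi = phi, base_value = base_value, fx = fx,
                 residual = residual),
            class = "shapley_attribution")
}

#' @export
print.shapley_attribution <- function(x, ...) {
  cat(sprintf("<shapley_attribution> %d features  base %.4f  fx %.4f\n",
              length(x$phi), x$base_value, x$fx))
  print(round(x$phi, 4))
  invisible(x)
}

#' Exact Shapley values by full coalition enumeration
#'
#' Enumerates all `2^M` coalitions, computes the value of each as the
#' background-averaged masked prediction (absent features replaced by
#' background rows), and combines marginal contributions with the
#' permutation weights `|S|! (M - |S| - 1)! / M!`. Satisfies efficiency
#' (`sum(phi) = fx - base_value`) and the null-player axiom by
#' construction.
#'
#' @param model Score function accepting a numeric matrix of rows and
#'   returning a numeric vector.
#' @param x Numeric instance vector (length M <= 15).
#' @param background Numeric matrix of background rows.
#' @return A `shapley_attribution`.
#' @export
exact_shapley <- function(model, x, background) {
  M <- length(x)
  if (M > 15L) stop("M > 15: full enumeration infeasible", call. = FALSE)
  if (is.null(dim(background))) background <- matrix(background, nrow = 1)
  if (nrow(background) == 0L) stop("`background` is empty", call. = FALSE)
  n_coal <- 2^M
  coal <- matrix(FALSE, n_coal, M)
  for (j in seq_len(M)) {
    coal[, j] <- bitwAnd(0:(n_coal - 1), 2^(j - 1)) > 0
  }
  v <- coalition_values(model, x, background, coal)
  sizes <- rowSums(coal)
  w_size <- factorial(0:(M - 1)) * factorial(M - 1 - (0:(M - 1))) /
    factorial(M)
  phi <- numeric(M)
  for (i in seq_len(M)) {
    without <- which(!coal[, i])
    with_i <- without + 2^(i - 1)
    phi[i] <- sum(w_size[sizes[without] + 1] * (v[with_i] - v[without]))
  }
  names(phi) <- names(x) %||% colnames(background)
  new_shapley_attribution(phi, base_value = v[1], fx = v[n_coal])
}

#' Kernel SHAP attribution by weighted least squares
#'
#' Samples (or, when the budget allows, fully enumerates) non-boundary
#' coalitions, evaluates each as the background-averaged masked
#' prediction, and solves the Shapley-kernel weighted regression with the
#' efficiency constraint `sum(phi) = fx - base_value` eliminated exactly.
#' With all `2^M - 2` coalitions enumerated the result equals
#' [exact_shapley()] up to numerical tolerance.
#'
#' @param model Score function accepting a matrix, returning a vector.
#' @param x Numeric instance vector.
#' @param background Numeric matrix of background rows.
#' @param n_coalitions Coalition budget, default 2048.
#' @param seed Integer seed for coalition sampling.
#' @param ridge Ridge fallback added to a singular normal matrix
#'   (default 1e-8).
#' @return A `shapley_attribution`; `residual` is the weighted RMS error of
#'   the local linear model on the evaluated coalitions.
#' @export
kernel_shap <- function(model, x, background, n_coalitions = 2048L,
                        seed = 1L, ridge = 1e-8) {
  M <- length(x)
  if (M < 2L) stop("need at least 2 features", call. = FALSE)
  if (is.null(dim(background))) background <- matrix(background, nrow = 1)
  if (nrow(background) == 0L) stop("`background` is empty", call. = FALSE)
  full_budget <- 2^M - 2
  if (n_coalitions >= full_budget) {
    coal <- matrix(FALSE, full_budget, M)
    ids <- setdiff(0:(2^M - 1), c(0, 2^M - 1))
    for (j in seq_len(M)) {
      coal[, j] <- bitwAnd(ids, 2^(j - 1)) > 0
    }
    w <- shapley_kernel_weight(M, rowSums(coal))
  } else {
    coal <- with_seed(seed, {
      # sample sizes with probability proportional to the total kernel
      # weight of that size, then subsets uniformly within the size
      s_grid <- 1:(M - 1)
      p_s <- (M - 1) / (s_grid * (M - s_grid))
      p_s <- p_s / sum(p_s)
      sizes <- sample(s_grid, n_coalitions, replace = TRUE, prob = p_s)
      t(vapply(sizes, function(s) {
        z <- logical(M)
        z[sample.int(M, s)] <- TRUE
        z
      }, logical(M)))
    })
    # aggregate duplicates; sampling already follows the kernel, so each
    # distinct coalition is weighted by its draw count
    key <- apply(coal, 1, paste, collapse = "")
    tab <- table(key)
    first <- !duplicated(key)
    w <- as.numeric(tab[key[first]])
    coal <- coal[first, , drop = FALSE]
  }
  v <- coalition_values(model, x, background, coal)
  base_value <- mean(model(as.matrix(background)))
  fx <- as.numeric(model(matrix(x, nrow = 1)))
  g <- fx - base_value
  # eliminate phi_M through the efficiency constraint
  zM <- coal[, M]
  yt <- v - base_value - zM * g
  Zt <- sweep(coal[, -M, drop = FALSE] * 1, 1, zM, `-`)
  A <- crossprod(Zt, Zt * w)
  b <- crossprod(Zt, yt * w)
  phi_red <- tryCatch(solve(A, b),
                      error = function(e) solve(A + ridge * diag(nrow(A)), b))
  phi <- c(as.vector(phi_red), g - sum(phi_red))
  names(phi) <- names(x) %||% colnames(background)
  fitted <- base_value + as.vector((coal * 1) %*% phi)
  residual <- sqrt(sum(w * (v - fitted)^2) / sum(w))
  new_shapley_attribution(phi, base_value, fx, residual = residual)
}

#' Summaries of per-sample Shapley attributions
#'
#' Reproduces the interpretation tables used for a trained classifier:
#' per-feature mean absolute attribution (global importance ranking),
#' per-predicted-class mean attribution and mean feature value, and the
#' same split by prediction correctness.
#'
#' @param phi_matrix n x M matrix of per-sample attributions.
#' @param X n x M matrix of the corresponding feature values.
#' @param labels True labels (-1/+1).
#' @param predictions Predicted labels (-1/+1).
#' @return List of data frames: `importance`, `by_class`, `by_correctness`.
#' @export
shap_summary <- function(phi_matrix, X, labels, predictions) {
  phi_matrix <- as.matrix(phi_matrix)
  X <- as.matrix(X)
  stopifnot(nrow(phi_matrix) >= 1L, all(dim(phi_matrix) == dim(X)))
  feats <- colnames(phi_matrix) %||% sprintf("feature_%02d",
                                             seq_len(ncol(phi_matrix)))
  importance <- data.frame(feature = feats,
                           mean_abs_phi = colMeans(abs(phi_matrix)))
  importance <- importance[order(-importance$mean_abs_phi), ]
  importance$rank <- seq_len(nrow(importance))
  rownames(importance) <- NULL

  group_table <- function(groups) {
    out <- list()
    for (gname in names(groups)) {
      rows <- groups[[gname]]
      if (!length(rows)) next
      out[[length(out) + 1L]] <- data.frame(
        group = gname, feature = feats,
        mean_phi = colMeans(phi_matrix[rows, , drop = FALSE]),
        mean_value = colMeans(X[rows, , drop = FALSE]))
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  }
  by_class <- group_table(list(
    "predicted -1" = which(predictions == -1),
    "predicted +1" = which(predictions == 1)))
  by_correctness <- group_table(list(
    "true" = which(predictions == labels),
    "false" = which(predictions != labels)))
  list(importance = importance, by_class = by_class,
       by_correctness = by_correctness)
}
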