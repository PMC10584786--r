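#' Standardize features using parameters fit on a row subset
#'
#' Subtracts the per-column mean and divides by the per-column standard
#' deviation computed on `fit_idx` rows only; the transform is then applied
#' to all rows, so test rows never influence the parameters. Columns that
#' are constant on the fit rows are dropped with a warning.
#'
#' @param table A `feature_table`.
#' @param fit_idx Row indices used to fit the parameters (default all rows).
#' @return List: `table` (standardized `feature_table`), `center`, `scale`,
#'   `dropped` (names of removed zero-variance columns).
#' @export
standardize <- function(table, fit_idx = seq_len(nrow(table$values))) {
  stopifnot(inherits(table, "feature_table"))
  if (length(fit_idx) == 0L) stop("`fit_idx` is empty", call. = FALSE)
  X <- table$values
  ctr <- colMeans(X[fit_idx, , drop = FALSE])
  scl <- apply(X[fit_idx, , drop = FALSE], 2, sd)
  drop <- which(!is.finite(scl) | scl < 1e-12)
  if (length(drop)) {
    warning(sprintf("dropping %d zero-variance column(s): %s",
                    length(drop),
                    paste(names(drop), collapse = ", ")), call. = FALSE)
    X <- X[, -drop, drop = FALSE]
    ctr <- ctr[-drop]; scl <- scl[-drop]
  }
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  list(table = feature_table(Xs, table$labels,
                             relevance = if (is.null(table$relevance)) NULL
                             else table$relevance[
                               table$relevance$name %in% colnames(Xs), ,
                               drop = FALSE]),
       center = ctr, scale = scl,
       dropped = names(drop))
}

#' Stratified train/test split
#'
#' Draws `round(fraction * n_c)` training rows from each class `c`
#' uniformly at random under the seed; remaining rows form the test set.
#'
#' @param labels Class labels (-1/+1), each class with >= 2 members.
#' @param fraction Training fraction in (0, 1), default 0.7.
#' @param seed Integer seed.
#' @return List with disjoint `train_idx` and `test_idx` covering all rows.
#' @export
stratified_split <- function(labels, fraction = 0.7, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie strictly in (0, 1)", call. = FALSE)
  }
  if (any(table(labels) < 2L)) {
    stop("each class needs at least 2 members", call. = FALSE)
  }
  with_seed(seed, {
    train <- integer(0)
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      n_tr <- round(fraction * length(idx))
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
      train <- c(train, sort(sample(idx, n_tr)))
    }
    train <- sort(train)
    list(train_idx = train,
         test_idx = setdiff(seq_along(labels), train),
         fraction = fraction)
  })
}

#' SMOTE oversampling combined with random undersampling
#'
#' The minority class is oversampled by convex interpolation between a
#' minority sample and one of its `k_neighbors` nearest minority neighbors
#' (uniform mixing weight), and the majority class is randomly subsampled
#' without replacement. Sizing meets in the middle: the minority grows to
#' `m = min(2 * n_min, round(target_ratio * n_maj))` and the majority
#' shrinks to `round(m / target_ratio)`, so the final minority:majority
#' ratio equals `target_ratio`.
#'
#' @param X Numeric matrix of training rows.
#' @param y Labels (-1/+1); minority count must exceed `k_neighbors`.
#' @param k_neighbors Neighborhood size for interpolation, default 5.
#' @param target_ratio Final minority/majority ratio, default 1.
#' @param seed Integer seed.
#' @return List: `X`, `y` (resampled), plus `synthetic` (logical flag per
#'   returned row).
#' @export
resample_balance <- function(X, y, k_neighbors = 5L, target_ratio = 1,
                             seed = 1L) {
  X <- as.matrix(X)
  classes <- sort(unique(y))
  stopifnot(length(classes) == 2L)
  cnt <- table(factor(y, levels = classes))
  minority <- classes[which.min(cnt)]
  majority <- classes[which.max(cnt)]
  n_min <- sum(y == minority); n_maj <- sum(y == majority)
  if (n_min <= k_neighbors) {
    stop("minority count must exceed `k_neighbors`", call. = FALSE)
  }
  m_target <- min(2L * n_min, round(target_ratio * n_maj))
  maj_target <- round(m_target / target_ratio)
  maj_target <- min(maj_target, n_maj)
  with_seed(seed, {
    Xmin <- X[y == minority, , drop = FALSE]
    n_new <- m_target - n_min
    synth <- NULL
    if (n_new > 0) {
      D <- as.matrix(dist(Xmin))
      diag(D) <- Inf
      nn <- t(apply(D, 1, function(r) order(r)[seq_len(k_neighbors)]))
      base <- sample.int(n_min, n_new, replace = TRUE)
      pick <- nn[cbind(base, sample.int(k_neighbors, n_new, replace = TRUE))]
      t_mix <- runif(n_new)
      synth <- Xmin[base, , drop = FALSE] +
        t_mix * (Xmin[pick, , drop = FALSE] - Xmin[base, , drop = FALSE])
    }
    maj_rows <- which(y == majority)
    keep_maj <- sort(sample(maj_rows, maj_target))
    X_out <- rbind(X[y == minority, , drop = FALSE],
                   synth,
                   X[keep_maj, , drop = FALSE])
    y_out <- c(rep(minority, n_min + max(0L, n_new)),
               rep(majority, maj_target))
    list(X = X_out, y = y_out,
         synthetic = c(rep(FALSE, n_min), rep(TRUE, max(0L, n_new)),
                       rep(FALSE, maj_target)))
  })
}

#' Prune highly correlated features by Spearman rank correlation
#'
#' Greedy scan in priority order: a column is kept only if its absolute
#' Spearman correlation with every already-kept column stays at or below
#' the threshold. By default the priority is each column's marginal mutual
#' information with the labels (higher first), so the informative member of
#' a redundant pair survives; with `y = NULL` the column order is used.
#'
#' @param X Numeric matrix (>= 2 columns).
#' @param threshold Correlation threshold, default 0.8.
#' @param y Optional labels used to rank columns by marginal MI.
#' @param bins Bins for the MI estimate (see [estimate_mi()]).
#' @return Sorted indices of kept columns; no surviving pair exceeds the
#'   threshold.
#' @export
spearman_prune <- function(X, threshold = 0.8, y = NULL, bins = 4L) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("`X` needs at least 2 columns", call. = FALSE)
  rho <- abs(cor(X, method = "spearman"))
  priority <- if (is.null(y)) {
    seq_len(ncol(X))
  } else {
    mi <- vapply(seq_len(ncol(X)), function(j) estimate_mi(X[, j], y, bins),
                 numeric(1))
    order(-mi, seq_len(ncol(X)))
  }
  kept <- integer(0)
  for (j in priority) {
    if (all(rho[j, kept] <= threshold)) kept <- c(kept, j)
  }
  sort(kept)
}

#' Sparse linear max-margin feature selection
#'
#' Fits an L1-penalized linear hinge-loss classifier by proximal
#' subgradient descent (soft-thresholding after each step, step size
#' `eta / sqrt(t)`), and returns the columns whose coefficients exceed a
#' small tolerance. Intended as a fast sparsity-inducing primary filter,
#' not a calibrated classifier.
#'
#' @param X Standardized numeric matrix.
#' @param y Labels (-1/+1), both classes present.
#' @param penalty_strength L1 penalty weight, default 0.01.
#' @param max_iter Iterations, default 2000.
#' @param eta Base step size, default 0.1.
#' @param tol Coefficient magnitude threshold, default 1e-5.
#' @return Sorted indices of selected columns (attribute `weights` carries
#'   the fitted coefficients).
#' @export
linear_margin_select <- function(X, y, penalty_strength = 0.01,
                                 max_iter = 2000L, eta = 0.1, tol = 1e-5) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2L) stop("both classes required", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  w <- numeric(p); b <- 0
  obj <- function(w, b) {
    margins <- y * (X %*% w + b)
    mean(pmax(0, 1 - margins)) + penalty_strength * sum(abs(w))
  }
  prev <- obj(w, b)
  converged <- FALSE
  for (t in seq_len(max_iter)) {
    margins <- y * (X %*% w + b)
    active <- as.numeric(margins < 1)
    grad_w <- -crossprod(X, active * y) / n
    grad_b <- -mean(active * y)
    step <- eta / sqrt(t)
    w <- w - step * as.vector(grad_w)
    w <- sign(w) * pmax(0, abs(w) - step * penalty_strength)
    b <- b - step * grad_b
    if (t %% 100L == 0L) {
      cur <- obj(w, b)
      if (abs(prev - cur) < 1e-8 * max(1, abs(prev))) {
        converged <- TRUE
        break
      }
      prev <- cur
    }
  }
  if (!converged && max_iter >= 100L) {
    # subgradient methods converge slowly; report but keep the solution
    warning("linear margin selector reached max_iter without convergence",
            call. = FALSE)
  }
  out <- sort(which(abs(w) > tol))
  attr(out, "weights") <- w
  out
}

#' Rank features by marginal mutual information
#'
#' @param X Numeric matrix.
#' @param y Labels.
#' @param top_m How many columns to return (default 17).
#' @param bins Bins for the MI estimate.
#' @return Column indices ordered by decreasing estimated MI (ties broken
#'   by column order).
#' @export
mi_rank <- function(X, y, top_m = 17L, bins = 4L) {
  X <- as.matrix(X)
  if (top_m > ncol(X)) stop("`top_m` exceeds the number of columns",
                            call. = FALSE)
  mi <- vapply(seq_len(ncol(X)), function(j) estimate_mi(X[, j], y, bins),
               numeric(1))
  head(order(-mi, seq_len(ncol(X))), top_m)
}
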