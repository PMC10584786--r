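#' Construct a cardinality-penalized QUBO problem
#'
#' The selection objective (to be minimized over binary `x`) is
#' `-sum_i Q_ii x_i - sum_{i<j} (Q_ij + Q_ji) x_i x_j +
#'  alpha * (sum_i x_i - k)^2`,
#' i.e. the mutual-information quadratic form plus a penalty that drives
#' solutions toward cardinality `k`. `alpha = "auto"` uses
#' `sum_i Q_ii + sum_{i<j} |Q_ij + Q_ji|`, an upper bound on the objective
#' range which guarantees a cardinality-`k` optimum.
#'
#' @param Q p x p matrix: MI on the diagonal, CMI off it (bits).
#' @param k Target cardinality, `1 <= k <= p`.
#' @param alpha Penalty amplitude (>= 0) or `"auto"`.
#' @return A `qubo_problem` list: `Q`, `k`, `alpha`.
#' @export
qubo_problem <- function(Q, k, alpha = "auto") {
  Q <- as.matrix(Q)
  p <- nrow(Q)
  if (ncol(Q) != p || p < 1L) stop("`Q` must be a square matrix", call. = FALSE)
  if (any(diag(Q) < -1e-9)) {
    stop("diagonal MI entries must be non-negative (up to estimator noise)",
         call. = FALSE)
  }
  if (k < 1L || k > p) stop("`k` must lie in [1, p]", call. = FALSE)
  if (identical(alpha, "auto")) {
    C <- Q + t(Q)
    alpha <- sum(pmax(diag(Q), 0)) + sum(abs(C[upper.tri(C)]))
  }
  if (!is.numeric(alpha) || alpha < 0) {
    stop("`alpha` must be >= 0 or \"auto\"", call. = FALSE)
  }
  structure(list(Q = Q, k = as.integer(k), alpha = alpha),
            class = "qubo_problem")
}

#' QUBO energy of a binary configuration
#'
#' @param problem A [qubo_problem()].
#' @param x Binary vector of length p.
#' @return Scalar energy (lower is better).
#' @export
qubo_energy <- function(problem, x) {
  stopifnot(inherits(problem, "qubo_problem"))
  Q <- problem$Q
  if (length(x) != nrow(Q)) stop("`x` has wrong length", call. = FALSE)
  x <- as.numeric(x)
  C <- Q + t(Q)
  diag(C) <- 0
  -sum(diag(Q) * x) - sum((C %*% x) * x) / 2 +
    problem$alpha * (sum(x) - problem$k)^2
}

# linear, pairwise (upper-triangular) and constant coefficients of the
# minimization-form QUBO including the penalty expansion
qubo_coefficients <- function(problem) {
  Q <- problem$Q
  p <- nrow(Q)
  a <- problem$alpha
  k <- problem$k
  lin <- -diag(Q) + a * (1 - 2 * k)
  C <- Q + t(Q)
  diag(C) <- 0
  B <- -C + 2 * a          # pairwise coefficient for i < j
  diag(B) <- 0
  list(lin = lin, B = B, const = a * k^2)
}

#' Map a QUBO to an Ising Hamiltonian
#'
#' Substitutes `x_i = (1 - s_i) / 2` with spins `s in {-1, +1}`, so that
#' for every configuration
#' `qubo_energy(problem, x) = sum_i h_i s_i + sum_{i<j} J_ij s_i s_j +
#'  offset`.
#'
#' @param problem A [qubo_problem()].
#' @return List: `h` (length-p fields), `J` (upper-triangular coupling
#'   matrix), `offset`.
#' @export
to_ising <- function(problem) {
  co <- qubo_coefficients(problem)
  p <- length(co$lin)
  Bu <- co$B
  Bu[lower.tri(Bu, diag = TRUE)] <- 0
  J <- Bu / 4
  h <- -co$lin / 2 - (rowSums(Bu) + colSums(Bu)) / 4
  offset <- co$const + sum(co$lin) / 2 + sum(Bu) / 4
  list(h = h, J = J, offset = offset)
}

#' Ising energy of a spin configuration (excluding the offset)
#'
#' @param ising Output of [to_ising()].
#' @param s Spin vector in -1/+1.
#' @return Scalar energy.
#' @export
ising_energy <- function(ising, s) {
  sum(ising$h * s) + sum((ising$J %*% s) * s)
}

new_qubo_solution <- function(x, problem, reads, solver) {
  structure(
    list(x = as.integer(x), energy = qubo_energy(problem, x),
         cardinality = sum(x), reads = reads, solver = solver),
    class = "qubo_solution"
  )
}

#' @export
print.qubo_solution <- function(x, ...) {
  cat(sprintf("<qubo_solution> solver %s  energy %.6g  cardinality %d\n",
              x$solver, x$energy, x$cardinality))
  cat("  x:", paste(x$x, collapse = ""), "\n")
  invisible(x)
}

#' Exhaustive QUBO ground-state search
#'
#' Enumerates all `2^p` configurations (or all `choose(p, k)` subsets when
#' the cardinality constraint is treated as hard) and returns the global
#' minimum. Enumeration is lexicographic with `x_1` as the most significant
#' bit, and ties resolve to the first (lexicographically smallest)
#' configuration.
#'
#' @param problem A [qubo_problem()] with `p <= 22`.
#' @param constraint `"penalty"` (default) scores the penalized objective
#'   over all configurations; `"hard"` enumerates only cardinality-`k`
#'   subsets and drops the penalty term.
#' @return A `qubo_solution`.
#' @export
solve_exhaustive <- function(problem, constraint = c("penalty", "hard")) {
  stopifnot(inherits(problem, "qubo_problem"))
  constraint <- match.arg(constraint)
  p <- nrow(problem$Q)
  if (p > 22L) {
    stop("p > 22: exhaustive enumeration infeasible, use solve_anneal()",
         call. = FALSE)
  }
  co <- qubo_coefficients(problem)
  energy_of <- function(Xm, penalized = TRUE) {
    Bu <- co$B
    Bu[lower.tri(Bu, diag = TRUE)] <- 0
    e <- as.vector(Xm %*% co$lin) + rowSums((Xm %*% Bu) * Xm)
    if (penalized) e + co$const else
      e - problem$alpha * (rowSums(Xm) - problem$k)^2 + co$const
  }
  if (constraint == "hard") {
    subsets <- combn(p, problem$k)
    Xm <- matrix(0, ncol(subsets), p)
    Xm[cbind(rep(seq_len(ncol(subsets)), each = problem$k),
             as.vector(subsets))] <- 1
    # without the penalty the quadratic form alone ranks the subsets
    Qonly <- qubo_problem(problem$Q, problem$k, alpha = 0)
    coq <- qubo_coefficients(Qonly)
    Bu <- coq$B
    Bu[lower.tri(Bu, diag = TRUE)] <- 0
    e <- as.vector(Xm %*% coq$lin) + rowSums((Xm %*% Bu) * Xm)
    best <- which.min(e)
    return(new_qubo_solution(Xm[best, ], problem, reads = NA_integer_,
                             solver = "exhaustive"))
  }
  n_states <- 2^p
  chunk <- 2^min(p, 16L)
  best_e <- Inf
  best_x <- NULL
  bit_mat <- function(ids, p) {
    # row per state; x_1 is the most significant bit
    m <- matrix(0, length(ids), p)
    for (j in seq_len(p)) {
      m[, j] <- ids %/% 2^(p - j) %% 2
    }
    m
  }
  for (start in seq(0, n_states - 1, by = chunk)) {
    ids <- start:min(start + chunk - 1, n_states - 1)
    Xm <- bit_mat(ids, p)
    e <- energy_of(Xm)
    i <- which.min(e)
    if (e[i] < best_e) {
      best_e <- e[i]
      best_x <- Xm[i, ]
    }
  }
  new_qubo_solution(best_x, problem, reads = NA_integer_,
                    solver = "exhaustive")
}

#' Simulated-annealing QUBO solver
#'
#' Best-of-`reads` single-spin-flip Metropolis annealing with a geometric
#' temperature schedule, standing in for a quantum annealer: each read
#' starts from a random configuration and sweeps all variables
#' sequentially while the temperature decays from `t_hot` to `t_cold`.
#' Deterministic given `seed`; reads consume the random stream
#' sequentially, so increasing `reads` never worsens the best energy found.
#'
#' @param problem A [qubo_problem()].
#' @param reads Number of restarts, default 5000.
#' @param sweeps Sweeps per read, default 200.
#' @param t_hot,t_cold Temperature schedule endpoints; defaults scale with
#'   the largest possible single-flip energy change.
#' @param seed Integer seed.
#' @return A `qubo_solution` with per-read best energies in
#'   `attr(, "read_energies")`.
#' @export
solve_anneal <- function(problem, reads = 5000L, sweeps = 200L,
                         t_hot = NULL, t_cold = NULL, seed = 1L) {
  stopifnot(inherits(problem, "qubo_problem"))
  if (reads < 1L) stop("`reads` must be >= 1", call. = FALSE)
  co <- qubo_coefficients(problem)
  dmax <- max(abs(co$lin) + rowSums(abs(co$B)))
  dmax <- max(dmax, 1e-9)
  t_hot <- t_hot %||% dmax
  t_cold <- t_cold %||% (1e-3 * dmax)
  res <- with_seed(seed, {
    anneal_qubo_cpp(co$lin, co$B, as.integer(reads), as.integer(sweeps),
                    t_hot, t_cold)
  })
  sol <- new_qubo_solution(res$x, problem, reads = as.integer(reads),
                           solver = "annealing")
  attr(sol, "read_energies") <- res$read_energies + co$const
  sol
}

#' QUBO mutual-information feature selection
#'
#' Builds the MI/CMI Q matrix, forms the cardinality-`k` penalized QUBO,
#' solves it (exhaustively for `p <= 22`, otherwise by simulated
#' annealing), and returns the selected feature indices ordered by
#' decreasing marginal MI.
#'
#' @param X Numeric n x p matrix (p >= k).
#' @param y Labels (-1/+1).
#' @param k Number of features to select, default 10.
#' @param bins Bins for the MI estimators.
#' @param alpha Penalty amplitude or `"auto"`.
#' @param reads Annealer reads (used only when p > 22), default 5000.
#' @param seed Integer seed.
#' @param solver `"auto"`, `"exhaustive"`, or `"anneal"`.
#' @return Integer vector of selected column indices, with the solved
#'   `qubo_solution` in `attr(, "solution")` and the Q matrix in
#'   `attr(, "Q")`.
#' @export
select_features <- function(X, y, k = 10L, bins = 4L, alpha = "auto",
                            reads = 5000L, seed = 1L,
                            solver = c("auto", "exhaustive", "anneal")) {
  solver <- match.arg(solver)
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < k) stop("fewer columns than `k`", call. = FALSE)
  Q <- build_q_matrix(X, y, bins)
  problem <- qubo_problem(Q, k, alpha)
  if (solver == "auto") solver <- if (p <= 22L) "exhaustive" else "anneal"
  sol <- if (solver == "exhaustive") {
    solve_exhaustive(problem)
  } else {
    solve_anneal(problem, reads = reads, seed = seed)
  }
  if (identical(alpha, "auto") && sol$cardinality != problem$k &&
      solver == "exhaustive") {
    stop("internal error: cardinality constraint violated under auto alpha",
         call. = FALSE)
  }
  idx <- which(sol$x == 1L)
  idx <- idx[order(-diag(Q)[idx], idx)]
  attr(idx, "solution") <- sol
  attr(idx, "Q") <- Q
  idx
}
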