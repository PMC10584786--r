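# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so no function in the package leaks random state.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
}

check_3d <- function(x, name) {
  if (is.null(dim(x)) || length(dim(x)) != 3L) {
    stop(sprintf("`%s` must be a 3D array", name), call. = FALSE)
  }
}

# shift a 3D array by `s` voxels along axis `ax`, padding with `fill`
shift3d <- function(x, ax, s, fill = 0) {
  d <- dim(x)
  out <- array(fill, d)
  if (s == 0) return(x)
  if (abs(s) >= d[ax]) return(out)
  src <- dst <- lapply(d, seq_len)
  if (s > 0) {
    dst[[ax]] <- (1 + s):d[ax]
    src[[ax]] <- 1:(d[ax] - s)
  } else {
    dst[[ax]] <- 1:(d[ax] + s)
    src[[ax]] <- (1 - s):d[ax]
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

# shift by an integer offset vector, zero padding
shift3d_offset <- function(x, off, fill = 0) {
  for (ax in 1:3) {
    if (off[ax] != 0) x <- shift3d(x, ax, off[ax], fill = fill)
  }
  x
}

# 1D convolution along one axis of a 3D array; kernel indexed -r..r
# boundary: "replicate" (edge value extension) or "periodic"
conv_axis3d <- function(x, kernel, ax, boundary = c("replicate", "periodic")) {
  boundary <- match.arg(boundary)
  r <- (length(kernel) - 1L) %/% 2L
  d <- dim(x)
  out <- array(0, d)
  for (i in -r:r) {
    w <- kernel[i + r + 1L]
    if (w == 0) next
    if (boundary == "periodic") {
      idx <- lapply(d, seq_len)
      idx[[ax]] <- ((seq_len(d[ax]) + i - 1L) %% d[ax]) + 1L
      out <- out + w * x[idx[[1]], idx[[2]], idx[[3]]]
    } else {
      idx <- lapply(d, seq_len)
      idx[[ax]] <- pmin(pmax(seq_len(d[ax]) + i, 1L), d[ax])
      out <- out + w * x[idx[[1]], idx[[2]], idx[[3]]]
    }
  }
  out
}

# separable Gaussian smoothing of a 3D array, sigma in voxels per axis
gaussian_smooth3d <- function(x, sigma, boundary = "replicate") {
  sigma <- rep(sigma, length.out = 3)
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    r <- max(1L, ceiling(3 * sigma[ax]))
    k <- dnorm(-r:r, sd = sigma[ax])
    k <- k / sum(k)
    x <- conv_axis3d(x, k, ax, boundary = boundary)
  }
  x
}

# the 13 unique 3D direction offsets (one per +/- pair), distance 1
offsets_13 <- function() {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  keep <- apply(offs, 1, function(d) {
    first <- d[which(d != 0)[1]]
    first > 0
  })
  unname(offs[keep, , drop = FALSE])
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}
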