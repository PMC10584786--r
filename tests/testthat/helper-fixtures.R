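# programmatic fixtures and independent brute-force oracles

ball_mask <- function(r, n = 2 * r + 5, center = (n + 1) / 2) {
  g <- expand.grid(x = seq_len(n), y = seq_len(n), z = seq_len(n))
  array((g$x - center)^2 + (g$y - center)^2 + (g$z - center)^2 <= r^2,
        c(n, n, n))
}

rod_mask <- function(k, pad = 3) {
  d <- c(2 * pad + 1, 2 * pad + 1, k + 2 * pad)
  m <- array(FALSE, d)
  m[pad + 1, pad + 1, (pad + 1):(pad + k)] <- TRUE
  m
}

random_blob_mask <- function(seed, n = 24) {
  set.seed(seed)
  f <- array(rnorm(n^3), c(n, n, n))
  f <- qradbrain:::gaussian_smooth3d(f, 3)
  m <- f > quantile(f, 0.85)
  # keep the largest connected piece crudely: erode/dilate not needed for
  # the sphericity bound; just require enough voxels
  if (sum(m) < 30) m <- f > quantile(f, 0.7)
  m
}

# naive triple-loop texture counters (independent oracle)
naive_glcm <- function(labels, mask, n_levels, directions) {
  d <- dim(labels)
  counts <- matrix(0, n_levels, n_levels)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (!mask[x, y, z]) next
    for (r in seq_len(nrow(directions))) {
      for (sgn in c(1, -1)) {
        p <- c(x, y, z) + sgn * directions[r, ]
        if (any(p < 1) || any(p > d)) next
        if (!mask[p[1], p[2], p[3]]) next
        i <- labels[x, y, z]; j <- labels[p[1], p[2], p[3]]
        counts[i, j] <- counts[i, j] + 1
      }
    }
  }
  counts / sum(counts)
}

naive_glrlm <- function(labels, mask, n_levels, directions) {
  d <- dim(labels)
  counts <- matrix(0, n_levels, max(d))
  inside <- function(p) all(p >= 1) && all(p <= d)
  at <- function(p) list(m = mask[p[1], p[2], p[3]],
                         l = labels[p[1], p[2], p[3]])
  for (r in seq_len(nrow(directions))) {
    dir <- directions[r, ]
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      p <- c(x, y, z)
      if (!mask[x, y, z]) next
      lv <- labels[x, y, z]
      prev <- p - dir
      if (inside(prev) && at(prev)$m && at(prev)$l == lv) next  # not a start
      len <- 1
      nxt <- p + dir
      while (inside(nxt) && at(nxt)$m && at(nxt)$l == lv) {
        len <- len + 1
        nxt <- nxt + dir
      }
      counts[lv, len] <- counts[lv, len] + 1
    }
  }
  counts
}

naive_glszm <- function(labels, mask, n_levels) {
  d <- dim(labels)
  seen <- array(FALSE, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  zones <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (!mask[x, y, z] || seen[x, y, z]) next
    lv <- labels[x, y, z]
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (any(q < 1) || any(q > d)) next
        if (!mask[q[1], q[2], q[3]] || seen[q[1], q[2], q[3]]) next
        if (labels[q[1], q[2], q[3]] != lv) next
        seen[q[1], q[2], q[3]] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
    zones[[length(zones) + 1]] <- c(lv, size)
  }
  zm <- do.call(rbind, zones)
  counts <- matrix(0, n_levels, max(zm[, 2]))
  for (i in seq_len(nrow(zm))) {
    counts[zm[i, 1], zm[i, 2]] <- counts[zm[i, 1], zm[i, 2]] + 1
  }
  counts
}

# a 10-feature table that is linearly separable with margin along a random
# direction and isotropic noise in the orthogonal complement
gen_separable_table <- function(n = 200, seed = 1) {
  set.seed(seed)
  y <- rep(c(-1, 1), length.out = n)
  w <- rnorm(10); w <- w / sqrt(sum(w^2))
  t_proj <- y * runif(n, 1, 2)
  noise <- matrix(rnorm(n * 10), n, 10) %*% (diag(10) - outer(w, w))
  list(X = outer(t_proj, w) + noise, y = y)
}

random_qubo <- function(p, seed) {
  set.seed(seed)
  Q <- matrix(rnorm(p * p, sd = 0.3), p, p)
  diag(Q) <- runif(p)
  k <- sample(2:(p - 2), 1)
  qubo_problem(Q, k, alpha = "auto")
}

random_amplitude <- function() {
  a <- abs(rnorm(4))
  a / sqrt(sum(a^2))
}
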