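#' Gray-level co-occurrence matrix
#'
#' Counts co-occurrences of discretized gray levels between masked voxels at
#' distance-1 offsets, aggregated at the matrix level (summed over
#' directions before normalization) and symmetrized, then normalized to sum
#' to 1.
#'
#' @param labels 3D integer array of gray levels in `[1, n_levels]`.
#' @param mask 3D logical array.
#' @param n_levels Number of gray levels.
#' @param directions Integer matrix of direction offsets (rows), default the
#'   13 unique 3D directions.
#' @return `n_levels` x `n_levels` matrix of joint probabilities.
#' @export
glcm_matrix <- function(labels, mask, n_levels,
                        directions = offsets_13()) {
  check_3d(labels, "labels")
  counts <- matrix(0, n_levels, n_levels)
  for (r in seq_len(nrow(directions))) {
    d <- directions[r, ]
    nb_lab <- shift3d_offset(labels, -d, fill = 0L)
    nb_msk <- shift3d_offset(mask, -d, fill = FALSE)
    valid <- mask & nb_msk
    if (!any(valid)) next
    i <- labels[valid]; j <- nb_lab[valid]
    tab <- tabulate((j - 1L) * n_levels + i, nbins = n_levels * n_levels)
    counts <- counts + matrix(tab, n_levels, n_levels)
  }
  counts <- counts + t(counts)  # symmetric pairs
  s <- sum(counts)
  if (s == 0) stop("no co-occurring voxel pairs inside mask", call. = FALSE)
  counts / s
}

#' Gray-level run-length matrix
#'
#' Counts maximal runs of equal gray level along each direction, aggregated
#' over directions. Rows index gray levels, columns run lengths.
#'
#' @inheritParams glcm_matrix
#' @return Matrix of non-negative integer run counts.
#' @export
glrlm_matrix <- function(labels, mask, n_levels,
                         directions = offsets_13()) {
  check_3d(labels, "labels")
  max_len <- max(dim(labels))
  counts <- matrix(0, n_levels, max_len)
  for (r in seq_len(nrow(directions))) {
    d <- directions[r, ]
    nxt_lab <- shift3d_offset(labels, -d, fill = 0L)
    nxt_msk <- shift3d_offset(mask, -d, fill = FALSE)
    same_nxt <- mask & nxt_msk & (labels == nxt_lab)
    prv_lab <- shift3d_offset(labels, d, fill = 0L)
    prv_msk <- shift3d_offset(mask, d, fill = FALSE)
    same_prv <- mask & prv_msk & (labels == prv_lab)
    start <- mask & !same_prv
    # remaining run length by fixed-point propagation against the direction
    run <- array(as.numeric(mask), dim(labels))
    repeat {
      nxt_run <- shift3d_offset(run, -d, fill = 0)
      run_new <- as.numeric(mask) + ifelse(same_nxt, nxt_run, 0)
      if (all(run_new == run)) break
      run <- run_new
    }
    lv <- labels[start]; ln <- run[start]
    tab <- tabulate((ln - 1L) * n_levels + lv, nbins = n_levels * max_len)
    counts <- counts + matrix(tab, n_levels, max_len)
  }
  counts
}

#' Gray-level size-zone matrix
#'
#' Zones are 26-connected components of equal gray level inside the mask.
#' Rows index gray levels, columns zone sizes.
#'
#' @inheritParams glcm_matrix
#' @return Matrix of non-negative integer zone counts.
#' @export
glszm_matrix <- function(labels, mask, n_levels,
                         directions = offsets_13()) {
  check_3d(labels, "labels")
  nvox <- sum(mask)
  if (nvox == 0) stop("`mask` is empty", call. = FALSE)
  idx <- array(0L, dim(labels))
  idx[mask] <- seq_len(nvox)
  edges <- integer(0)
  for (r in seq_len(nrow(directions))) {
    d <- directions[r, ]
    nb_idx <- shift3d_offset(idx, -d, fill = 0L)
    nb_lab <- shift3d_offset(labels, -d, fill = 0L)
    ok <- mask & (nb_idx > 0L) & (labels == nb_lab)
    if (any(ok)) edges <- c(edges, rbind(idx[ok], nb_idx[ok]))
  }
  g <- igraph::make_graph(edges, n = nvox, directed = FALSE)
  comp <- igraph::components(g)
  zone_size <- comp$csize[comp$membership]
  # one entry per zone: take the first voxel of each component
  first <- !duplicated(comp$membership)
  lv <- labels[mask][first]
  sz <- comp$csize
  counts <- matrix(0, n_levels, max(sz))
  tab <- tabulate((sz - 1L) * n_levels + lv, nbins = n_levels * max(sz))
  counts + matrix(tab, n_levels, max(sz))
}

#' Texture summary statistics
#'
#' The texture features used by the classifier and its interpretation:
#' GLCM contrast and cluster prominence, GLRLM run entropy and GLSZM zone
#' entropy, all with base-2 logarithms and the `0 log 0 = 0` convention.
#'
#' @inheritParams glcm_matrix
#' @return Named list: `glcm_contrast`, `glcm_cluster_prominence`,
#'   `glrlm_run_entropy`, `glszm_zone_entropy`.
#' @export
texture_stats <- function(labels, mask, n_levels,
                          directions = offsets_13()) {
  if (sum(mask) < 2L) stop("mask must contain at least 2 voxels",
                           call. = FALSE)
  if (any(labels[mask] < 1L | labels[mask] > n_levels)) {
    stop("labels inside mask must lie in [1, n_levels]", call. = FALSE)
  }
  P <- glcm_matrix(labels, mask, n_levels, directions)
  ii <- row(P); jj <- col(P)
  contrast <- sum(P * (ii - jj)^2)
  mu_i <- sum(ii * P); mu_j <- sum(jj * P)
  prominence <- sum(P * (ii + jj - mu_i - mu_j)^4)
  R <- glrlm_matrix(labels, mask, n_levels, directions)
  run_entropy <- entropy_bits(R / sum(R))
  Z <- glszm_matrix(labels, mask, n_levels, directions)
  zone_entropy <- entropy_bits(Z / sum(Z))
  list(glcm_contrast = contrast,
       glcm_cluster_prominence = prominence,
       glrlm_run_entropy = run_entropy,
       glszm_zone_entropy = zone_entropy)
}
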