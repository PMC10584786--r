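#' Z-score intensity normalization
#'
#' Centers and scales the image so masked voxels have mean 0 and unit
#' variance; the same affine map is applied to voxels outside the mask.
#'
#' @param image 3D numeric array.
#' @param mask 3D logical array, non-empty. Defaults to the whole volume.
#' @return Normalized 3D array.
#' @export
zscore_normalize <- function(image, mask = NULL) {
  check_3d(image, "image")
  if (is.null(mask)) mask <- array(TRUE, dim(image))
  if (!any(mask)) stop("`mask` is empty", call. = FALSE)
  v <- image[mask]
  s <- sd(v)
  if (!is.finite(s) || s < 1e-12) {
    stop("zero intensity variance inside mask", call. = FALSE)
  }
  (image - mean(v)) / s
}

#' Fixed-bin-number gray-level discretization
#'
#' Equal-width bins spanning the min..max of the masked intensities; the
#' maximum intensity maps to bin `n_bins`. A constant image maps every voxel
#' to bin 1 (documented convention, not an error).
#'
#' @param image 3D numeric array.
#' @param mask 3D logical array.
#' @param n_bins Number of gray levels (>= 2), default 32.
#' @return 3D integer array of bin labels in `[1, n_bins]` (values outside
#'   the mask are clamped into the same range).
#' @export
discretize_fbn <- function(image, mask, n_bins = 32L) {
  check_3d(image, "image")
  if (n_bins < 2L) stop("`n_bins` must be >= 2", call. = FALSE)
  v <- image[mask]
  lo <- min(v); hi <- max(v)
  if (hi - lo < 1e-300) {
    return(array(1L, dim(image)))
  }
  lab <- floor((image - lo) / (hi - lo) * n_bins) + 1L
  lab <- pmin(pmax(lab, 1L), as.integer(n_bins))
  array(as.integer(lab), dim(image))
}

#' Laplacian-of-Gaussian filter
#'
#' Sum of second Gaussian derivatives along the three axes, computed with
#' separable sampled kernels. Second-derivative kernels are corrected to
#' have zero sum and exact second moment, so constant and linear-ramp images
#' give an (interior) zero response.
#'
#' @param image 3D numeric array.
#' @param sigma Filter scale in mm (> 0), default 1.
#' @param spacing Voxel spacing in mm.
#' @return Filtered 3D array.
#' @export
log_filter <- function(image, sigma = 1, spacing = c(1, 1, 1)) {
  check_3d(image, "image")
  if (sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  sig_vox <- sigma / spacing
  kgauss <- function(s) {
    r <- max(2L, ceiling(4 * s))
    k <- dnorm(-r:r, sd = s)
    k / sum(k)
  }
  kd2 <- function(s) {
    r <- max(2L, ceiling(4 * s))
    x <- -r:r
    k <- (x^2 - s^2) / s^4 * dnorm(x, sd = s)
    k <- k - mean(k)                  # zero response to constants
    k * (2 / sum(k * x^2))            # exact curvature of x^2
  }
  out <- array(0, dim(image))
  for (ax in 1:3) {
    part <- image
    for (bx in 1:3) {
      kern <- if (bx == ax) kd2(sig_vox[bx]) else kgauss(sig_vox[bx])
      part <- conv_axis3d(part, kern, bx, boundary = "replicate")
    }
    # scale-normalize each axis term to physical units (1/mm^2)
    out <- out + part / spacing[ax]^2
  }
  out
}

#' One-level 3D Haar wavelet sub-bands
#'
#' Undecimated single-level separable Haar decomposition with periodic
#' boundary and energy-normalized filters `L = (1/2, 1/2)`,
#' `H = (1/2, -1/2)` per axis, so the eight same-size sub-bands form a tight
#' frame: their energies sum to the input energy. Sub-band names give the
#' per-axis filter sequence for array axes 1..3 (e.g. `LLH` = low-pass along
#' axes 1 and 2, high-pass along axis 3).
#'
#' @param image 3D numeric array with all dimensions >= 2.
#' @return Named list of eight 3D arrays: `LLL`, `LLH`, `LHL`, `LHH`,
#'   `HLL`, `HLH`, `HHL`, `HHH`.
#' @export
wavelet_subbands <- function(image) {
  check_3d(image, "image")
  if (any(dim(image) < 2L)) stop("array too small for the Haar filter",
                                 call. = FALSE)
  pass <- function(x, ax, type) {
    d <- dim(x)
    idx <- lapply(d, seq_len)
    idx[[ax]] <- c(2:d[ax], 1L)  # periodic neighbor
    nb <- x[idx[[1]], idx[[2]], idx[[3]]]
    if (type == "L") (x + nb) / 2 else (x - nb) / 2
  }
  out <- list()
  for (a1 in c("L", "H")) {
    x1 <- pass(image, 1, a1)
    for (a2 in c("L", "H")) {
      x2 <- pass(x1, 2, a2)
      for (a3 in c("L", "H")) {
        out[[paste0(a1, a2, a3)]] <- pass(x2, 3, a3)
      }
    }
  }
  out[c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")]
}
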