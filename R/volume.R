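#' Generate a synthetic ring-enhancing lesion volume
#'
#' Simulates a 3D grayscale volume containing a single enhancing lesion with
#' a peritumoral ring, emulating the two lesion phenotypes the classifier is
#' built to separate: metastasis-like lesions (`label = -1`) are close to
#' spherical with fine-grained (high run-entropy) internal texture, while
#' glioma-like lesions (`label = +1`) have irregular margins and smoother,
#' more slowly varying internal texture.
#'
#' The lesion boundary is an ellipsoid whose radius is modulated along each
#' direction by a smooth random field (a small sum of low-frequency cosine
#' modes of the unit direction vector); `shape_irregularity` scales the
#' modulation amplitude, so 0 yields a digital ellipsoid and larger values
#' monotonically reduce sphericity. Internal texture is a correlated
#' Gaussian random field whose variance and patch size (correlation length)
#' both grow with `texture_heterogeneity`: heterogeneous enhancement shows
#' up as multi-voxel patches, which after fixed-bin-number discretization
#' (amplitude-normalizing by construction) widen the spread of gray-level
#' run lengths and so raise GLRLM run entropy monotonically.
#'
#' @param label Class label: `-1` (metastasis-like) or `+1` (glioma-like).
#' @param size Integer triple, volume dimensions in voxels (each >= 32).
#' @param spacing Numeric triple, voxel spacing in mm.
#' @param shape_irregularity Non-negative scalar scaling boundary
#'   perturbation. `NULL` picks the class default (0.08 for `-1`, 0.35 for
#'   `+1`).
#' @param texture_heterogeneity Non-negative scalar controlling texture
#'   granularity. `NULL` picks the class default (2 for `-1`, 0.5 for `+1`).
#' @param ring_radius_mm Physical radius of the peritumoral ring (default 5).
#' @param seed Integer seed; identical inputs give bit-identical output.
#' @return A `volume_sample` list with fields `image`, `tumor_mask`,
#'   `ring_mask`, `spacing`, `label`, `seed`.
#' @examples
#' v <- gen_volume(-1, size = c(40, 40, 40), seed = 1)
#' sum(v$tumor_mask & v$ring_mask) # masks are disjoint
#' @export
gen_volume <- function(label,
                       size = c(64L, 64L, 64L),
                       spacing = c(1, 1, 1),
                       shape_irregularity = NULL,
                       texture_heterogeneity = NULL,
                       ring_radius_mm = 5,
                       seed = 1L) {
  if (!label %in% c(-1, 1)) stop("`label` must be -1 or +1", call. = FALSE)
  size <- as.integer(size)
  if (length(size) != 3L || any(size < 32L)) {
    stop("`size` must be three integers, each >= 32 voxels", call. = FALSE)
  }
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be three positive numbers (mm)", call. = FALSE)
  }
  irregularity <- shape_irregularity %||% if (label == -1) 0.08 else 0.35
  heterogeneity <- texture_heterogeneity %||% if (label == -1) 2 else 0.5
  if (irregularity < 0 || heterogeneity < 0) {
    stop("irregularity and heterogeneity must be >= 0", call. = FALSE)
  }

  with_seed(seed, {
    center <- (size + 1) / 2
    # base radius in mm; diameter >= 22 mm satisfies the > 2 cm inclusion rule
    r0 <- runif(1, 11, 14)
    # mild random ellipsoidal axes for both classes
    axes <- r0 * (1 + runif(3, -0.1, 0.1))
    # the lesion plus ring must fit inside the volume with a 2-voxel margin
    extent_mm <- max(axes) * (1 + 1.2 * irregularity) + ring_radius_mm
    fits <- all(extent_mm / spacing + 2 <= size / 2)
    if (!fits) {
      stop("volume too small to contain the lesion plus its peritumoral ring",
           call. = FALSE)
    }

    # physical coordinates relative to center
    gx <- (seq_len(size[1]) - center[1]) * spacing[1]
    gy <- (seq_len(size[2]) - center[2]) * spacing[2]
    gz <- (seq_len(size[3]) - center[3]) * spacing[3]
    X <- array(gx, size)
    Y <- array(rep(gy, each = size[1]), size)
    Z <- array(rep(gz, each = size[1] * size[2]), size)

    # normalized ellipsoid radius q(v) <= 1 + irregularity * g(direction)
    q <- sqrt((X / axes[1])^2 + (Y / axes[2])^2 + (Z / axes[3])^2)
    rr <- sqrt(X^2 + Y^2 + Z^2)
    rr[rr == 0] <- 1
    ux <- X / rr; uy <- Y / rr; uz <- Z / rr
    n_modes <- 6L
    amp <- rnorm(n_modes) / sqrt(n_modes)
    kvec <- matrix(runif(3 * n_modes, -3, 3), ncol = 3)
    phase <- runif(n_modes, 0, 2 * pi)
    g <- array(0, size)
    for (m in seq_len(n_modes)) {
      g <- g + amp[m] * cos(kvec[m, 1] * ux + kvec[m, 2] * uy +
                              kvec[m, 3] * uz + phase[m])
    }
    g <- g / max(1e-12, max(abs(g)))
    tumor <- q <= 1 + irregularity * g

    ring <- make_ring(tumor, radius = ring_radius_mm, spacing = spacing)

    # texture: background field everywhere outside the tumor, a
    # heterogeneity-controlled field inside it
    image <- array(20, size)
    bg <- gaussian_smooth3d(array(rnorm(prod(size)), size), 2)
    image <- image + 2 * bg / max(1e-12, sd(bg))
    if (heterogeneity > 0) {
      sig_tex <- 1 + heterogeneity
      tex <- gaussian_smooth3d(array(rnorm(prod(size)), size), sig_tex)
      tex <- tex / max(1e-12, sd(tex[tumor]))
      image[tumor] <- 100 + heterogeneity * 10 * tex[tumor]
    } else {
      image[tumor] <- 100
    }

    structure(
      list(image = image, tumor_mask = tumor, ring_mask = ring,
           spacing = spacing, label = label, seed = as.integer(seed)),
      class = "volume_sample"
    )
  })
}

#' Peritumoral ring from a tumor mask
#'
#' Dilates the tumor mask by a spherical structuring element of the given
#' physical radius (per-axis voxel radii under anisotropic spacing) and
#' subtracts the tumor, yielding a ring shell disjoint from the tumor.
#'
#' @param tumor_mask 3D logical array, non-empty.
#' @param radius Physical dilation radius in mm (> 0), default 5.
#' @param spacing Numeric triple, voxel spacing in mm.
#' @return 3D logical array of the same dimensions.
#' @export
make_ring <- function(tumor_mask, radius = 5, spacing = c(1, 1, 1)) {
  check_3d(tumor_mask, "tumor_mask")
  if (!any(tumor_mask)) stop("`tumor_mask` is empty", call. = FALSE)
  if (radius <= 0) stop("`radius` must be > 0", call. = FALSE)
  rv <- ceiling(radius / spacing)
  offs <- as.matrix(expand.grid(dx = -rv[1]:rv[1],
                                dy = -rv[2]:rv[2],
                                dz = -rv[3]:rv[3]))
  d2 <- (offs[, 1] * spacing[1])^2 + (offs[, 2] * spacing[2])^2 +
    (offs[, 3] * spacing[3])^2
  offs <- offs[d2 <= radius^2, , drop = FALSE]
  dil <- array(FALSE, dim(tumor_mask))
  m <- tumor_mask
  for (i in seq_len(nrow(offs))) {
    dil <- dil | shift3d_offset(m, offs[i, ], fill = FALSE)
  }
  dil & !tumor_mask
}

#' @export
print.volume_sample <- function(x, ...) {
  cat(sprintf(
    "<volume_sample> %s  label %+d  tumor %d vox  ring %d vox  spacing %s mm\n",
    paste(dim(x$image), collapse = "x"), x$label,
    sum(x$tumor_mask), sum(x$ring_mask),
    paste(format(x$spacing), collapse = "x")
  ))
  invisible(x)
}

#' Write a volume sample as NIfTI files
#'
#' Writes `<prefix>_image.nii.gz`, `<prefix>_tumor.nii.gz` and
#' `<prefix>_ring.nii.gz` with the sample's voxel spacing in the header.
#'
#' @param sample A `volume_sample`.
#' @param prefix Output path prefix.
#' @return Invisibly, the three file paths written.
#' @export
write_volume_sample <- function(sample, prefix) {
  stopifnot(inherits(sample, "volume_sample"))
  paths <- paste0(prefix, c("_image.nii.gz", "_tumor.nii.gz", "_ring.nii.gz"))
  arrays <- list(sample$image, sample$tumor_mask * 1L, sample$ring_mask * 1L)
  for (i in 1:3) {
    img <- RNifti::asNifti(arrays[[i]])
    RNifti::pixdim(img) <- sample$spacing
    RNifti::writeNifti(img, paths[i])
  }
  invisible(paths)
}

#' Read a volume sample back from NIfTI files
#'
#' @param prefix Path prefix used by [write_volume_sample()].
#' @param label Class label to attach.
#' @return A `volume_sample`.
#' @export
read_volume_sample <- function(prefix, label = NA_real_) {
  img <- RNifti::readNifti(paste0(prefix, "_image.nii.gz"))
  tum <- RNifti::readNifti(paste0(prefix, "_tumor.nii.gz"))
  rng <- RNifti::readNifti(paste0(prefix, "_ring.nii.gz"))
  spacing <- RNifti::pixdim(img)[1:3]
  structure(
    list(image = array(as.numeric(img), dim(img)),
         tumor_mask = array(as.numeric(tum) > 0.5, dim(tum)),
         ring_mask = array(as.numeric(rng) > 0.5, dim(rng)),
         spacing = spacing, label = label, seed = NA_integer_),
    class = "volume_sample"
  )
}
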