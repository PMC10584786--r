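# canonical feature-name lists per class; the class cardinalities
# (13/17/22/16/16/14/5) are the tested contract
manifest_feature_names <- function() {
  list(
    shape = c("MeshVolume", "VoxelVolume", "SurfaceArea",
              "SurfaceVolumeRatio", "Sphericity", "Maximum3DDiameter",
              "Maximum2DDiameterSlice", "Maximum2DDiameterColumn",
              "Maximum2DDiameterRow", "MajorAxisLength", "MinorAxisLength",
              "LeastAxisLength", "Elongation"),
    firstorder = c("Energy", "Entropy", "Minimum", "TenthPercentile",
                   "NinetiethPercentile", "Maximum", "Mean", "Median",
                   "InterquartileRange", "Range", "MeanAbsoluteDeviation",
                   "RobustMeanAbsoluteDeviation", "RootMeanSquared",
                   "Skewness", "Kurtosis", "Variance", "Uniformity"),
    glcm = c("Autocorrelation", "JointAverage", "ClusterProminence",
             "ClusterShade", "ClusterTendency", "Contrast", "Correlation",
             "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
             "JointEnergy", "JointEntropy", "Imc1", "Imc2", "Idm", "Idmn",
             "Id", "Idn", "InverseVariance", "MaximumProbability",
             "SumEntropy", "SumSquares"),
    glrlm = c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
              "GrayLevelVariance", "HighGrayLevelRunEmphasis",
              "LongRunEmphasis", "LongRunHighGrayLevelEmphasis",
              "LongRunLowGrayLevelEmphasis", "LowGrayLevelRunEmphasis",
              "RunEntropy", "RunLengthNonUniformity",
              "RunLengthNonUniformityNormalized", "RunPercentage",
              "RunVariance", "ShortRunEmphasis",
              "ShortRunHighGrayLevelEmphasis", "ShortRunLowGrayLevelEmphasis"),
    glszm = c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
              "GrayLevelVariance", "HighGrayLevelZoneEmphasis",
              "LargeAreaEmphasis", "LargeAreaHighGrayLevelEmphasis",
              "LargeAreaLowGrayLevelEmphasis", "LowGrayLevelZoneEmphasis",
              "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
              "SmallAreaEmphasis", "SmallAreaHighGrayLevelEmphasis",
              "SmallAreaLowGrayLevelEmphasis", "ZoneEntropy",
              "ZonePercentage", "ZoneVariance"),
    gldm = c("DependenceEntropy", "DependenceNonUniformity",
             "DependenceNonUniformityNormalized", "DependenceVariance",
             "GrayLevelNonUniformity", "GrayLevelVariance",
             "HighGrayLevelEmphasis", "LargeDependenceEmphasis",
             "LargeDependenceHighGrayLevelEmphasis",
             "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
             "SmallDependenceEmphasis",
             "SmallDependenceHighGrayLevelEmphasis",
             "SmallDependenceLowGrayLevelEmphasis"),
    ngtdm = c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength")
  )
}

manifest_image_types <- function() {
  c("original", "log-sigma-1",
    "wavelet-LLH", "wavelet-LHL", "wavelet-LHH", "wavelet-HLL",
    "wavelet-HLH", "wavelet-HHL", "wavelet-HHH", "wavelet-LLL")
}

#' Default extraction configuration
#'
#' Seven feature classes with fixed cardinalities (shape 13, first-order 17,
#' GLCM 22, GLRLM 16, GLSZM 16, GLDM 14, NGTDM 5), ten image types
#' (original plus a 9-filter bank: one Laplacian-of-Gaussian at sigma 1 mm
#' and eight Haar wavelet sub-bands), and two regions (tumor, ring).
#'
#' @return Named list with `classes`, `cardinalities`, `image_types`,
#'   `regions`, `n_bins`.
#' @export
manifest_config <- function() {
  list(classes = manifest_feature_names(),
       cardinalities = c(shape = 13L, firstorder = 17L, glcm = 22L,
                         glrlm = 16L, glszm = 16L, gldm = 14L, ngtdm = 5L),
       image_types = manifest_image_types(),
       regions = c("tumor", "ring"),
       n_bins = 32L)
}

#' Enumerate all feature descriptors
#'
#' Shape features are computed only on the original tumor mask; every other
#' class is extracted per image type and region, giving 13 + 90 x 10 = 913
#' tumor descriptors and 90 x 10 = 900 ring descriptors (1813 in total).
#'
#' @param config Configuration as from [manifest_config()].
#' @return Data frame with columns `region`, `image_type`, `feature_class`,
#'   `name`, and the unique descriptor `id`
#'   (`region_imagetype_class_name`).
#' @export
feature_manifest <- function(config = manifest_config()) {
  got <- vapply(config$classes, length, integer(1))
  want <- config$cardinalities[names(got)]
  if (any(got != want)) {
    bad <- names(got)[got != want]
    stop(sprintf("feature class cardinality mismatch: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  rows <- list()
  for (region in config$regions) {
    for (cls in names(config$classes)) {
      if (cls == "shape") {
        if (region != "tumor") next  # shape omitted for the ring volume
        types <- "original"
      } else {
        types <- config$image_types
      }
      for (ty in types) {
        rows[[length(rows) + 1L]] <- data.frame(
          region = region, image_type = ty, feature_class = cls,
          name = config$classes[[cls]], stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$id <- paste(out$region, out$image_type, out$feature_class, out$name,
                  sep = "_")
  stopifnot(!anyDuplicated(out$id))
  rownames(out) <- NULL
  out
}

# descriptors whose values this package computes
supported_features <- function() {
  list(shape = "Sphericity",
       firstorder = c("Mean", "Variance", "Entropy"),
       glcm = c("Contrast", "ClusterProminence"),
       glrlm = "RunEntropy",
       glszm = "ZoneEntropy")
}

#' Extract feature values from a volume sample
#'
#' For each requested descriptor: the image is z-score normalized over the
#' whole volume, the image-type filter is applied (identity,
#' Laplacian-of-Gaussian, or a Haar wavelet sub-band), intensities are
#' discretized within the region mask by fixed bin number, and the feature
#' is computed on the region. Only the implemented subset is computable
#' (shape sphericity; first-order mean/variance/entropy; GLCM contrast and
#' cluster prominence; GLRLM run entropy; GLSZM zone entropy); requesting
#' any other descriptor is an explicit error, not a silent `NA`.
#'
#' @param sample A `volume_sample`.
#' @param which Subset of the manifest: a data frame of manifest rows or a
#'   character vector of descriptor ids.
#' @param n_bins Gray levels for discretization (default 32).
#' @return Named numeric vector keyed by descriptor id.
#' @export
extract_features <- function(sample, which, n_bins = 32L) {
  stopifnot(inherits(sample, "volume_sample"))
  man <- feature_manifest()
  if (is.character(which)) {
    missing_ids <- setdiff(which, man$id)
    if (length(missing_ids)) {
      stop(sprintf("unknown descriptor ids: %s",
                   paste(missing_ids, collapse = ", ")), call. = FALSE)
    }
    which <- man[match(which, man$id), , drop = FALSE]
  }
  if (nrow(which) == 0L) return(setNames(numeric(0), character(0)))

  sup <- supported_features()
  ok <- mapply(function(cls, nm) cls %in% names(sup) && nm %in% sup[[cls]],
               which$feature_class, which$name)
  if (!all(ok)) {
    stop(sprintf("unsupported descriptors requested: %s",
                 paste(which$id[!ok], collapse = ", ")), call. = FALSE)
  }

  norm <- zscore_normalize(sample$image)
  filtered <- list(original = norm)
  get_filtered <- function(ty) {
    if (!is.null(filtered[[ty]])) return(filtered[[ty]])
    img <- if (ty == "log-sigma-1") {
      log_filter(norm, sigma = 1, spacing = sample$spacing)
    } else if (grepl("^wavelet-", ty)) {
      wavelet_subbands(norm)[[sub("wavelet-", "", ty)]]
    } else {
      stop(sprintf("unknown image type `%s`", ty), call. = FALSE)
    }
    filtered[[ty]] <<- img
    img
  }

  masks <- list(tumor = sample$tumor_mask, ring = sample$ring_mask)
  tex_cache <- list()
  out <- numeric(nrow(which))
  for (i in seq_len(nrow(which))) {
    row <- which[i, ]
    if (row$feature_class == "shape") {
      out[i] <- sphericity(sample$tumor_mask, sample$spacing)
      next
    }
    img <- get_filtered(row$image_type)
    mask <- masks[[row$region]]
    key <- paste(row$region, row$image_type)
    if (row$feature_class == "firstorder") {
      v <- img[mask]
      out[i] <- switch(row$name,
        Mean = mean(v),
        Variance = mean((v - mean(v))^2),
        Entropy = {
          lab <- discretize_fbn(img, mask, n_bins)[mask]
          entropy_bits(tabulate(lab, n_bins) / length(lab))
        })
      next
    }
    if (is.null(tex_cache[[key]])) {
      lab <- discretize_fbn(img, mask, n_bins)
      tex_cache[[key]] <- texture_stats(lab, mask, n_bins)
    }
    ts <- tex_cache[[key]]
    out[i] <- switch(paste(row$feature_class, row$name),
      "glcm Contrast" = ts$glcm_contrast,
      "glcm ClusterProminence" = ts$glcm_cluster_prominence,
      "glrlm RunEntropy" = ts$glrlm_run_entropy,
      "glszm ZoneEntropy" = ts$glszm_zone_entropy)
  }
  setNames(out, which$id)
}
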