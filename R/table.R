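#' Specification for a planted synthetic feature table
#'
#' Describes the statistical structure of a generated tabular dataset:
#' informative features with class-shifted means, redundant near-copies that
#' a Spearman prune at 0.8 must remove, interacting (XOR-of-signs) pairs
#' that are individually label-independent but jointly predictive, and pure
#' noise features, under class imbalance.
#'
#' @param n_samples Number of rows (>= 20). Default 2000, a size at which
#'   the plug-in mutual-information estimators used downstream are well
#'   calibrated.
#' @param class_ratio Fraction of minority-class (`+1`, glioma-like) rows;
#'   default 72/201, mirroring a 129:72 cohort imbalance.
#' @param n_informative Features with class-shifted means.
#' @param n_redundant Noisy copies of informative features with Spearman
#'   |rho| above 0.8.
#' @param n_interacting_pairs XOR-style feature pairs.
#' @param n_noise Label-independent features.
#' @param effect_sizes Mean shift (in SD units) per informative feature,
#'   recycled to `n_informative`.
#' @param correlation Target Spearman |rho| between a redundant copy and its
#'   parent; must lie in (0.8, 1).
#' @param xor_fidelity Probability that the sign product of an interacting
#'   pair equals the label (default 0.95).
#' @param seed Integer seed.
#' @return A `synthetic_table_spec` list.
#' @export
synthetic_table_spec <- function(n_samples = 2000L,
                                 class_ratio = 72 / 201,
                                 n_informative = 5L,
                                 n_redundant = 2L,
                                 n_interacting_pairs = 1L,
                                 n_noise = 10L,
                                 effect_sizes = 0.8,
                                 correlation = 0.9,
                                 xor_fidelity = 0.95,
                                 seed = 1L) {
  counts <- c(n_informative, n_redundant, n_interacting_pairs, n_noise)
  if (any(counts < 0)) stop("feature counts must be >= 0", call. = FALSE)
  if (n_samples < 20L) stop("`n_samples` must be >= 20", call. = FALSE)
  if (class_ratio <= 0 || class_ratio >= 1) {
    stop("`class_ratio` must lie in (0, 1)", call. = FALSE)
  }
  if (n_redundant > 0 && (correlation <= 0.8 || correlation >= 1)) {
    stop("`correlation` must lie in (0.8, 1) for redundant copies",
         call. = FALSE)
  }
  if (n_redundant > 0 && n_informative == 0) {
    stop("redundant copies require at least one informative feature",
         call. = FALSE)
  }
  p <- n_informative + n_redundant + 2L * n_interacting_pairs + n_noise
  if (p < 1L) stop("at least one feature is required", call. = FALSE)
  structure(
    list(n_samples = as.integer(n_samples), class_ratio = class_ratio,
         n_informative = as.integer(n_informative),
         n_redundant = as.integer(n_redundant),
         n_interacting_pairs = as.integer(n_interacting_pairs),
         n_noise = as.integer(n_noise),
         effect_sizes = rep(effect_sizes, length.out = max(1L, n_informative)),
         correlation = correlation, xor_fidelity = xor_fidelity,
         seed = as.integer(seed)),
    class = "synthetic_table_spec"
  )
}

#' Generate a feature table with planted relevance structure
#'
#' @param spec A [synthetic_table_spec()].
#' @return A `feature_table`: list with `values` (n x p matrix), `names`,
#'   `labels` (in -1/+1), and `relevance`, a data frame recording each
#'   column's planted role (`informative`, `redundant`, `interacting`,
#'   `noise`) and, for redundant copies, the parent column.
#' @export
gen_feature_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_table_spec"))
  with_seed(spec$seed, {
    n <- spec$n_samples
    n_min <- round(spec$class_ratio * n)
    if (n_min < 2 || n - n_min < 2) {
      stop("class ratio leaves fewer than 2 samples in a class", call. = FALSE)
    }
    y <- sample(c(rep(1, n_min), rep(-1, n - n_min)))

    cols <- list()
    names_out <- character(0)
    role <- character(0)
    parent <- character(0)

    # informative: class-shifted means, unit-variance noise
    for (j in seq_len(spec$n_informative)) {
      delta <- spec$effect_sizes[j]
      cols[[length(cols) + 1L]] <- delta / 2 * y + rnorm(n)
      names_out <- c(names_out, sprintf("informative_%02d", j))
      role <- c(role, "informative")
      parent <- c(parent, NA_character_)
    }
    # redundant: parent plus Gaussian noise calibrated so that the
    # population Spearman correlation matches `correlation`
    if (spec$n_redundant > 0) {
      rho_s <- spec$correlation
      r_pearson <- 2 * sin(pi * rho_s / 6)  # bivariate-normal inversion
      tau <- sqrt(1 / r_pearson^2 - 1)
      for (j in seq_len(spec$n_redundant)) {
        src <- ((j - 1L) %% spec$n_informative) + 1L
        cols[[length(cols) + 1L]] <- cols[[src]] + tau * rnorm(n)
        names_out <- c(names_out, sprintf("redundant_%02d", j))
        role <- c(role, "redundant")
        parent <- c(parent, sprintf("informative_%02d", src))
      }
    }
    # interacting: each pair's sign product matches the label with
    # probability xor_fidelity; each member is marginally label-independent
    for (j in seq_len(spec$n_interacting_pairs)) {
      s1 <- sample(c(-1, 1), n, replace = TRUE)
      flip <- ifelse(runif(n) < spec$xor_fidelity, 1, -1)
      s2 <- s1 * y * flip
      cols[[length(cols) + 1L]] <- s1 * abs(rnorm(n))
      names_out <- c(names_out, sprintf("interacting_%02da", j))
      role <- c(role, "interacting")
      parent <- c(parent, sprintf("interacting_%02db", j))
      cols[[length(cols) + 1L]] <- s2 * abs(rnorm(n))
      names_out <- c(names_out, sprintf("interacting_%02db", j))
      role <- c(role, "interacting")
      parent <- c(parent, sprintf("interacting_%02da", j))
    }
    for (j in seq_len(spec$n_noise)) {
      cols[[length(cols) + 1L]] <- rnorm(n)
      names_out <- c(names_out, sprintf("noise_%02d", j))
      role <- c(role, "noise")
      parent <- c(parent, NA_character_)
    }

    values <- do.call(cbind, cols)
    colnames(values) <- names_out
    feature_table(values, labels = y,
                  relevance = data.frame(name = names_out, role = role,
                                         parent = parent,
                                         stringsAsFactors = FALSE))
  })
}

#' Construct a feature table
#'
#' @param values Numeric n x p matrix without missing values.
#' @param labels Numeric vector of class labels in -1/+1, both present.
#' @param relevance Optional data frame of per-column ground truth.
#' @return A `feature_table`.
#' @export
feature_table <- function(values, labels, relevance = NULL) {
  values <- as.matrix(values)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("`values` must be finite with no missing entries", call. = FALSE)
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("feature_%03d", seq_len(ncol(values)))
  }
  if (anyDuplicated(colnames(values))) {
    stop("feature names must be unique", call. = FALSE)
  }
  if (length(labels) != nrow(values)) {
    stop("`labels` length must match rows of `values`", call. = FALSE)
  }
  if (!all(labels %in% c(-1, 1)) || length(unique(labels)) < 2L) {
    stop("`labels` must contain both classes, coded -1/+1", call. = FALSE)
  }
  structure(
    list(values = values, names = colnames(values), labels = as.numeric(labels),
         relevance = relevance),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features  (+1: %d, -1: %d)\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == 1), sum(x$labels == -1)))
  invisible(x)
}

#' Write a feature table as CSV (+ JSON relevance sidecar)
#'
#' The CSV has one header row, feature columns, and a final `label` column
#' in -1/+1. If the table carries planted-relevance ground truth it is
#' written next to the CSV as `<path>.relevance.json`.
#'
#' @param table A `feature_table`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- as.data.frame(table$values)
  df$label <- table$labels
  write.csv(df, path, row.names = FALSE)
  if (!is.null(table$relevance)) {
    jsonlite::write_json(table$relevance,
                         paste0(path, ".relevance.json"))
  }
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path; the last column must be `label`.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df)) stop("CSV must contain a `label` column",
                                    call. = FALSE)
  labels <- df$label
  df$label <- NULL
  relevance <- NULL
  sidecar <- paste0(path, ".relevance.json")
  if (file.exists(sidecar)) {
    relevance <- as.data.frame(jsonlite::read_json(sidecar,
                                                   simplifyVector = TRUE))
  }
  feature_table(as.matrix(df), labels, relevance = relevance)
}
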