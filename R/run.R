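#' Default end-to-end pipeline configuration
#'
#' Every stochastic stage derives its seed from the top-level `seed`, so a
#' configuration fully determines the run.
#'
#' @param seed Top-level integer seed.
#' @return Nested configuration list (serializable to JSON).
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    table_spec = list(),                 # overrides for synthetic_table_spec()
    split = list(fraction = 0.7),
    resample = list(k_neighbors = 5L, target_ratio = 1),
    prune = list(threshold = 0.8),
    linear_select = list(penalty_strength = 0.01),
    mi_rank = list(top_m = 17L, bins = 4L),
    qubo = list(k = 10L, bins = 4L, alpha = "auto", reads = 5000L),
    qnn = list(layers = 6L, lr = 0.01, epochs = 60L, batch = NULL,
               pad = 0.3),
    shap = list(background_size = 50L, n_coalitions = 2048L)
  )
}

#' Run the full classification pipeline
#'
#' Chains the stages end to end on a feature table: stratified 70/30
#' split, train-fitted standardization, SMOTE plus undersampling of the
#' training rows only, Spearman correlation pruning at 0.8, sparse linear
#' margin selection, mutual-information ranking to 17 candidates, QUBO
#' selection of the final `k` features, variational quantum classifier
#' training, Kernel SHAP attribution of the test predictions, and metrics.
#' Test rows never influence fitted parameters or resampling. Re-running
#' with the same configuration reproduces all results.
#'
#' @param config Configuration as from [default_config()].
#' @param table Optional `feature_table`; by default a synthetic table is
#'   generated from `config$table_spec`.
#' @param out_dir Optional directory; when given, tables, selections,
#'   parameters, attributions and the report are written there as CSV/JSON.
#' @param verbose Print stage progress, default `FALSE`.
#' @return List with the fitted objects, selected features, train/test
#'   `metrics_report`s (and their generalization gap), and SHAP summaries.
#' @export
run_pipeline <- function(config = default_config(), table = NULL,
                         out_dir = NULL, verbose = FALSE) {
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  seed <- config$seed

  tab <- stage("input", {
    if (is.null(table)) {
      spec <- do.call(synthetic_table_spec,
                      modifyList(list(seed = seed), config$table_spec))
      gen_feature_table(spec)
    } else table
  })
  say("input: %d x %d", nrow(tab$values), ncol(tab$values))

  split <- stage("split", stratified_split(tab$labels,
                                           fraction = config$split$fraction,
                                           seed = seed + 1L))
  std <- stage("standardize", standardize(tab, fit_idx = split$train_idx))
  Xs <- std$table$values
  y <- std$table$labels

  res <- stage("resample", resample_balance(
    Xs[split$train_idx, , drop = FALSE], y[split$train_idx],
    k_neighbors = config$resample$k_neighbors,
    target_ratio = config$resample$target_ratio, seed = seed + 2L))
  say("resampled train: %d rows", nrow(res$X))

  kept <- stage("prune", spearman_prune(res$X,
                                        threshold = config$prune$threshold,
                                        y = res$y))
  say("prune: %d of %d kept", length(kept), ncol(res$X))

  lin <- stage("linear_select", {
    sel <- suppressWarnings(linear_margin_select(
      res$X[, kept, drop = FALSE], res$y,
      penalty_strength = config$linear_select$penalty_strength))
    kept[sel]
  })
  if (length(lin) == 0L) lin <- kept  # degenerate: keep pruned set
  say("linear select: %d columns", length(lin))

  top_m <- min(config$mi_rank$top_m, length(lin))
  mi_sel <- stage("mi_rank", lin[mi_rank(res$X[, lin, drop = FALSE], res$y,
                                         top_m = top_m,
                                         bins = config$mi_rank$bins)])

  k <- config$qubo$k
  if (k > length(mi_sel)) {
    stop(sprintf(
      "pipeline stage `qubo_select` failed: k = %d exceeds the %d surviving features",
      k, length(mi_sel)), call. = FALSE)
  }
  qsel <- stage("qubo_select", {
    idx <- select_features(res$X[, mi_sel, drop = FALSE], res$y, k = k,
                           bins = config$qubo$bins,
                           alpha = config$qubo$alpha,
                           reads = config$qubo$reads, seed = seed + 3L)
    mi_sel[idx]
  })
  selected_names <- colnames(Xs)[qsel]
  say("selected: %s", paste(selected_names, collapse = ", "))

  fit <- stage("qnn_train", train_qnn(
    res$X[, qsel, drop = FALSE], res$y,
    layers = config$qnn$layers, lr = config$qnn$lr,
    epochs = config$qnn$epochs, batch = config$qnn$batch,
    pad = config$qnn$pad, seed = seed + 4L))

  pred_train <- predict_qnn(res$X[, qsel, drop = FALSE], fit$params,
                            fit$transform)
  X_test <- Xs[split$test_idx, qsel, drop = FALSE]
  y_test <- y[split$test_idx]
  pred_test <- predict_qnn(X_test, fit$params, fit$transform)

  metrics_train <- stage("metrics",
                         classification_report(res$y, pred_train$score))
  metrics_test <- classification_report(y_test, pred_test$score)

  shap <- stage("shap", {
    bg_n <- min(config$shap$background_size, nrow(res$X))
    bg_rows <- with_seed(seed + 5L, sample.int(nrow(res$X), bg_n))
    background <- res$X[bg_rows, qsel, drop = FALSE]
    model <- function(M) predict_qnn(M, fit$params, fit$transform)$score
    phis <- t(vapply(seq_len(nrow(X_test)), function(i) {
      kernel_shap(model, X_test[i, ], background,
                  n_coalitions = config$shap$n_coalitions,
                  seed = seed + 6L + i)$phi
    }, numeric(length(qsel))))
    colnames(phis) <- selected_names
    list(phi = phis,
         summary = shap_summary(phis, X_test, y_test, pred_test$label))
  })

  result <- list(
    config = config,
    split = split,
    standardization = std[c("center", "scale", "dropped")],
    selected = selected_names,
    selected_idx = qsel,
    qnn = fit,
    metrics_train = metrics_train,
    metrics_test = metrics_test,
    generalization_gap = list(
      bacc = metrics_train$bacc - metrics_test$bacc,
      auc = metrics_train$auc - metrics_test$auc),
    test_scores = pred_test$score,
    test_labels = y_test,
    shap = shap
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(config, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, null = "null")
    write.csv(data.frame(feature = selected_names),
              file.path(out_dir, "selected_features.csv"),
              row.names = FALSE)
    write.csv(fit$history, file.path(out_dir, "qnn_history.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(angles = fit$params$angles, bias = fit$params$bias),
      file.path(out_dir, "qnn_params.json"), digits = NA)
    write.csv(as.data.frame(shap$phi),
              file.path(out_dir, "shap_attributions.csv"),
              row.names = FALSE)
    report <- list(
      train = list(auc = metrics_train$auc, bacc = metrics_train$bacc),
      test = list(auc = metrics_test$auc, bacc = metrics_test$bacc),
      generalization_gap = result$generalization_gap,
      selected = selected_names)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}
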