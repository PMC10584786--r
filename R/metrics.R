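#' Classification metrics report
#'
#' Computes ROC-AUC by the rank statistic (tied scores receive midranks),
#' and balanced accuracy, per-class precision/recall/F1 and confusion
#' counts from the confusion matrix at the given score threshold (scores
#' at or above the threshold predict +1). Balanced accuracy is by
#' definition the mean of the per-class recalls.
#'
#' @param labels True labels in -1/+1, both classes present.
#' @param scores Numeric scores, larger favoring +1.
#' @param threshold Decision threshold, default 0.
#' @return A `metrics_report` list: `auc`, `bacc`, `accuracy`, `confusion`
#'   (2 x 2 counts), and `per_class` data frame with precision, recall, F1
#'   and support, plus a macro row.
#' @export
classification_report <- function(labels, scores, threshold = 0) {
  if (length(labels) != length(scores)) {
    stop("`labels` and `scores` lengths differ", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("AUC undefined: only one class present", call. = FALSE)
  }
  pos <- labels == 1
  r <- rank(scores)  # midranks for ties
  n1 <- sum(pos); n0 <- sum(!pos)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  pred <- ifelse(scores < threshold, -1, 1)
  conf <- table(factor(labels, levels = c(-1, 1)),
                factor(pred, levels = c(-1, 1)))
  dimnames(conf) <- list(truth = c("-1", "+1"), prediction = c("-1", "+1"))
  per_class <- do.call(rbind, lapply(c(-1, 1), function(cl) {
    tp <- sum(labels == cl & pred == cl)
    fp <- sum(labels != cl & pred == cl)
    fn <- sum(labels == cl & pred != cl)
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- tp / (tp + fn)
    f1 <- if (is.na(precision) || precision + recall == 0) NA_real_ else
      2 * precision * recall / (precision + recall)
    data.frame(class = sprintf("%+d", cl), precision = precision,
               recall = recall, f1 = f1, support = sum(labels == cl))
  }))
  macro <- data.frame(class = "macro",
                      precision = mean(per_class$precision),
                      recall = mean(per_class$recall),
                      f1 = mean(per_class$f1),
                      support = length(labels))
  per_class <- rbind(per_class, macro)
  rownames(per_class) <- NULL
  structure(list(auc = auc, bacc = mean(per_class$recall[1:2]),
                 accuracy = mean(pred == labels),
                 confusion = unclass(conf), per_class = per_class),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> AUC %.3f  bACC %.3f  ACC %.3f\n",
              x$auc, x$bacc, x$accuracy))
  print(x$per_class, digits = 3)
  invisible(x)
}
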