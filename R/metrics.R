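#' Per-class confusion counts for multi-label predictions
#'
#' @param labels `n x K` binary matrix (or length-`n` vector for `K = 1`).
#' @param predictions same shape, binary hard predictions.
#' @return tibble with one row per class: `class`, `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(labels, predictions) {
  labels <- as.matrix(labels)
  predictions <- as.matrix(predictions)
  if (!identical(dim(labels), dim(predictions)))
    stopf("labels (%s) and predictions (%s) have different shapes",
          paste(dim(labels), collapse = "x"),
          paste(dim(predictions), collapse = "x"))
  if (!all(labels %in% c(0, 1)) || !all(predictions %in% c(0, 1)))
    stopf("labels and predictions must be binary (0/1)")
  K <- ncol(labels)
  tibble::tibble(
    class = colnames(labels) %||% paste0("class_", seq_len(K)),
    tp = colSums(predictions == 1 & labels == 1),
    fp = colSums(predictions == 1 & labels == 0),
    tn = colSums(predictions == 0 & labels == 0),
    fn = colSums(predictions == 0 & labels == 1)
  )
}

#' Rank-based AUROC (Mann-Whitney statistic)
#'
#' Probability that a random positive is scored above a random negative,
#' ties counted one half.
#'
#' @param scores numeric vector.
#' @param labels binary vector.
#' @return AUROC in `[0, 1]`, or `NA` if either class is absent.
#' @export
auroc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

metric_row <- function(tp, fp, tn, fn, auc = NA_real_) {
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  sensitivity <- recall
  specificity <- safe_div(tn, tn + fp)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else
    (tp * tn - fp * fn) / sqrt(denom)
  tibble::tibble(precision = precision, recall = recall,
                 sensitivity = sensitivity, specificity = specificity,
                 f1 = f1, mcc = mcc, auc = auc,
                 auc_sens_spec = sensitivity * specificity)
}

#' Full multi-label metric report
#'
#' Computes per-class precision, recall, sensitivity, specificity, F1 and
#' MCC from the confusion counts, plus rank-based AUROC from the continuous
#' scores, with macro (unweighted per-class mean) and micro (pooled-count)
#' averages.  Zero-denominator conventions: precision, recall and F1 are 0
#' when undefined, and MCC is 0 when any marginal is 0.  The literal
#' sensitivity-times-specificity product is also reported as `auc_sens_spec`
#' alongside the standard rank-based AUROC.
#'
#' @param counts tibble from [confusion()].
#' @param scores optional `n x K` matrix of continuous scores (for AUROC
#'   and subset accuracy).
#' @param labels optional `n x K` binary matrix matching `scores`.
#' @param threshold hard-label threshold used for subset accuracy.
#' @return object of class `rlwbs_metrics`: list with `per_class`
#'   (tibble), `macro`, `micro` (one-row tibbles), and `subset_accuracy`
#'   (scalar or `NA`).
#' @export
compute_metrics <- function(counts, scores = NULL, labels = NULL,
                            threshold = 0.5) {
  stopifnot(all(c("tp", "fp", "tn", "fn") %in% names(counts)))
  K <- nrow(counts)
  aucs <- rep(NA_real_, K)
  if (!is.null(scores) && !is.null(labels)) {
    scores <- as.matrix(scores)
    labels <- as.matrix(labels)
    aucs <- vapply(seq_len(K), function(k) auroc(scores[, k], labels[, k]),
                   numeric(1))
  }
  per_class <- dplyr::bind_cols(
    counts,
    dplyr::bind_rows(lapply(seq_len(K), function(k)
      metric_row(counts$tp[k], counts$fp[k], counts$tn[k], counts$fn[k],
                 aucs[k])))
  )
  metric_cols <- c("precision", "recall", "sensitivity", "specificity",
                   "f1", "mcc", "auc", "auc_sens_spec")
  macro <- dplyr::summarise(per_class, dplyr::across(
    dplyr::all_of(metric_cols), ~ mean(.x, na.rm = TRUE)))
  micro <- metric_row(sum(counts$tp), sum(counts$fp), sum(counts$tn),
                      sum(counts$fn),
                      if (!is.null(scores) && !is.null(labels))
                        auroc(as.vector(scores), as.vector(labels))
                      else NA_real_)
  subset_acc <- NA_real_
  if (!is.null(scores) && !is.null(labels)) {
    hard <- (scores >= threshold) * 1
    subset_acc <- mean(rowSums(hard != labels) == 0)
  }
  out <- list(per_class = per_class, macro = macro, micro = micro,
              subset_accuracy = subset_acc)
  class(out) <- "rlwbs_metrics"
  out
}

#' Scalar reward from a metric report
#'
#' The reward of a training iteration is one scalar summary of the
#' evaluation-split classification performance.  Default is macro-F1;
#' macro-AUROC and subset accuracy are the alternatives.
#'
#' @param report an `rlwbs_metrics` object.
#' @param which one of `"macro_f1"`, `"macro_auc"`, `"subset_accuracy"`.
#' @return scalar in `[0, 1]`.
#' @export
reward_metric <- function(report, which = "macro_f1") {
  stopifnot(inherits(report, "rlwbs_metrics"))
  switch(which,
         macro_f1 = report$macro$f1,
         macro_auc = report$macro$auc,
         subset_accuracy = report$subset_accuracy,
         stopf("unknown reward metric '%s' (use macro_f1, macro_auc or subset_accuracy)",
               which))
}

#' @export
print.rlwbs_metrics <- function(x, ...) {
  cat("<rlwbs_metrics>\n per-class:\n")
  print(x$per_class)
  cat(" macro:\n")
  print(x$macro)
  cat(" micro:\n")
  print(x$micro)
  if (!is.na(x$subset_accuracy))
    cat(sprintf(" subset accuracy: %.4f\n", x$subset_accuracy))
  invisible(x)
}

#' Tidy a metric report into one row per class and averaging level
#'
#' @param x an `rlwbs_metrics` object.
#' @param ... ignored.
#' @return a tibble with a `level` column (`"class"`, `"macro"`,
#'   `"micro"`).
#' @method tidy rlwbs_metrics
#' @export
tidy.rlwbs_metrics <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$per_class, level = "class", .before = 1),
    dplyr::mutate(x$macro, level = "macro", class = "macro", .before = 1),
    dplyr::mutate(x$micro, level = "micro", class = "micro", .before = 1)
  )
}

#' Write a metric report as a flat key-value text table
#'
#' @param report an `rlwbs_metrics`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  tab <- tidy.rlwbs_metrics(report)
  utils::write.table(format(as.data.frame(tab), digits = 6), path,
                     row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}
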