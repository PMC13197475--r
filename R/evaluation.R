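# Classification metrics, ROC/AUC, and per-layer feature export.

#' Confusion counts at a decision threshold
#'
#' The winged class (label 1) is the positive class; a sample is predicted
#' positive when its score reaches the threshold.
#'
#' @param labels Integer 0/1 labels.
#' @param scores Predicted winged-class probabilities (or hard 0/1 calls).
#' @param threshold Decision threshold (default 0.5).
#' @return A one-row tibble with columns `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores)) abort("`labels` and `scores` differ in length")
  pred <- scores >= threshold
  pos <- labels == 1L
  tibble::tibble(
    tp = sum(pos & pred), tn = sum(!pos & !pred),
    fp = sum(!pos & pred), fn = sum(pos & !pred)
  )
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall and F1:
#' \deqn{Acc = (TP+TN)/(TP+TN+FP+FN)}
#' \deqn{Pre = TP/(TP+FP), \quad Re = TP/(TP+FN)}
#' \deqn{F1 = 2 \cdot Pre \cdot Re / (Pre + Re)}
#' A zero denominator makes the corresponding metric undefined: it is
#' reported as `NA` with a warning, not as 0; F1 is undefined whenever
#' precision or recall is.
#'
#' @param counts One-row tibble from [confusion_counts()] (or a list with
#'   `tp`, `tn`, `fp`, `fn`).
#' @return A one-row tibble with `accuracy`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp
  tn <- counts$tn
  fp <- counts$fp
  fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total == 0) abort("all confusion counts are zero")
  pre <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  re <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  if (is.na(pre)) warn("precision undefined: no predicted positives")
  if (is.na(re)) warn("recall undefined: no positive samples")
  f1 <- if (is.na(pre) || is.na(re) || pre + re == 0) {
    if (!is.na(pre) && !is.na(re)) warn("F1 undefined: precision + recall = 0")
    NA_real_
  } else {
    2 * pre * re / (pre + re)
  }
  tibble::tibble(accuracy = (tp + tn) / total, precision = pre, recall = re, f1 = f1)
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique scores, records one
#' (FPR, TPR) point per threshold, and integrates by the trapezoidal rule.
#' The resulting AUC equals the rank statistic
#' `P(score_pos > score_neg) + 0.5 P(score_pos = score_neg)`.
#'
#' @param scores Predicted winged-class probabilities.
#' @param labels Integer 0/1 labels; both classes must be present.
#' @return A list with `roc` (tibble `threshold`, `fpr`, `tpr`, from
#'   (0, 0) to (1, 1)) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(labels) != length(scores)) abort("`labels` and `scores` differ in length")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) abort("ROC needs both classes present")
  ord <- order(-scores)
  s <- scores[ord]
  y <- labels[ord]
  # one point per unique score: cumulative counts at the block ends
  last_of_block <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y == 1L)[last_of_block]
  fp <- cumsum(y == 0L)[last_of_block]
  roc <- tibble::tibble(
    threshold = c(Inf, s[last_of_block]),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Extract per-layer document features
#'
#' Exports the feature matrix a 2-D projection (e.g. t-SNE) would consume,
#' for one of the three stages of the network: the embedding layer (masked
#' mean of the sentence vectors, width d), the BiLSTM layer (masked mean of
#' the concatenated hidden states, width 2H), or the attention layer
#' (masked mean of the context vectors, width 2H).
#'
#' @param model A fitted `wing_model`.
#' @param corpus Corpus tibble.
#' @param embedding The training `kmer_embedding`.
#' @param layer One of `"embedding"`, `"bilstm"`, `"attention"`.
#' @return A tibble of class `layer_features`: `sample_id`, `label`, then
#'   one column per feature (`f1`, `f2`, ...); the layer name is kept as an
#'   attribute.
#' @export
extract_layer_features <- function(model, corpus, embedding,
                                   layer = c("embedding", "bilstm", "attention")) {
  layer <- match.arg(layer)
  inf <- infer_corpus(model, corpus, embedding, collect = TRUE)
  mat <- switch(layer,
    embedding = inf$embedding_pooled,
    bilstm = inf$bilstm_pooled,
    attention = inf$attention_pooled
  )
  colnames(mat) <- paste0("f", seq_len(ncol(mat)))
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = inf$sample_ids, label = inf$y),
    tibble::as_tibble(mat)
  )
  attr(out, "layer") <- layer
  class(out) <- c("layer_features", class(out))
  out
}

#' Evaluate a fitted model on one split subset
#'
#' Convenience wrapper: predicts the subset, computes confusion counts,
#' threshold metrics and AUC.
#'
#' @param model A fitted `wing_model`.
#' @param corpus Corpus tibble.
#' @param embedding The training `kmer_embedding`.
#' @param split A `dataset_split`.
#' @param subset Which subset to evaluate (default `"test"`).
#' @param threshold Decision threshold (default 0.5).
#' @return A list with `predictions`, `counts`, `metrics` (one-row tibble
#'   including `auc`), and `roc`.
#' @export
evaluate_model <- function(model, corpus, embedding, split, subset = "test",
                           threshold = 0.5) {
  ids <- split_ids(split, subset)
  sub <- corpus[corpus$sample_id %in% ids, ]
  preds <- predict(model, sub, embedding, threshold = threshold)
  counts <- confusion_counts(preds$label, preds$p_winged, threshold = threshold)
  metrics <- classification_metrics(counts)
  if (length(unique(preds$label)) == 2L) {
    rc <- roc_auc(preds$p_winged, preds$label)
    metrics$auc <- rc$auc
    roc <- rc$roc
  } else {
    warn("AUC undefined: evaluated subset contains a single class")
    metrics$auc <- NA_real_
    roc <- NULL
  }
  list(predictions = preds, counts = counts, metrics = metrics, roc = roc)
}
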