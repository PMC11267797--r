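## Classifier-style evaluation of scores against easy/hard synthesis
## labels.  Higher score = predicted harder, so the hard class ("HS") is
## the positive class throughout.

check_labeled <- function(data, score_col, label_col, positive) {
  stopifnot(is.data.frame(data), score_col %in% names(data), label_col %in% names(data))
  score <- data[[score_col]]
  label <- as.character(data[[label_col]])
  if (any(is.na(score)) || any(is.na(label))) {
    stop("labeled scores contain missing values", call. = FALSE)
  }
  pos <- label == positive
  if (!any(pos) || all(pos)) {
    stop("both classes must be present to compute PR/ROC curves", call. = FALSE)
  }
  list(score = score, pos = pos)
}

#' Evaluate labeled scores: PR-AUC and ROC-AUC
#'
#' ROC-AUC is computed via the rank statistic (Mann-Whitney; ties counted
#' half). PR-AUC is interpolation-free step integration of precision over
#' recall, processing tied scores as one threshold group.
#'
#' @param data Data frame with a score column and a binary label column.
#' @param score_col,label_col Column names (defaults `"score"`,
#'   `"label"`).
#' @param positive Positive-class label; default `"HS"` (hard to
#'   synthesize; higher score must mean harder).
#' @return A one-row tibble: `pr_auc`, `roc_auc`, `n_pos`, `n_neg`.
#' @export
evaluate_scores <- function(data, score_col = "score", label_col = "label",
                            positive = "HS") {
  x <- check_labeled(data, score_col, label_col, positive)
  tibble::tibble(
    pr_auc = pr_auc(x$score, x$pos),
    roc_auc = roc_auc(x$score, x$pos),
    n_pos = sum(x$pos),
    n_neg = sum(!x$pos)
  )
}

roc_auc <- function(score, pos) {
  r <- rank(score, ties.method = "average")
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

pr_auc <- function(score, pos) {
  cv <- pr_curve_points(score, pos)
  sum(diff(c(0, cv$recall)) * cv$precision)
}

## precision/recall at each descending score threshold (ties grouped)
pr_curve_points <- function(score, pos) {
  ord <- order(-score)
  score <- score[ord]
  pos <- pos[ord]
  grp_last <- !duplicated(score, fromLast = TRUE)  # last index of each tie group
  tp <- cumsum(pos)[grp_last]
  fp <- cumsum(!pos)[grp_last]
  tibble::tibble(
    threshold = score[grp_last],
    recall = tp / sum(pos),
    precision = tp / (tp + fp)
  )
}

roc_curve_points <- function(score, pos) {
  ord <- order(-score)
  score <- score[ord]
  pos <- pos[ord]
  grp_last <- !duplicated(score, fromLast = TRUE)
  tp <- c(0, cumsum(pos)[grp_last])
  fp <- c(0, cumsum(!pos)[grp_last])
  tibble::tibble(
    threshold = c(Inf, score[grp_last]),
    fpr = fp / sum(!pos),
    tpr = tp / sum(pos)
  )
}

#' Precision-recall curve of labeled scores
#' @inheritParams evaluate_scores
#' @return Tibble `threshold`, `recall`, `precision`.
#' @export
pr_curve <- function(data, score_col = "score", label_col = "label", positive = "HS") {
  x <- check_labeled(data, score_col, label_col, positive)
  pr_curve_points(x$score, x$pos)
}

#' ROC curve of labeled scores
#' @inheritParams evaluate_scores
#' @return Tibble `threshold`, `fpr`, `tpr` (starts at the origin).
#' @export
roc_curve <- function(data, score_col = "score", label_col = "label", positive = "HS") {
  x <- check_labeled(data, score_col, label_col, positive)
  roc_curve_points(x$score, x$pos)
}
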