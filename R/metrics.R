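#' Classification accuracy from confusion counts
#'
#' `(TN + TP) / (TN + FP + TP + FN) * 100`. For single-label multiclass
#' problems the micro-averaged one-vs-rest form of these counts reduces to
#' the plain fraction of correctly predicted samples, which equals top-1
#' accuracy.
#'
#' @param counts list or data frame with fields `TP`, `TN`, `FP`, `FN`
#'   (non-negative; summed if vectors).
#' @return accuracy percentage in `[0, 100]`.
#' @examples
#' accuracy(list(TP = 3, TN = 4, FP = 2, FN = 1))  # 70
#' @export
accuracy <- function(counts) {
  tp <- sum(counts$TP); tn <- sum(counts$TN)
  fp <- sum(counts$FP); fn <- sum(counts$FN)
  if (any(c(tp, tn, fp, fn) < 0)) stop("confusion counts must be non-negative")
  tot <- tp + tn + fp + fn
  if (tot == 0) stop("all confusion counts are zero")
  (tn + tp) / tot * 100
}

#' One-vs-rest confusion counts
#'
#' @param pred,truth class label vectors (same length).
#' @param positive the class treated as positive.
#' @return list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(pred, truth, positive) {
  p <- pred == positive; t <- truth == positive
  list(TP = sum(p & t), TN = sum(!p & !t), FP = sum(p & !t), FN = sum(!p & t))
}

#' Top-k accuracy
#'
#' Percentage of samples whose true label is among the `k` highest-scoring
#' classes. Score ties are broken by the lower class index.
#'
#' @param scores `N x K` score matrix (rows = samples).
#' @param labels integer vector of true class indices in `1..K`.
#' @param k number of top predictions considered, `1 <= k <= K`.
#' @return percentage in `[0, 100]`.
#' @export
topk_accuracy <- function(scores, labels, k) {
  scores <- as.matrix(scores)
  n <- nrow(scores); K <- ncol(scores)
  if (n < 1) stop("need at least one sample")
  if (k < 1 || k > K) stop("`k` must be in [1, K]")
  if (any(labels < 1 | labels > K)) stop("label outside [1, K]")
  hit <- vapply(seq_len(n), function(i) {
    ord <- order(scores[i, ], decreasing = TRUE)  # stable: ties -> lower index
    labels[i] %in% ord[seq_len(k)]
  }, logical(1))
  mean(hit) * 100
}

#' Evaluate a classifier on a manifest split
#'
#' Classifies every image of the named split and reports top-1 and top-5
#' accuracy (fraction of correctly predicted samples, as percentages) plus a per-class
#' one-vs-rest breakdown.
#'
#' @param model a classifier from [build_modified_resnet50()].
#' @param manifest data frame with `path`, `label`, `split`.
#' @param split which split to evaluate (`"test"` by default).
#' @param classes optional fixed class-name ordering; defaults to the sorted
#'   labels of the manifest.
#' @return a `metrics_report` list with `top1`, `top5`, `n`, `per_class`,
#'   `scores`, `labels`.
#' @export
evaluate <- function(model, manifest, split = "test", classes = NULL) {
  rows <- manifest[manifest$split == split, , drop = FALSE]
  if (nrow(rows) == 0L) stop("empty split: ", split)
  if (is.null(classes)) classes <- sort(unique(manifest$label))
  if (!all(rows$label %in% classes)) stop("label outside the declared class set")
  K <- length(classes)
  scores <- matrix(0, nrow(rows), K)
  for (i in seq_len(nrow(rows)))
    scores[i, ] <- classify(read_image(rows$path[i]), model)
  labels <- match(rows$label, classes)
  pred <- classes[max.col(scores, ties.method = "first")]
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    cc <- confusion_counts(pred, rows$label, cl)
    data.frame(class = cl, TP = cc$TP, TN = cc$TN, FP = cc$FP, FN = cc$FN,
               accuracy = accuracy(cc), stringsAsFactors = FALSE)
  }))
  structure(list(top1 = topk_accuracy(scores, labels, 1L),
                 top5 = topk_accuracy(scores, labels, min(5L, K)),
                 n = nrow(rows), per_class = per_class,
                 scores = scores, labels = labels),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report n=%d top-1 %.2f%% top-5 %.2f%%>\n",
              x$n, x$top1, x$top5))
  invisible(x)
}
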