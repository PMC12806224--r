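#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, in
#' [-1, 1]. Robust to class imbalance: 1 means perfect prediction, 0 no
#' better than chance, -1 total disagreement. When any denominator factor is
#' zero (a degenerate predictor or degenerate labels) the convention MCC = 0
#' is returned, since such a predictor carries no correlation.
#'
#' @param tp,tn,fp,fn Nonnegative confusion counts (must not all be zero).
#' @return MCC in [-1, 1].
#' @examples
#' mcc(tp = 90, tn = 80, fp = 10, fn = 20)  # 0.70353...
#' @export
mcc <- function(tp, tn, fp, fn) {
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0)) stop("confusion counts must be nonnegative")
  if (sum(counts) == 0) stop("all confusion counts are zero")
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom2)
}

#' Confusion counts for binary labels/predictions
#' @param labels,predictions 0/1 vectors of equal length.
#' @return Named list with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(labels, predictions) {
  if (length(labels) != length(predictions)) stop("length mismatch")
  list(tp = sum(labels == 1 & predictions == 1),
       tn = sum(labels == 0 & predictions == 0),
       fp = sum(labels == 0 & predictions == 1),
       fn = sum(labels == 1 & predictions == 0))
}

#' MCC from label/prediction vectors (binary or multiclass)
#'
#' For more than two classes the multi-category generalization
#' (R_k statistic) over the K x K confusion matrix is used.
#'
#' @param labels,predictions Integer class vectors of equal length.
#' @return MCC in [-1, 1].
#' @export
mcc_from_predictions <- function(labels, predictions) {
  if (length(labels) != length(predictions)) stop("length mismatch")
  classes <- sort(unique(c(labels, predictions)))
  if (length(classes) <= 2L) {
    cc <- confusion_counts(as.integer(labels == max(classes)),
                           as.integer(predictions == max(classes)))
    return(mcc(cc$tp, cc$tn, cc$fp, cc$fn))
  }
  C <- table(factor(labels, classes), factor(predictions, classes))
  C <- matrix(as.numeric(C), nrow(C))
  n <- sum(C); tr <- sum(diag(C))
  rs <- rowSums(C); cs <- colSums(C)
  num <- tr * n - sum(rs * cs)
  den <- sqrt(n^2 - sum(rs^2)) * sqrt(n^2 - sum(cs^2))
  if (den == 0) return(0)
  num / den
}

#' Macro-averaged F1 score
#'
#' Unweighted mean of per-class F1. A class absent from both labels and
#' predictions contributes an F1 of 0 and still counts in the mean
#' (deterministic, conservative convention).
#'
#' @param labels,predictions Class vectors of equal length.
#' @param n_classes Number of classes K; classes are 0..K-1 (or provide
#'   factors/characters and K is inferred).
#' @return Macro F1 in [0, 1].
#' @export
f1_macro <- function(labels, predictions, n_classes = NULL) {
  if (length(labels) != length(predictions)) stop("length mismatch")
  if (length(labels) == 0L) stop("empty input")
  classes <- if (is.null(n_classes)) sort(unique(c(labels, predictions)))
             else seq_len(n_classes) - 1L
  f1s <- vapply(classes, function(k) {
    tp <- sum(labels == k & predictions == k)
    fp <- sum(labels != k & predictions == k)
    fn <- sum(labels == k & predictions != k)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1s)
}

#' Classification accuracy
#' @param labels,predictions Equal-length vectors.
#' @return Fraction of exact matches.
#' @export
accuracy <- function(labels, predictions) {
  if (length(labels) != length(predictions)) stop("length mismatch")
  mean(labels == predictions)
}

#' Area under the ROC curve (rank-sum formulation)
#'
#' The probability that a uniformly random positive receives a higher score
#' than a uniformly random negative, with ties counted one half
#' (Mann-Whitney U statistic). Exact and parameter-free; no curve
#' interpolation.
#'
#' @param labels 0/1 vector; both classes must be present.
#' @param scores Real scores, higher = more positive.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(labels, scores) {
  if (length(labels) != length(scores)) stop("length mismatch")
  pos <- labels == 1; neg <- labels == 0
  n1 <- sum(pos); n0 <- sum(neg)
  if (n1 == 0L || n0 == 0L) stop("AUROC undefined: only one class present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Average-precision formulation: scores are ranked decreasingly and the
#' precision at each positive's rank is averaged (ties resolved by stable
#' order of the ranking). A perfect ranking gives 1; a random ranking gives
#' about the positive prevalence.
#'
#' @param labels 0/1 vector with at least one positive.
#' @param scores Real scores.
#' @return AUPRC in (0, 1].
#' @export
auprc <- function(labels, scores) {
  if (length(labels) != length(scores)) stop("length mismatch")
  if (sum(labels == 1) == 0L) stop("AUPRC undefined: no positives")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  cum_tp <- cumsum(lab == 1)
  prec <- cum_tp / seq_along(lab)
  mean(prec[lab == 1])
}

#' Spearman rank correlation
#'
#' Pearson correlation of the (average-tie) ranks: invariant under strictly
#' monotone transforms of either argument.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Correlation in [-1, 1].
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2L) stop("need at least two observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation undefined for constant input")
  stats::cor(x, y, method = "spearman")
}

#' Regression losses: MSE, MAE and Student-t loss
#'
#' The Student-t loss is the mean negative log-kernel of a standardized
#' Student-t distribution applied to the residuals:
#' `mean(((nu+1)/2) * log(1 + r^2/nu))` with `nu = 1` by default. Reported
#' "Student-t losses" in the benchmarking literature rarely print their
#' exact normalization, so `nu` and this form are configurable and
#' documented as an interpretation: the loss grows logarithmically,
#' down-weighting outliers relative to MSE.
#'
#' @param y_true,y_pred Aligned numeric vectors.
#' @param nu Student-t degrees of freedom (default 1).
#' @return Named list with `mse`, `mae`, `student_t`.
#' @export
regression_losses <- function(y_true, y_pred, nu = 1) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) == 0L) stop("empty input")
  r <- y_pred - y_true
  list(mse = mean(r^2), mae = mean(abs(r)),
       student_t = mean(((nu + 1) / 2) * log1p(r^2 / nu)))
}

#' Assemble the metric report for a task type
#'
#' Emits the metric set used for each task family: accuracy, macro-F1, MCC
#' and AUROC for binary tasks; the same plus macro AUROC/AUPRC (one-vs-rest)
#' for multiclass; Spearman, MSE, MAE and Student-t loss for regression.
#'
#' @param task_type `"binary"`, `"multiclass"`, or `"regression"`.
#' @param labels True labels (classes or reals).
#' @param predictions Predicted classes (classification) or reals
#'   (regression).
#' @param scores For classification: score matrix (n x K class
#'   probabilities) or a vector of positive-class scores for binary tasks.
#' @param n_classes Number of classes.
#' @return A named list of metric values (class `metrics_report`),
#'   serializable to JSON with stable key names.
#' @export
metrics_report <- function(task_type, labels, predictions, scores = NULL,
                           n_classes = NULL) {
  out <- switch(task_type,
    binary = {
      sc <- if (is.matrix(scores)) scores[, 2L] else scores
      cc <- confusion_counts(labels, predictions)
      list(accuracy = accuracy(labels, predictions),
           f1_macro = f1_macro(labels, predictions, n_classes = 2L),
           mcc = mcc(cc$tp, cc$tn, cc$fp, cc$fn),
           auroc = if (length(unique(labels)) == 2L) auroc(labels, sc) else NA_real_,
           confusion = cc)
    },
    multiclass = {
      K <- n_classes %||% ncol(scores)
      per_class <- lapply(seq_len(K) - 1L, function(k) {
        lab_k <- as.integer(labels == k)
        if (length(unique(lab_k)) < 2L) return(list(auroc = NA_real_, auprc = NA_real_))
        sc_k <- scores[, k + 1L]
        list(auroc = auroc(lab_k, sc_k), auprc = auprc(lab_k, sc_k))
      })
      list(accuracy = accuracy(labels, predictions),
           f1_macro = f1_macro(labels, predictions, n_classes = K),
           mcc = mcc_from_predictions(labels, predictions),
           auroc = mean(vapply(per_class, `[[`, numeric(1), "auroc"), na.rm = TRUE),
           auprc = mean(vapply(per_class, `[[`, numeric(1), "auprc"), na.rm = TRUE))
    },
    regression = {
      rl <- regression_losses(labels, predictions)
      list(spearman = spearman(labels, predictions),
           mse = rl$mse, mae = rl$mae, student_t_loss = rl$student_t)
    },
    stop("unknown task type: ", task_type)
  )
  structure(out, class = "metrics_report")
}
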