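# Inter-rater agreement (Cohen's kappa, consistency rate) and binary
# classifier evaluation (confusion-matrix metrics, ROC, AUC).

#' Confusion matrix of paired categorical calls
#'
#' Either cross-tabulates two vectors of calls (rows = method 1, columns =
#' method 2) or validates a ready-made K x K count matrix.
#'
#' @param x vector of calls from method 1, or a K x K count matrix.
#' @param y vector of calls from method 2 (ignored when `x` is a matrix).
#' @param labels class labels; default: sorted union of observed classes,
#'   or the matrix dimnames.
#' @return Object of class `confusion_matrix` (an integer matrix).
#' @examples
#' confusion_matrix(matrix(c(20, 10, 5, 15), 2))
#' @export
confusion_matrix <- function(x, y = NULL, labels = NULL) {
  if (is.matrix(x)) {
    m <- x
    if (nrow(m) != ncol(m) || nrow(m) < 2)
      stop("confusion matrix must be square with K >= 2")
    if (any(m < 0) || any(!is.finite(m))) stop("counts must be non-negative")
    if (sum(m) <= 0) stop("confusion matrix must contain observations")
    if (is.null(labels))
      labels <- if (!is.null(rownames(m))) rownames(m)
                else paste0("class", seq_len(nrow(m)))
  } else {
    if (is.null(y) || length(x) != length(y))
      stop("x and y must be call vectors of equal length")
    if (is.null(labels)) labels <- sort(unique(c(as.character(x), as.character(y))))
    if (length(labels) < 2) stop("need at least 2 classes")
    fx <- factor(as.character(x), levels = labels)
    fy <- factor(as.character(y), levels = labels)
    m <- unclass(table(fx, fy))
  }
  dimnames(m) <- list(method1 = labels, method2 = labels)
  structure(m, class = c("confusion_matrix", "matrix", "array"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d classes, N = %d\n", nrow(x), sum(x)))
  print(unclass(x))
  invisible(x)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between two raters from a K x K confusion
#' matrix: observed agreement P0 = sum(diagonal)/N, expected chance
#' agreement Pe = sum_k r_k c_k / N^2 from the row and column marginals,
#' and kappa = (P0 - Pe)/(1 - Pe) in \[-1, 1\].
#'
#' @param m a [confusion_matrix()] (or square count matrix).
#' @return Object of class `cohens_kappa`: list with `P0`, `Pe`, `kappa`,
#'   `N`.
#' @examples
#' cohens_kappa(confusion_matrix(matrix(c(20, 10, 5, 15), 2)))
#' @export
cohens_kappa <- function(m) {
  if (!inherits(m, "confusion_matrix")) m <- confusion_matrix(m)
  N <- sum(m)
  P0 <- sum(diag(m)) / N
  Pe <- sum(rowSums(m) * colSums(m)) / N^2
  if (abs(1 - Pe) < .Machine$double.eps * 4)
    stop("kappa undefined: expected chance agreement Pe = 1 ",
         "(both raters constant on the same class)")
  structure(list(P0 = P0, Pe = Pe, kappa = (P0 - Pe) / (1 - Pe), N = N),
            class = "cohens_kappa")
}

#' @export
print.cohens_kappa <- function(x, ...) {
  cat(sprintf("<cohens_kappa> kappa = %.4f (P0 = %.4f, Pe = %.4f, N = %d)\n",
              x$kappa, x$P0, x$Pe, x$N))
  invisible(x)
}

#' Consistency rate
#'
#' The observed agreement rate P0 (fraction of observations on the
#' confusion-matrix diagonal).
#'
#' @param m a [confusion_matrix()] (or square count matrix).
#' @return Scalar in \[0, 1\].
#' @export
consistency_rate <- function(m) {
  if (!inherits(m, "confusion_matrix")) m <- confusion_matrix(m)
  sum(diag(m)) / sum(m)
}

#' Reduce multi-label determinations to a single primary class
#'
#' When an image receives one or more categorical determinations, the
#' agreement analysis needs a single class per image. The default priority
#' lets an epithelial call dominate a non-epithelial one, and a cancerous
#' call dominate a healthy one; the priority order is configurable.
#'
#' @param calls list of character vectors, one vector of determinations
#'   per image.
#' @param priority class labels in decreasing priority.
#' @return Character vector of primary classes, one per image.
#' @export
reduce_determinations <- function(calls,
                                  priority = c("cancerous", "healthy",
                                               "nonepithelial")) {
  vapply(calls, function(cs) {
    if (length(cs) == 0) stop("each image needs at least one determination")
    hit <- priority[priority %in% cs]
    if (length(hit) == 0)
      stop("determination outside the priority list: ",
           paste(cs, collapse = ", "))
    hit[1]
  }, character(1))
}

#' Binary classification metrics
#'
#' Accuracy, precision, recall and F1 from TP/FP/TN/FN counts. A metric
#' whose denominator is zero is reported as NA and flagged in the
#' `undefined` field rather than coerced to 0.
#'
#' @param TP,FP,TN,FN non-negative counts; alternatively pass a single
#'   list/vector with those names as `TP`.
#' @return Object of class `binary_metrics`: list with `accuracy`,
#'   `precision`, `recall`, `f1`, the counts, and `undefined` (character
#'   vector of metrics with zero denominators).
#' @examples
#' binary_metrics(30, 10, 50, 10)
#' @export
binary_metrics <- function(TP, FP = NULL, TN = NULL, FN = NULL) {
  if (is.list(TP) || (is.numeric(TP) && length(TP) == 4 && !is.null(names(TP)))) {
    e <- as.list(TP); TP <- e$TP; FP <- e$FP; TN <- e$TN; FN <- e$FN
  }
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be non-negative finite numbers")
  undefined <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); NA_real_ }
    else num / den
  }
  accuracy <- safe(TP + TN, TP + FN + FP + TN, "accuracy")
  precision <- safe(TP, TP + FP, "precision")
  recall <- safe(TP, TP + FN, "recall")
  f1 <- if (is.na(precision) || is.na(recall)) {
    undefined <- c(undefined, "f1"); NA_real_
  } else if (precision + recall == 0) {
    0
  } else 2 * precision * recall / (precision + recall)
  structure(list(accuracy = accuracy, precision = precision,
                 recall = recall, f1 = f1, counts = counts,
                 undefined = unique(undefined)),
            class = "binary_metrics")
}

#' @export
print.binary_metrics <- function(x, ...) {
  cat(sprintf(
    "<binary_metrics> accuracy %.4f | precision %.4f | recall %.4f | F1 %.4f\n",
    x$accuracy, x$precision, x$recall, x$f1))
  if (length(x$undefined))
    cat("  undefined (zero denominator):", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' ROC curve by threshold sweep
#'
#' Sweeps the decision threshold over the unique score values (ties
#' grouped at a single threshold, descending) and records the
#' false-positive and true-positive rate at each cut; the curve is
#' anchored at (0, 0) and (1, 1).
#'
#' @param scores numeric score per item (higher = more positive).
#' @param labels binary truth per item (logical, 0/1, or a two-level
#'   factor whose second level is positive).
#' @return Object of class `roc_curve`: list with descending `thresholds`
#'   (starting at Inf) and matching `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  scores <- as.numeric(scores)
  pos <- as_binary_labels(labels)
  if (length(scores) != length(pos)) stop("scores and labels lengths differ")
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0 || nN == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  cum_tp <- cumsum(p); cum_fp <- cumsum(!p)
  last <- cumsum(rle(s)$lengths)  # last index of each tied score block
  structure(list(thresholds = c(Inf, s[last]),
                 fpr = c(0, cum_fp[last] / nN),
                 tpr = c(0, cum_tp[last] / nP)),
            class = "roc_curve")
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) {
    if (nlevels(labels) != 2) stop("labels factor must have 2 levels")
    return(labels == levels(labels)[2])
  }
  u <- sort(unique(labels))
  if (!all(u %in% c(0, 1))) stop("numeric labels must be 0/1")
  labels == 1
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.4f\n",
              length(x$fpr), auc(x)))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "false-positive rate", ylab = "true-positive rate", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Permutation null of the AUC
#'
#' Mean AUC of the same scores against label permutations: the exact
#' chance-level calibration of the ROC/AUC machinery (expected value 0.5
#' regardless of how the scores are distributed or clustered).
#'
#' @param scores numeric score per item.
#' @param labels binary truth per item.
#' @param n_perm number of label permutations (default 20).
#' @param seed integer seed for the permutations.
#' @return Mean AUC over the permutations.
#' @export
permutation_null_auc <- function(scores, labels, n_perm = 20, seed = 1) {
  pos <- as_binary_labels(labels)
  with_seed(seed, mean(vapply(seq_len(n_perm), function(i)
    auc(roc_curve(scores, sample(pos))), numeric(1))))
}

#' Area under the ROC curve
#'
#' Trapezoidal integral of TPR over FPR. With the tie-grouping threshold
#' sweep this equals the Mann-Whitney pairwise-win probability with ties
#' counted one half: 1 is perfect discrimination, 0.5 chance level.
#'
#' @param x a `roc_curve`, or a numeric score vector (then `labels` is
#'   required).
#' @param labels binary truth per item when `x` is a score vector.
#' @return Scalar in \[0, 1\].
#' @export
auc <- function(x, labels = NULL) {
  if (!inherits(x, "roc_curve")) x <- roc_curve(x, labels)
  sum(diff(x$fpr) * (utils::head(x$tpr, -1) + utils::tail(x$tpr, -1)) / 2)
}
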