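# normalize label input to logical "is positive"
as_binary_labels <- function(y) {
  if (is.logical(y)) return(y)
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    if (!all(y %in% c("positive", "negative"))) {
      stop("character labels must be 'positive'/'negative'", call. = FALSE)
    }
    return(y == "positive")
  }
  if (is.numeric(y)) return(y > 0.5)
  stop("unsupported label type", call. = FALSE)
}

#' Confusion counts from truth and prediction
#'
#' @param truth,pred Labels (logical, `"positive"`/`"negative"` character,
#'   or 0/1).
#' @return A list of class `"confusion_counts"` with `n_pos`, `n_neg`
#'   (class sizes), `fn` (positives called negative) and `fp` (negatives
#'   called positive).
#' @export
confusion_counts <- function(truth, pred) {
  t <- as_binary_labels(truth); p <- as_binary_labels(pred)
  structure(list(n_pos = sum(t), n_neg = sum(!t),
                 fn = sum(t & !p), fp = sum(!t & p)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Sensitivity `Sn = 1 - FN/N+`, specificity `Sp = 1 - FP/N-`, accuracy
#' `Acc = 1 - (FN + FP)/(N+ + N-)` and the Matthews correlation coefficient.
#' These "one minus error rate" forms are algebraically identical to the
#' usual TP/TN/FP/FN definitions. MCC is 0 whenever a factor under its root
#' vanishes (e.g. an empty predicted class).
#'
#' @param counts A [confusion_counts()] object, or `n_pos` when the four
#'   counts are given separately.
#' @param n_neg,fn,fp Counts when not using a `confusion_counts` object.
#' @return A one-row tibble with `sn`, `sp`, `acc`, `mcc`.
#' @examples
#' metrics_report(confusion_counts(rep(c(TRUE, FALSE), c(10, 10)),
#'                                 rep(c(TRUE, FALSE), c(12, 8))))
#' @export
metrics_report <- function(counts, n_neg = NULL, fn = NULL, fp = NULL) {
  if (!inherits(counts, "confusion_counts")) {
    counts <- structure(list(n_pos = counts, n_neg = n_neg, fn = fn, fp = fp),
                        class = "confusion_counts")
  }
  with(counts, {
    if (n_pos <= 0 || n_neg <= 0) stop("both classes must be non-empty", call. = FALSE)
    stopifnot(fn >= 0, fn <= n_pos, fp >= 0, fp <= n_neg)
    tp <- as.numeric(n_pos - fn); tn <- as.numeric(n_neg - fp)
    fp <- as.numeric(fp); fn <- as.numeric(fn)
    denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    tibble::tibble(
      sn = 1 - fn / n_pos,
      sp = 1 - fp / n_neg,
      acc = 1 - (fn + fp) / (n_pos + n_neg),
      mcc = if (denom2 == 0) 0 else (tp * tn - fp * fn) / sqrt(denom2)
    )
  })
}

#' ROC curve and AUC
#'
#' Curve over all score thresholds; AUC as the normalized Mann–Whitney
#' U statistic (rank-based, so tied scores are averaged), which equals the
#' trapezoidal area under the tie-aware curve and is invariant to strictly
#' monotone transforms of the scores.
#'
#' @param truth Labels as in [confusion_counts()]; both classes required.
#' @param scores Finite numeric scores, larger favouring the positive class.
#' @return An object of class `"pseterm_roc"`: `curve` tibble
#'   (`threshold`, `fpr`, `tpr`) and `auc`.
#' @examples
#' r <- roc_auc(c(TRUE, TRUE, FALSE), c(0.9, 0.8, 0.1))
#' r$auc
#' @export
roc_auc <- function(truth, scores) {
  t <- as_binary_labels(truth)
  if (!any(t) || all(t)) stop("both classes must be present", call. = FALSE)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  n_pos <- sum(t); n_neg <- sum(!t)
  r <- rank(scores)  # ties averaged
  auc <- (sum(r[t]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  th <- sort(unique(scores), decreasing = TRUE)
  curve <- tibble::tibble(
    threshold = c(Inf, th),
    tpr = vapply(c(Inf, th), function(x) mean(scores[t] >= x), numeric(1)),
    fpr = vapply(c(Inf, th), function(x) mean(scores[!t] >= x), numeric(1))
  )
  structure(list(curve = curve, auc = auc), class = "pseterm_roc")
}

#' @export
print.pseterm_roc <- function(x, ...) {
  cat("<pseterm_roc> AUC = ", round(x$auc, 4), " (",
      nrow(x$curve), " thresholds)\n", sep = "")
  invisible(x)
}
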