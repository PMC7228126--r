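#' Fit a min-max scaler on training features
#'
#' Maps every feature affinely so the training minimum hits the low end of
#' `range` and the training maximum the high end; constant features map to
#' the midpoint. Intended for margin/distance-based learners (SVM, logistic
#' regression, KNN, perceptron and boosting over them); tree and naive-Bayes
#' models are scale-invariant and skip it.
#'
#' @param X A feature tibble or numeric matrix — training rows only.
#' @param range `c(0, 1)` (default) or `c(-1, 1)`.
#' @return An object of class `"minmax_scaler"`.
#' @examples
#' sc <- minmax_fit(matrix(c(0, 5, 10), ncol = 1))
#' minmax_apply(sc, matrix(c(0, 5, 10), ncol = 1))
#' @export
minmax_fit <- function(X, range = c(0, 1)) {
  m <- if (is.data.frame(X)) features_as_matrix(X) else X
  stopifnot(length(range) == 2, range[1] < range[2])
  structure(list(min = apply(m, 2, min), max = apply(m, 2, max),
                 range = range, features = colnames(m)),
            class = "minmax_scaler")
}

#' Apply a fitted min-max scaler
#'
#' Unseen data may fall outside the training extrema; values are not
#' clipped, so out-of-range outputs are possible and expected.
#'
#' @param scaler A [minmax_fit()] result.
#' @param X Feature tibble or matrix with the same feature columns.
#' @return Object of the same shape as `X`, scaled.
#' @export
minmax_apply <- function(scaler, X) {
  if (!inherits(scaler, "minmax_scaler")) {
    stop("scaler has not been fitted (expected a 'minmax_scaler')", call. = FALSE)
  }
  is_df <- is.data.frame(X)
  m <- if (is_df) features_as_matrix(X) else X
  span <- scaler$max - scaler$min
  lo <- scaler$range[1]; hi <- scaler$range[2]
  out <- sapply(seq_len(ncol(m)), function(j) {
    if (span[j] == 0) rep((lo + hi) / 2, nrow(m))
    else lo + (m[, j] - scaler$min[j]) / span[j] * (hi - lo)
  })
  out <- matrix(out, nrow = nrow(m), dimnames = dimnames(m))
  if (is_df) {
    res <- dplyr::bind_cols(tibble::tibble(id = X$id), tibble::as_tibble(out))
    res
  } else {
    out
  }
}
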