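#' Pearson correlation matrix of features
#'
#' Redundancy diagnostic over feature columns. Constant features correlate
#' with nothing: their rows/columns are set to 0 (1 on the diagonal) and
#' flagged, never NaN.
#'
#' @param X A feature tibble (first column `id`) or numeric matrix.
#' @return A symmetric correlation matrix with unit diagonal; attribute
#'   `constant` marks zero-variance features.
#' @export
pearson_matrix <- function(X) {
  m <- if (is.data.frame(X)) features_as_matrix(X) else X
  if (nrow(m) < 2) stop("need at least 2 samples", call. = FALSE)
  const <- apply(m, 2, stats::sd) < 1e-300
  r <- suppressWarnings(stats::cor(m))
  r[const, ] <- 0
  r[, const] <- 0
  diag(r) <- 1
  structure(r, constant = const)
}

new_ranking <- function(method, scores, feature_names) {
  # descending scores, ties broken by original index (stable)
  ord <- order(-scores, seq_along(scores))
  structure(list(method = method,
                 scores = stats::setNames(scores, feature_names),
                 order = ord),
            class = "pseterm_ranking")
}

#' @export
print.pseterm_ranking <- function(x, ...) {
  cat("<pseterm_ranking> method = ", x$method, ", ", length(x$scores),
      " features; top: ",
      paste(names(x$scores)[utils::head(x$order, 3)], collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' F-score feature ranking
#'
#' For feature i the F-score is the squared separation of the class means
#' from the overall mean, divided by the summed unbiased within-class
#' variances:
#' \deqn{F_i = \frac{(\bar x_i^{(+)} - \bar x_i)^2 + (\bar x_i^{(-)} -
#'   \bar x_i)^2}{\frac{1}{n^+ - 1}\sum_k (x_{k,i}^{(+)} - \bar x_i^{(+)})^2
#'   + \frac{1}{n^- - 1}\sum_k (x_{k,i}^{(-)} - \bar x_i^{(-)})^2}}
#' Larger is more class-discriminative. A feature constant within both
#' classes scores 0 if the class means agree and a large sentinel (ranked
#' first) if they differ.
#'
#' @param X A feature tibble or numeric matrix.
#' @param y Labels: logical, or character with `"positive"` as the positive
#'   class.
#' @return A `"pseterm_ranking"`; see [generics::tidy()] for a tabular view.
#' @examples
#' X <- tibble::tibble(id = as.character(1:4), f = c(2, 4, 0, 2))
#' f_scores(X, c(TRUE, TRUE, FALSE, FALSE))$scores  # 0.5
#' @export
f_scores <- function(X, y) {
  m <- if (is.data.frame(X)) features_as_matrix(X) else X
  pos <- as_binary_labels(y)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos < 2 || n_neg < 2) {
    stop("each class needs >= 2 members (within-class variance undefined)",
         call. = FALSE)
  }
  mu <- colMeans(m)
  mu_p <- colMeans(m[pos, , drop = FALSE])
  mu_n <- colMeans(m[!pos, , drop = FALSE])
  var_p <- apply(m[pos, , drop = FALSE], 2, stats::var)
  var_n <- apply(m[!pos, , drop = FALSE], 2, stats::var)
  num <- (mu_p - mu)^2 + (mu_n - mu)^2
  den <- var_p + var_n
  scores <- ifelse(den > 0, num / den,
                   ifelse(num > 0, .Machine$double.xmax / 2, 0))
  new_ranking("fscore", scores, colnames(m))
}

#' Binomial-confidence feature ranking
#'
#' For count-valued features (k-mer occurrence counts). With `q_i = m_i / M`
#' the class prior and `N_j` the total occurrences of feature j, the upper
#' binomial tail
#' \deqn{P(n_{ij}) = \sum_{m = n_{ij}}^{N_j} \binom{N_j}{m} q_i^m
#'   (1-q_i)^{N_j - m}}
#' measures how surprising the observed concentration `n_ij` of feature j
#' in class i is; the confidence `CL_j = max_i (1 - P(n_{ij}))` ranks
#' features. Computed through the stable binomial survival function.
#'
#' @param X A feature tibble or matrix of nonnegative integer counts;
#'   real-valued features are refused.
#' @param y Labels as in [f_scores()].
#' @return A `"pseterm_ranking"`.
#' @export
binomial_confidence <- function(X, y) {
  m <- if (is.data.frame(X)) features_as_matrix(X) else X
  bad <- which(abs(m - round(m)) > 1e-9 | m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("binomial ranking needs nonnegative integer counts; feature '",
         colnames(m)[bad[1, 2]], "' is not count-valued", call. = FALSE)
  }
  pos <- as_binary_labels(y)
  if (sum(pos) == 0 || sum(!pos) == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  q <- c(pos = mean(pos), neg = mean(!pos))
  N_j <- colSums(m)
  n_pos_j <- colSums(m[pos, , drop = FALSE])
  tail_p <- function(n, N, q) {
    # upper tail including n itself; survival form for stability
    ifelse(N == 0, 1, stats::pbinom(n - 1, N, q, lower.tail = FALSE))
  }
  cl <- pmax(1 - tail_p(n_pos_j, N_j, q["pos"]),
             1 - tail_p(N_j - n_pos_j, N_j, q["neg"]))
  new_ranking("binomial", unname(cl), colnames(m))
}

#' Incremental feature selection over a ranking
#'
#' Evaluates a classifier on growing prefixes of the ranked feature list and
#' keeps the prefix with the highest cross-validated accuracy (smallest
#' prefix on ties). `stride` evaluates every stride-th prefix (plus the
#' full set), the standard cost control for thousands of features.
#'
#' @param X A feature tibble or matrix.
#' @param y Labels as in [f_scores()].
#' @param ranking A `"pseterm_ranking"` covering all features of `X`.
#' @param evaluator `function(X_matrix, y_logical, seed)` returning a CV
#'   accuracy; default [cv_evaluator()] (gradient-boosted trees, 5-fold,
#'   5 repeats).
#' @param stride Evaluate prefixes `stride, 2*stride, ...` (default 1);
#'   `"auto"` picks a stride giving about 20 prefixes.
#' @param max_features Cap on the largest prefix (default all).
#' @param seed Seed forwarded to the evaluator.
#' @return An object of class `"pseterm_ifs"` with the accuracy curve,
#'   `best_size` and `best_features`.
#' @export
incremental_selection <- function(X, y, ranking, evaluator = cv_evaluator(),
                                  stride = 1, max_features = NULL, seed = 1) {
  m <- if (is.data.frame(X)) features_as_matrix(X) else X
  stopifnot(inherits(ranking, "pseterm_ranking"),
            length(ranking$order) == ncol(m))
  n <- if (is.null(max_features)) ncol(m) else min(max_features, ncol(m))
  if (identical(stride, "auto")) stride <- max(1L, floor(n / 20))
  sizes <- unique(c(seq(stride, n, by = stride), n))
  acc <- vapply(sizes, function(s) {
    idx <- ranking$order[seq_len(s)]
    evaluator(m[, idx, drop = FALSE], as_binary_labels(y), seed)
  }, numeric(1))
  best <- sizes[which.max(acc)]  # which.max takes the first (smallest) tie
  structure(list(sizes = sizes, curve = acc, best_size = best,
                 best_features = colnames(m)[ranking$order[seq_len(best)]],
                 method = ranking$method, stride = stride),
            class = "pseterm_ifs")
}

#' @export
print.pseterm_ifs <- function(x, ...) {
  cat("<pseterm_ifs> ", length(x$sizes), " prefixes evaluated; best size ",
      x$best_size, " (accuracy ", round(max(x$curve), 4), ")\n", sep = "")
  invisible(x)
}

#' Class preference of k-mers
#'
#' For each k-mer, the share of sequences in each class containing it at
#' least once (`mode = "presence"`, default) or its share of all k-mer
#' occurrences in the class (`mode = "occurrence"`). Terminators show a
#' marked preference for T-rich pentamers, above all `TTTTT`.
#'
#' @param data A labelled sequence tibble with both classes present.
#' @param k K-mer size; must not exceed the shortest sequence.
#' @param kmers Optional subset of k-mers to report (default: all observed).
#' @param mode `"presence"` or `"occurrence"`.
#' @return A tibble `kmer`, `ratio_pos`, `ratio_neg`, sorted by
#'   `ratio_pos - ratio_neg` descending.
#' @export
kmer_class_preference <- function(data, k = 5, kmers = NULL,
                                  mode = c("presence", "occurrence")) {
  mode <- match.arg(mode)
  pos <- data$label == "positive"
  if (!any(pos) || !any(data$label == "negative")) {
    stop("both classes must be present", call. = FALSE)
  }
  if (k > min(nchar(data$sequence))) {
    stop("k exceeds the shortest sequence length", call. = FALSE)
  }
  ratio_in <- function(rows) {
    if (mode == "presence") {
      seen <- lapply(data$sequence[rows], function(s) unique(seq_windows(s, k)))
      tab <- table(unlist(seen))
      prop <- as.numeric(tab) / sum(rows)
    } else {
      tab <- table(unlist(lapply(data$sequence[rows], seq_windows, k = k)))
      prop <- as.numeric(tab) / sum(tab)
    }
    stats::setNames(prop, names(tab))
  }
  rp <- ratio_in(pos)
  rn <- ratio_in(data$label == "negative")
  km <- kmers %||% sort(union(names(rp), names(rn)))
  out <- tibble::tibble(
    kmer = km,
    ratio_pos = unname(ifelse(is.na(rp[km]), 0, rp[km])),
    ratio_neg = unname(ifelse(is.na(rn[km]), 0, rn[km]))
  )
  dplyr::arrange(out, dplyr::desc(.data$ratio_pos - .data$ratio_neg))
}
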