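#' Count overlapping k-mers in one sequence
#'
#' @param seq A single DNA string.
#' @param k K-mer size; must not exceed the sequence length.
#' @return Named integer vector of counts over the k-mers observed in the
#'   `L - k + 1` overlapping windows; counts sum to `L - k + 1`.
#' @examples
#' count_kmers("ACGT", 2)
#' @export
count_kmers <- function(seq, k) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  if (k > nchar(seq)) {
    stop("k = ", k, " exceeds sequence length ", nchar(seq), call. = FALSE)
  }
  tab <- table(seq_windows(seq, k))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

# counts over the full lexicographic 4^k alphabet (zeros included)
kmer_count_vector <- function(seq, k) {
  km <- all_kmers(k)
  out <- stats::setNames(integer(length(km)), km)
  got <- count_kmers(seq, k)
  out[names(got)] <- got
  out
}

#' Fit a position-weight model of k-tuple log-odds
#'
#' For each scored start site i, the probability of k-tuple x is estimated
#' over the training sequences that are long enough to have site i:
#' `p_xi = (n_xi + pseudocount) / (N_i + 4^k * pseudocount)`; the weight is
#' its log-odds against the uniform background `p0 = 1 / 4^k`,
#' `W_xi = ln(p_xi / p0)`. Train on the positive class only (the model is a
#' terminator profile); inside cross-validation it must be rebuilt per fold
#' from the training fold.
#'
#' @param data A sequence tibble; typically `dplyr::filter(d, label == "positive")`.
#' @param k K-tuple size.
#' @param pseudocount Additive smoothing per k-tuple per site (default 0.25).
#'   With `pseudocount = 0`, sites with a zero count would give `-Inf`
#'   weights; those entries instead get the floor `log(zero_floor / p0)` and
#'   the model is flagged.
#' @param zero_floor Probability floor used for zero counts when
#'   `pseudocount = 0` (default 1e-3).
#' @return An object of class `"pseterm_pwm"` with the weight matrix
#'   (`4^k` rows x `n_sites` columns).
#' @examples
#' train <- seq_dataset(c("a", "b"), c("AA", "AA"))
#' m <- build_pwm(train, k = 1, pseudocount = 0)
#' m$weights["A", ]  # ln 4 at both sites
#' @export
build_pwm <- function(data, k, pseudocount = 0.25, zero_floor = 1e-3) {
  stopifnot(nrow(data) > 0, pseudocount >= 0)
  seqs <- data$sequence
  L <- nchar(seqs)
  if (any(L < k)) stop("all training sequences must have length >= k", call. = FALSE)
  n_sites <- max(L) - k + 1
  km <- all_kmers(k)
  p0 <- 1 / 4^k
  counts <- matrix(0L, nrow = length(km), ncol = n_sites,
                   dimnames = list(km, NULL))
  N_i <- integer(n_sites)
  for (s in seqs) {
    w <- seq_windows(s, k)
    idx <- match(w, km)
    for (i in seq_along(idx)) counts[idx[i], i] <- counts[idx[i], i] + 1L
    N_i[seq_along(idx)] <- N_i[seq_along(idx)] + 1L
  }
  p <- sweep(counts + pseudocount, 2, N_i + 4^k * pseudocount, "/")
  has_zero <- pseudocount == 0 && any(counts == 0)
  W <- log(p / p0)
  if (has_zero) {
    W[counts == 0] <- log(zero_floor / p0)
  }
  structure(list(k = k, n_sites = n_sites, weights = W,
                 pseudocount = pseudocount, p0 = p0,
                 zero_floored = has_zero),
            class = "pseterm_pwm")
}

#' Length-normalised PWM score of sequences
#'
#' The score of a sequence is the mean site weight,
#' `F = (1/L) * sum_i W_{x_i, i}`, where the sum runs over the sites the
#' sequence actually has (at most `n_sites` of the model) and `L` is the
#' number of sites scored. Averaging rather than summing removes the length
#' advantage that longer sequences would otherwise accrue.
#'
#' @param data A sequence tibble.
#' @param pwm A model from [build_pwm()].
#' @return Numeric vector of scores, one per row of `data`.
#' @examples
#' train <- seq_dataset(c("a", "b"), c("AA", "AA"))
#' m <- build_pwm(train, k = 1, pseudocount = 0)
#' pwm_score(seq_dataset("q", "AA"), m)  # ln 4
#' @export
pwm_score <- function(data, pwm) {
  stopifnot(inherits(pwm, "pseterm_pwm"))
  km <- rownames(pwm$weights)
  vapply(data$sequence, function(s) {
    if (nchar(s) < pwm$k) {
      stop("sequence shorter than the model's k = ", pwm$k, call. = FALSE)
    }
    w <- seq_windows(s, pwm$k)
    n <- min(length(w), pwm$n_sites)
    idx <- match(w[seq_len(n)], km)
    mean(pwm$weights[cbind(idx, seq_len(n))])
  }, numeric(1), USE.NAMES = FALSE)
}

#' @export
print.pseterm_pwm <- function(x, ...) {
  cat("<pseterm_pwm> k = ", x$k, ", ", x$n_sites, " sites, pseudocount = ",
      x$pseudocount, if (x$zero_floored) " (zero counts floored)", "\n", sep = "")
  invisible(x)
}
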