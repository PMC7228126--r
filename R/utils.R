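DNA_BASES <- c("A", "C", "G", "T")

#' Enumerate all k-mers in lexicographic order
#'
#' K-mers over the DNA alphabet with A < C < G < T, the column order used by
#' every k-mer-indexed feature family.
#'
#' @param k K-mer size (positive integer).
#' @return Character vector of length `4^k`.
#' @examples
#' all_kmers(1)
#' head(all_kmers(3))
#' @export
all_kmers <- function(k) {
  stopifnot(length(k) == 1, k >= 1)
  out <- DNA_BASES
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      out <- as.vector(t(outer(out, DNA_BASES, paste0)))
    }
  }
  out
}

#' Reverse complement of a DNA string
#'
#' @param x Character vector of sequences over A/C/G/T.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ACGT")
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    b <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    paste(c(T = "A", A = "T", G = "C", C = "G")[b], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# run `expr` under a seeded RNG, restoring global RNG state afterwards;
# all randomized operations in the package funnel through this
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# split sequences into a character matrix padded with NA (rows = sequences)
seq_char_matrix <- function(seqs) {
  L <- nchar(seqs)
  m <- matrix(NA_character_, nrow = length(seqs), ncol = max(L))
  for (i in seq_along(seqs)) {
    m[i, seq_len(L[i])] <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
  }
  m
}

# overlapping k-mer windows of a single sequence
seq_windows <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) stop("sequence shorter than k = ", k, call. = FALSE)
  substring(seq, seq_len(L - k + 1), seq_len(L - k + 1) + k - 1)
}

check_labels <- function(label) {
  ok <- label %in% c("positive", "negative", "unknown")
  if (!all(ok)) {
    stop("labels must be 'positive', 'negative' or 'unknown'; got: ",
         paste(unique(label[!ok]), collapse = ", "), call. = FALSE)
  }
  label
}

# validate bases, reporting the first offending record and position
check_alphabet <- function(id, sequence) {
  for (i in seq_along(sequence)) {
    bad <- regexpr("[^ACGT]", sequence[i])
    if (bad > 0) {
      stop("non-ACGT character '", substr(sequence[i], bad, bad),
           "' in record '", id[i], "' at position ", bad,
           " (IUPAC ambiguity codes are not supported)", call. = FALSE)
    }
    if (!nzchar(sequence[i])) {
      stop("empty sequence in record '", id[i], "'", call. = FALSE)
    }
  }
  invisible(sequence)
}
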