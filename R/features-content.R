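#' Base-content features
#'
#' Five strand-composition statistics per sequence: AT content, GC content,
#' AT/GC ratio, GC skew `(G - C) / (G + C)` and AT skew `(A - T) / (A + T)`.
#' Intrinsic terminators are GC-rich in the stem and T-rich in the tail, so
#' these capture coarse class signal. A zero denominator (e.g. gcSkew of a
#' GC-free sequence) yields 0 and sets the `degenerate` flag rather than
#' erroring.
#'
#' @param data A sequence tibble.
#' @return A tibble with columns `id`, `atContent`, `gcContent`,
#'   `atgcRatio`, `gcSkew`, `atSkew` and logical `degenerate`.
#' @examples
#' base_content(seq_dataset("s", "ATGC"))
#' @export
base_content <- function(data) {
  m <- t(vapply(data$sequence, function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- c(A = sum(b == "A"), C = sum(b == "C"),
           G = sum(b == "G"), T = sum(b == "T"))
    at <- n["A"] + n["T"]; gc <- n["G"] + n["C"]; L <- length(b)
    degen <- FALSE
    safe_div <- function(num, den) {
      if (den == 0) { degen <<- TRUE; 0 } else num / den
    }
    c(atContent = unname(at / L),
      gcContent = unname(gc / L),
      atgcRatio = unname(safe_div(at, gc)),
      gcSkew = unname(safe_div(n["G"] - n["C"], gc)),
      atSkew = unname(safe_div(n["A"] - n["T"], at)),
      degenerate = as.numeric(degen))
  }, numeric(6), USE.NAMES = FALSE))
  tibble::tibble(id = data$id,
                 atContent = m[, 1], gcContent = m[, 2], atgcRatio = m[, 3],
                 gcSkew = m[, 4], atSkew = m[, 5],
                 degenerate = m[, 6] > 0)
}

#' Binary chemical encoding of one sequence
#'
#' Each base is encoded by its three chemical dichotomies — ring structure
#' (purine 0, pyrimidine 1), hydrogen bond (strong 0, weak 1) and functional
#' group (amino 0, keto 1) — giving A = (0,1,0), C = (1,0,0), G = (0,0,1),
#' T = (1,1,1).
#'
#' @param seq A single DNA string.
#' @param table A [load_property_table()] result.
#' @return A 3 x L binary matrix, rows in the order above.
#' @examples
#' chemical_encoding("AG")
#' @export
chemical_encoding <- function(seq, table = default_property_table()) {
  stopifnot(is.character(seq), length(seq) == 1, nzchar(seq))
  b <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  table$chemical[, b, drop = FALSE]
}

#' Physicochemical positional encoding of one sequence
#'
#' For each of the 32 dinucleotide properties, column i holds the property
#' value of the dinucleotide starting at position i (the final column is 0);
#' for each of the 12 trinucleotide properties, analogously with the last
#' two columns 0.
#'
#' @param seq A single DNA string of length >= 3.
#' @param table A [load_property_table()] result.
#' @return A 44 x L real matrix (32 dinucleotide rows above 12 trinucleotide
#'   rows).
#' @export
physico_encoding <- function(seq, table = default_property_table()) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < 3) stop("physico_encoding needs length >= 3", call. = FALSE)
  din <- seq_windows(seq, 2)
  tri <- seq_windows(seq, 3)
  m <- matrix(0, nrow = nrow(table$dinucleotide) + nrow(table$trinucleotide),
              ncol = L)
  rownames(m) <- c(rownames(table$dinucleotide), rownames(table$trinucleotide))
  m[seq_len(nrow(table$dinucleotide)), seq_along(din)] <-
    table$dinucleotide[, din, drop = FALSE]
  m[nrow(table$dinucleotide) + seq_len(nrow(table$trinucleotide)), seq_along(tri)] <-
    table$trinucleotide[, tri, drop = FALSE]
  m
}

#' Per-position 47-property feature vectors
#'
#' Stacks the 3-row chemical encoding over the 44-row physicochemical
#' encoding into a 47 x `l_max` matrix per sequence (columns beyond the
#' sequence end are zero), flattened position by position into a
#' `47 * l_max` feature vector: the first 47 entries are the properties of
#' position 0, and so on. Feature names encode property and position
#' (`<property>_p<position>`).
#'
#' @param data A sequence tibble; every sequence must satisfy
#'   `nchar(sequence) <= l_max`.
#' @param l_max Fixed encoding width in bp. The default 82 accommodates the
#'   longest benchmark-style sequence.
#' @param table A [load_property_table()] result.
#' @return A tibble: `id` plus `47 * l_max` numeric columns.
#' @export
nucleotidepro <- function(data, l_max = 82, table = default_property_table()) {
  too_long <- nchar(data$sequence) > l_max
  if (any(too_long)) {
    stop("sequence '", data$id[which(too_long)[1]], "' is longer than l_max = ",
         l_max, "; raise l_max", call. = FALSE)
  }
  prop_names <- c(rownames(table$chemical), rownames(table$dinucleotide),
                  rownames(table$trinucleotide))
  feat_names <- as.vector(outer(prop_names, seq_len(l_max) - 1,
                                function(p, i) paste0(p, "_p", i)))
  vals <- matrix(0, nrow = nrow(data), ncol = 47 * l_max,
                 dimnames = list(NULL, feat_names))
  for (r in seq_len(nrow(data))) {
    s <- data$sequence[r]
    enc <- rbind(chemical_encoding(s, table), physico_encoding(s, table))
    full <- matrix(0, nrow = 47, ncol = l_max)
    full[, seq_len(ncol(enc))] <- enc
    vals[r, ] <- as.vector(full)
  }
  out <- tibble::as_tibble(vals)
  dplyr::bind_cols(tibble::tibble(id = data$id), out)
}
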