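#' Build a labelled sequence table
#'
#' The package's central data structure is an ordinary tibble with columns
#' `id`, `sequence`, `label` and `species`. Bases are uppercased and
#' validated against the A/C/G/T alphabet; ambiguity codes are rejected
#' because every encoder downstream is defined only for the four bases.
#'
#' @param id Character vector of unique record identifiers.
#' @param sequence Character vector of DNA sequences (case-insensitive).
#' @param label `"positive"` (terminator), `"negative"` (non-terminator) or
#'   `"unknown"`. Recycled if length 1.
#' @param species Free-text species tag, recycled if length 1.
#' @return A tibble with columns `id`, `sequence`, `label`, `species`.
#' @examples
#' seq_dataset(c("s1", "s2"), c("ACGT", "ttttt"), label = "positive")
#' @export
seq_dataset <- function(id, sequence, label = "unknown", species = NA_character_) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (anyDuplicated(id)) {
    stop("duplicate ids: ", paste(unique(id[duplicated(id)]), collapse = ", "),
         call. = FALSE)
  }
  check_alphabet(id, sequence)
  tibble::tibble(
    id = id,
    sequence = sequence,
    label = check_labels(rep_len(as.character(label), length(id))),
    species = rep_len(as.character(species), length(id))
  )
}

#' Read labelled DNA sequences from FASTA or CSV
#'
#' CSV files use the dialect `id,sequence,label` (header required for the
#' multi-column form; `label` optional). A headerless single-column file is
#' read as a bare sequence list with auto-generated ids, so supplementary-
#' style one-sequence-per-line tables load directly. FASTA records get label
#' `"unknown"` unless `label` is supplied.
#'
#' @param path File to read.
#' @param format `"auto"` (by extension), `"fasta"` or `"csv"`.
#' @param label Optional label applied to every record (handy when a file
#'   holds one class, as the supplementary-style tables do).
#' @param species Optional species tag applied to every record.
#' @return A sequence tibble (see [seq_dataset()]).
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "acgt"), tf)
#' read_sequences(tf)
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "csv"),
                           label = NULL, species = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|fna|ffn)$", path, ignore.case = TRUE))
      "fasta" else "csv"
  }
  if (format == "fasta") {
    txt <- readLines(path, warn = FALSE)
    if (!any(nzchar(trimws(txt)))) stop("empty FASTA file: ", path, call. = FALSE)
    ss <- Biostrings::readBStringSet(path, format = "fasta")
    if (length(ss) == 0) stop("no FASTA records in: ", path, call. = FALSE)
    ids <- sub("\\s.*$", "", names(ss))
    seqs <- as.character(ss)
    return(seq_dataset(ids, seqs, label = label %||% "unknown", species = species))
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0 || !nzchar(trimws(first))) {
    stop("empty CSV file: ", path, call. = FALSE)
  }
  has_header <- grepl("^\\s*\"?id\"?\\s*,", first, ignore.case = TRUE) ||
    grepl("^\\s*\"?sequence\"?\\s*(,|$)", first, ignore.case = TRUE)
  if (has_header) {
    df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
    names(df) <- tolower(names(df))
    if (!"sequence" %in% names(df)) {
      stop("CSV must contain a 'sequence' column", call. = FALSE)
    }
    ids <- if ("id" %in% names(df)) df$id else sprintf("seq%d", seq_len(nrow(df)))
    labs <- label %||% (if ("label" %in% names(df)) df$label else "unknown")
    sp <- if (!is.na(species)) species else
      (if ("species" %in% names(df)) df$species else NA_character_)
    return(seq_dataset(ids, df$sequence, label = labs, species = sp))
  }
  # headerless single-column sequence list
  seqs <- trimws(readLines(path, warn = FALSE))
  seqs <- seqs[nzchar(seqs)]
  seq_dataset(sprintf("seq%d", seq_along(seqs)), seqs,
              label = label %||% "unknown", species = species)
}

#' Write a sequence table to FASTA or CSV
#'
#' Round-trips with [read_sequences()]: ids, bases and labels are preserved
#' (FASTA does not carry labels, so pass `label=` when reading back a
#' single-class FASTA).
#'
#' @param data A sequence tibble (see [seq_dataset()]).
#' @param path Output file.
#' @param format `"auto"`, `"fasta"` or `"csv"`.
#' @return `data`, invisibly.
#' @export
write_sequences <- function(data, path, format = c("auto", "fasta", "csv")) {
  format <- match.arg(format)
  if (nrow(data) == 0) stop("refusing to write an empty dataset", call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|fna|ffn)$", path, ignore.case = TRUE))
      "fasta" else "csv"
  }
  if (format == "fasta") {
    ss <- Biostrings::DNAStringSet(data$sequence)
    names(ss) <- data$id
    Biostrings::writeXStringSet(ss, path)
  } else {
    readr::write_csv(data[, c("id", "sequence", "label")], path, progress = FALSE)
  }
  invisible(data)
}

#' Split a sequence table into two parts
#'
#' Used to carve a benchmark / independent-test split (the usual ratio for
#' this problem is 8:2). The first part receives `round(n * ratio)` records;
#' under stratification the rounding is applied per class, in class order.
#' The split is a pure function of `seed`.
#'
#' @param data A sequence tibble.
#' @param ratio Fraction assigned to the first part, in (0, 1).
#' @param seed Integer seed.
#' @param stratified Preserve per-class proportions (default `TRUE`).
#' @return A named list of two tibbles, `train` and `test`.
#' @examples
#' d <- generate_background(10, 20, seed = 1)
#' sp <- split_dataset(d, ratio = 0.8, seed = 1)
#' nrow(sp$train); nrow(sp$test)
#' @export
split_dataset <- function(data, ratio = 0.8, seed = 1, stratified = TRUE) {
  stopifnot(ratio > 0, ratio < 1)
  take <- function(idx) {
    n1 <- round(length(idx) * ratio)
    with_seed(seed, sample(idx, n1))
  }
  if (stratified) {
    classes <- unique(data$label)
    sizes <- table(data$label)
    if (any(sizes < 2)) {
      stop("stratified split needs at least 2 records per class; class '",
           names(sizes)[which(sizes < 2)[1]], "' has ", min(sizes), call. = FALSE)
    }
    first <- integer(0)
    for (cl in classes) {
      idx <- which(data$label == cl)
      # per-class seed offset keeps classes independent but deterministic
      n1 <- round(length(idx) * ratio)
      first <- c(first, with_seed(seed + match(cl, classes), sample(idx, n1)))
    }
  } else {
    first <- take(seq_len(nrow(data)))
  }
  first <- sort(first)
  list(train = data[first, , drop = FALSE],
       test = data[setdiff(seq_len(nrow(data)), first), , drop = FALSE])
}

#' Generate i.i.d. background sequences
#'
#' Emulates non-terminator background drawn from regions flanking real
#' terminators: fixed-length sequences with independent bases.
#'
#' @param n Number of sequences.
#' @param length Sequence length in bp.
#' @param base_probs Probabilities for A, C, G, T (must sum to 1).
#' @param seed Integer seed.
#' @param species Species tag.
#' @return A sequence tibble with `label = "negative"`.
#' @examples
#' generate_background(3, 10, seed = 42)
#' @export
generate_background <- function(n, length, base_probs = rep(0.25, 4), seed = 1,
                                species = "synthetic") {
  if (n <= 0 || length <= 0) stop("n and length must be positive", call. = FALSE)
  if (abs(sum(base_probs) - 1) > 1e-9) {
    stop("base_probs must sum to 1", call. = FALSE)
  }
  seqs <- with_seed(seed, vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, length, replace = TRUE, prob = base_probs),
          collapse = "")
  }, character(1)))
  seq_dataset(sprintf("neg%d", seq_len(n)), seqs, label = "negative",
              species = species)
}

#' Simulation settings for terminator-like sequences
#'
#' Defaults mirror the length asymmetry of the real benchmark: ~50 bp
#' positives carrying a GC-rich inverted-repeat stem, a loop and a poly-T
#' tail, versus 80 bp i.i.d. negatives.
#'
#' @param n_pos,n_neg Number of positive / negative sequences.
#' @param stem_len Stem arm length in bp.
#' @param loop_len Loop length in bp.
#' @param polyt_len Poly-T tail length in bp.
#' @param stem_gc_bias Probability that a stem base is G or C, in \[0, 1\].
#' @param pos_len,neg_len Total lengths of positives / negatives in bp.
#' @param seed Integer seed.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_pos = 400, n_neg = 400, stem_len = 9, loop_len = 5,
                       polyt_len = 7, stem_gc_bias = 0.9, pos_len = 50,
                       neg_len = 80, seed = 1) {
  cfg <- list(n_pos = n_pos, n_neg = n_neg, stem_len = stem_len,
              loop_len = loop_len, polyt_len = polyt_len,
              stem_gc_bias = stem_gc_bias, pos_len = pos_len,
              neg_len = neg_len, seed = seed)
  counts <- unlist(cfg[c("n_pos", "n_neg", "stem_len", "loop_len", "polyt_len",
                         "pos_len", "neg_len")])
  if (any(counts <= 0)) stop("all counts and lengths must be positive", call. = FALSE)
  if (stem_gc_bias < 0 || stem_gc_bias > 1) {
    stop("stem_gc_bias must lie in [0, 1]", call. = FALSE)
  }
  if (pos_len < 2 * stem_len + loop_len + polyt_len) {
    stop("pos_len must be at least 2*stem_len + loop_len + polyt_len = ",
         2 * stem_len + loop_len + polyt_len, call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Generate terminator-like positive sequences
#'
#' Each sequence embeds, at a random offset, a hairpin cassette:
#' a GC-biased stem arm, a random loop, the reverse complement of the stem,
#' then a poly-T tail — the sequence signature of intrinsic (rho-independent)
#' termination. Flanking bases are i.i.d. uniform.
#'
#' @param config A [sim_config()].
#' @return A sequence tibble with `label = "positive"`.
#' @examples
#' pos <- generate_terminators(sim_config(n_pos = 3, seed = 7))
#' all(grepl("TTTTTTT", pos$sequence))
#' @export
generate_terminators <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  core_len <- 2 * config$stem_len + config$loop_len + config$polyt_len
  seqs <- with_seed(config$seed, vapply(seq_len(config$n_pos), function(i) {
    gc <- stats::runif(config$stem_len) < config$stem_gc_bias
    stem <- ifelse(gc, sample(c("G", "C"), config$stem_len, replace = TRUE),
                   sample(c("A", "T"), config$stem_len, replace = TRUE))
    stem <- paste(stem, collapse = "")
    loop <- paste(sample(DNA_BASES, config$loop_len, replace = TRUE), collapse = "")
    core <- paste0(stem, loop, revcomp(stem), strrep("T", config$polyt_len))
    n_flank <- config$pos_len - core_len
    offset <- if (n_flank > 0) sample.int(n_flank + 1, 1) - 1 else 0
    left <- paste(sample(DNA_BASES, offset, replace = TRUE), collapse = "")
    right <- paste(sample(DNA_BASES, n_flank - offset, replace = TRUE),
                   collapse = "")
    paste0(left, core, right)
  }, character(1)))
  seq_dataset(sprintf("pos%d", seq_len(config$n_pos)), seqs,
              label = "positive", species = "synthetic")
}

#' Generate a full synthetic labelled dataset
#'
#' Positives from [generate_terminators()], negatives from
#' [generate_background()], in one table. This is the offline stand-in for a
#' real benchmark: it reproduces the hairpin + poly-T signal and the class
#' length asymmetry, not the genomic base composition of any organism.
#'
#' @param config A [sim_config()].
#' @return A sequence tibble with both classes.
#' @examples
#' d <- simulate_terminator_data(sim_config(n_pos = 5, n_neg = 5))
#' table(d$label)
#' @export
simulate_terminator_data <- function(config = sim_config()) {
  pos <- generate_terminators(config)
  neg <- generate_background(config$n_neg, config$neg_len,
                             seed = config$seed + 1L)
  dplyr::bind_rows(pos, neg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
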