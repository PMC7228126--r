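#' Pseudo K-tuple nucleotide composition configuration
#'
#' @param k K-tuple size, one of 4, 5, 6.
#' @param lambda Number of correlation tiers (>= 0); every encoded sequence
#'   must satisfy `nchar(sequence) - k >= lambda`.
#' @param w Weight of the pseudo components (>= 0); at `w = 0` the encoding
#'   collapses to the plain normalized k-tuple frequency vector.
#' @param mode `"parallel"` (type I: one tier per distance, properties
#'   averaged) or `"series"` (type II: one tier per distance and property).
#' @param props Dinucleotide property names used for correlations; defaults
#'   to the six helical parameters (rise, slide, shift, twist, roll, tilt).
#' @param series_correlation How a series-mode tier combines two positions:
#'   `"sqdiff"` (per-property squared difference, which vanishes on
#'   homopolymers) or `"product"`.
#' @return A list of class `"pseknc_config"`.
#' @export
pseknc_config <- function(k = 5, lambda = 5, w = 0.1,
                          mode = c("parallel", "series"),
                          props = PSEKNC_PROPS,
                          series_correlation = c("sqdiff", "product")) {
  mode <- match.arg(mode)
  series_correlation <- match.arg(series_correlation)
  if (!k %in% c(4, 5, 6)) stop("k must be 4, 5 or 6", call. = FALSE)
  if (lambda < 0 || w < 0) stop("lambda and w must be >= 0", call. = FALSE)
  structure(list(k = k, lambda = lambda, w = w, mode = mode, props = props,
                 series_correlation = series_correlation),
            class = "pseknc_config")
}

# property-profile matrix: one row per selected property, one column per
# dinucleotide position of the sequence
pseknc_profile <- function(seq, cfg, table) {
  P <- table$dinucleotide[cfg$props, , drop = FALSE]
  P[, seq_windows(seq, 2), drop = FALSE]
}

pseknc_one <- function(seq, cfg, table) {
  L <- nchar(seq)
  if (L - cfg$k < cfg$lambda || L < cfg$k + 1) {
    stop("sequence of length ", L, " too short for k = ", cfg$k,
         " with lambda = ", cfg$lambda, call. = FALSE)
  }
  f <- kmer_count_vector(seq, cfg$k)
  f <- f / sum(f)
  prof <- pseknc_profile(seq, cfg, table)   # Lambda x (L-1)
  n_din <- ncol(prof)
  if (cfg$mode == "parallel") {
    theta <- vapply(seq_len(cfg$lambda), function(j) {
      i <- seq_len(n_din - j)
      mean(colMeans((prof[, i, drop = FALSE] - prof[, i + j, drop = FALSE])^2))
    }, numeric(1))
  } else {
    theta <- as.vector(vapply(seq_len(cfg$lambda), function(j) {
      i <- seq_len(n_din - j)
      if (cfg$series_correlation == "sqdiff") {
        rowMeans((prof[, i, drop = FALSE] - prof[, i + j, drop = FALSE])^2)
      } else {
        rowMeans(prof[, i, drop = FALSE] * prof[, i + j, drop = FALSE])
      }
    }, numeric(length(cfg$props))))
  }
  if (cfg$lambda == 0) theta <- numeric(0)
  denom <- sum(f) + cfg$w * sum(theta)
  c(f / denom, cfg$w * theta / denom)
}

pseknc_names <- function(cfg) {
  tag <- if (cfg$mode == "parallel") "pse1" else "pse2"
  base <- paste0(tag, "_", cfg$k, "_", all_kmers(cfg$k))
  if (cfg$lambda == 0) return(base)
  pseudo <- if (cfg$mode == "parallel") {
    paste0(tag, "_", cfg$k, "_theta", seq_len(cfg$lambda))
  } else {
    as.vector(vapply(seq_len(cfg$lambda), function(j)
      paste0(tag, "_", cfg$k, "_theta", j, "_", cfg$props),
      character(length(cfg$props))))
  }
  c(base, pseudo)
}

#' Pseudo K-tuple nucleotide composition features
#'
#' Encodes each sequence as a probability vector combining normalized
#' k-tuple frequencies `f_u` with `lambda` pseudo components that summarize
#' physicochemical correlation between dinucleotides `j` positions apart.
#' In parallel mode (type I) the tier at distance j is
#' `theta_j = mean_i (1/Lambda) * sum_z (P_z(i) - P_z(i+j))^2` over the
#' `Lambda` selected properties; in series mode (type II) each (distance,
#' property) pair keeps its own tier. Components are normalized by
#' `sum(f) + w * sum(theta)`, so each vector sums to 1: length `4^k + lambda`
#' (parallel) or `4^k + Lambda * lambda` (series).
#'
#' @param data A sequence tibble.
#' @param config A [pseknc_config()].
#' @param table A [load_property_table()] result.
#' @return A tibble: `id` plus one numeric column per component.
#' @examples
#' d <- seq_dataset("s", "ACGTACGTACGT")
#' v <- pseknc(d, pseknc_config(k = 4, lambda = 2))
#' sum(v[, -1])  # 1
#' @export
pseknc <- function(data, config = pseknc_config(),
                   table = default_property_table()) {
  stopifnot(inherits(config, "pseknc_config"))
  vals <- t(vapply(data$sequence, pseknc_one, cfg = config, table = table,
                   FUN.VALUE = numeric(4^config$k +
                     config$lambda * if (config$mode == "series")
                       length(config$props) else 1),
                   USE.NAMES = FALSE))
  colnames(vals) <- pseknc_names(config)
  dplyr::bind_cols(tibble::tibble(id = data$id), tibble::as_tibble(vals))
}
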