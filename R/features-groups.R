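#' Assemble a combined feature matrix from named feature families
#'
#' Concatenates, per sample, any subset of the five encoder families in the
#' declared order:
#' \describe{
#'   \item{`kpwm(k)`}{one length-normalised PWM log-odds score per `k`
#'     (models supplied via `pwms` or trained on `data`'s positives).}
#'   \item{`basecontent`}{the five base-content statistics.}
#'   \item{`nucleotidepro`}{the `47 * l_max` per-position property features.}
#'   \item{`pseknc1(k)` / `pseknc2(k)`}{parallel / series pseudo k-tuple
#'     composition.}
#' }
#' Family names follow e.g. `"kpwm(1)"`, `"pseknc1(5)"`; bare `"pseknc1"`
#' uses `k = 5`. The combination `c("pseknc1(5)", "pseknc2(5)",
#' "nucleotidepro")` is the best-performing group for terminator
#' classification and is the package default elsewhere.
#'
#' @param data A sequence tibble.
#' @param families Character vector of family specifiers (see above).
#' @param lambda,w PseKNC tier count and weight, shared by both PseKNC
#'   families.
#' @param l_max Fixed width for `nucleotidepro`.
#' @param pwms Optional named list of fitted [build_pwm()] models, names
#'   `"1"`, `"6"`, ... If missing, models are trained on the positive
#'   records of `data` with the default pseudocount — only appropriate
#'   outside cross-validation; inside CV supply fold-trained models.
#' @param table A [load_property_table()] result.
#' @param series_correlation Passed to [pseknc_config()] for `pseknc2`.
#' @return A tibble of class `"pseterm_features"`: `id` column plus numeric
#'   feature columns; attribute `family` tags each feature column with its
#'   family.
#' @examples
#' d <- simulate_terminator_data(sim_config(n_pos = 4, n_neg = 4))
#' X <- extract_group(d, c("basecontent", "kpwm(1)"))
#' attr(X, "family")
#' @export
extract_group <- function(data, families = c("pseknc1(5)", "pseknc2(5)",
                                             "nucleotidepro"),
                          lambda = 5, w = 0.1, l_max = 82, pwms = NULL,
                          table = default_property_table(),
                          series_correlation = "sqdiff") {
  parse_fam <- function(f) {
    m <- regmatches(f, regexec("^([a-z]+[12]?)(?:\\((\\d+)\\))?$", f))[[1]]
    if (length(m) == 0) stop("cannot parse family '", f, "'", call. = FALSE)
    list(name = m[2], k = if (nzchar(m[3])) as.integer(m[3]) else NA_integer_)
  }
  blocks <- list()
  fam_tags <- character(0)
  for (f in families) {
    pf <- parse_fam(f)
    block <- switch(pf$name,
      basecontent = {
        bc <- base_content(data)
        bc[, c("atContent", "gcContent", "atgcRatio", "gcSkew", "atSkew")]
      },
      kpwm = {
        k <- if (is.na(pf$k)) 1L else pf$k
        pwm <- if (!is.null(pwms) && !is.null(pwms[[as.character(k)]])) {
          pwms[[as.character(k)]]
        } else {
          pos <- data[data$label == "positive", , drop = FALSE]
          if (nrow(pos) == 0) {
            stop("kpwm needs fitted models via `pwms` or positive records in `data`",
                 call. = FALSE)
          }
          build_pwm(pos, k = k)
        }
        tibble::tibble(!!paste0("kpwm_", k) := pwm_score(data, pwm))
      },
      nucleotidepro = nucleotidepro(data, l_max = l_max, table = table)[, -1],
      pseknc1 = pseknc(data, pseknc_config(k = if (is.na(pf$k)) 5L else pf$k,
                                           lambda = lambda, w = w,
                                           mode = "parallel"),
                       table = table)[, -1],
      pseknc2 = pseknc(data, pseknc_config(k = if (is.na(pf$k)) 5L else pf$k,
                                           lambda = lambda, w = w,
                                           mode = "series",
                                           series_correlation = series_correlation),
                       table = table)[, -1],
      stop("unknown feature family '", pf$name, "'", call. = FALSE)
    )
    fam <- sub("\\(.*$", "", f)
    fam_tags <- c(fam_tags, rep(fam, ncol(block)))
    blocks[[length(blocks) + 1]] <- block
  }
  out <- dplyr::bind_cols(tibble::tibble(id = data$id), blocks)
  structure(out, family = stats::setNames(fam_tags, names(out)[-1]),
            class = c("pseterm_features", class(out)))
}

#' Feature columns of a feature tibble as a numeric matrix
#'
#' @param X A feature tibble from [extract_group()] (or any tibble whose
#'   first column is `id`).
#' @return Numeric matrix with `id` as rownames.
#' @export
features_as_matrix <- function(X) {
  m <- as.matrix(X[, setdiff(names(X), "id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- X$id
  m
}
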