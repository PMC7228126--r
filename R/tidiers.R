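#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a feature ranking
#'
#' @param x A `"pseterm_ranking"`.
#' @param ... Unused.
#' @return A tibble `feature`, `score`, `rank`, ordered best first.
#' @method tidy pseterm_ranking
#' @export
tidy.pseterm_ranking <- function(x, ...) {
  tibble::tibble(feature = names(x$scores)[x$order],
                 score = unname(x$scores[x$order]),
                 rank = seq_along(x$order))
}

#' Tidy an incremental-selection result
#'
#' @param x A `"pseterm_ifs"`.
#' @param ... Unused.
#' @return A tibble `n_features`, `accuracy` — the IFS curve.
#' @method tidy pseterm_ifs
#' @export
tidy.pseterm_ifs <- function(x, ...) {
  tibble::tibble(n_features = x$sizes, accuracy = x$curve)
}

#' @rdname tidy.pseterm_ifs
#' @method glance pseterm_ifs
#' @export
glance.pseterm_ifs <- function(x, ...) {
  tibble::tibble(best_size = x$best_size, best_accuracy = max(x$curve),
                 method = x$method, prefixes_evaluated = length(x$sizes))
}

#' Tidy a cross-validation report
#'
#' @param x A `"pseterm_cv"`.
#' @param ... Unused.
#' @return Long tibble `metric`, `estimate`, `std.error`.
#' @method tidy pseterm_cv
#' @export
tidy.pseterm_cv <- function(x, ...) x$summary

#' @rdname tidy.pseterm_cv
#' @method glance pseterm_cv
#' @export
glance.pseterm_cv <- function(x, ...) {
  wide <- stats::setNames(as.list(x$summary$estimate), x$summary$metric)
  tibble::as_tibble(c(wide, list(folds = x$cv$folds, repeats = x$cv$repeats,
                                 model = x$spec$algorithm)))
}

#' Tidy a ROC result
#'
#' @param x A `"pseterm_roc"`.
#' @param ... Unused.
#' @return The curve tibble (`threshold`, `tpr`, `fpr`).
#' @method tidy pseterm_roc
#' @export
tidy.pseterm_roc <- function(x, ...) x$curve

#' @rdname tidy.pseterm_roc
#' @method glance pseterm_roc
#' @export
glance.pseterm_roc <- function(x, ...) tibble::tibble(auc = x$auc)

#' Summarize a fitted pipeline
#'
#' @param x A `"pseterm_pipeline"`.
#' @param ... Unused.
#' @return One-row tibble with the pipeline's structural summary.
#' @method glance pseterm_pipeline
#' @export
glance.pseterm_pipeline <- function(x, ...) {
  tibble::tibble(
    families = paste(x$config$families, collapse = "+"),
    selection = x$config$selection,
    ifs = x$config$ifs,
    n_selected = length(x$selected),
    model = x$config$model$algorithm,
    seed = x$config$seed
  )
}
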