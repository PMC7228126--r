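#' Cross-validation settings
#'
#' @param folds Number of folds (>= 2, default 5).
#' @param repeats Number of independent repetitions with fresh random
#'   partitions (default 5; raise towards 100 for publication-grade
#'   standard errors, at proportional cost).
#' @param seed Integer seed; the whole CV is a pure function of it.
#' @param stratified Preserve class proportions per fold (default `TRUE`).
#' @return A list of class `"cv_config"`.
#' @export
cv_config <- function(folds = 5, repeats = 5, seed = 1, stratified = TRUE) {
  stopifnot(folds >= 2, repeats >= 1)
  structure(list(folds = folds, repeats = repeats, seed = as.integer(seed),
                 stratified = stratified),
            class = "cv_config")
}

# fold assignment vector, stratified or plain, deterministic in seed
make_folds <- function(y, folds, stratified, seed) {
  n <- length(y)
  assign_block <- function(idx) {
    with_seed(seed + 7 * length(idx), sample(rep_len(seq_len(folds), length(idx))))
  }
  out <- integer(n)
  if (stratified) {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      out[idx] <- assign_block(idx)
    }
  } else {
    out <- assign_block(seq_len(n))
  }
  out
}

# one repeat: pooled out-of-fold predictions
cv_one_repeat <- function(spec, X, y, folds_id, seed, select = NULL,
                          refit_features = NULL) {
  scores <- rep(NA_real_, length(y))
  skipped <- 0L
  for (f in sort(unique(folds_id))) {
    te <- which(folds_id == f); tr <- which(folds_id != f)
    if (length(unique(y[tr])) < 2 || length(unique(y[te])) < 2) {
      skipped <- skipped + 1L
      warning("fold ", f, " missing a class; skipped", call. = FALSE)
      next
    }
    if (!is.null(refit_features)) {
      XX <- refit_features(tr, te)   # e.g. per-fold PWM features
      Xtr <- XX$train; Xte <- XX$test
    } else {
      Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    }
    if (!is.null(select)) {
      keep <- select(Xtr, y[tr])     # fitted on the training fold only
      Xtr <- Xtr[, keep, drop = FALSE]; Xte <- Xte[, keep, drop = FALSE]
    }
    if (spec$needs_scaling) {
      sc <- minmax_fit(Xtr)
      Xtr <- minmax_apply(sc, Xtr); Xte <- minmax_apply(sc, Xte)
    }
    fit <- fit_model(spec, Xtr, y[tr], seed = seed + f)
    scores[te] <- predict_scores(fit, Xte)
  }
  list(scores = scores, skipped = skipped)
}

#' Repeated stratified k-fold cross-validation
#'
#' The dataset is split into `folds` random parts; each serves once as the
#' test fold while the rest train. Everything that learns from data —
#' scaler, optional feature selection, optionally the feature encoding
#' itself — is refitted inside every fold, so test folds never leak into
#' fitting. Per repeat, out-of-fold predictions are pooled into one
#' confusion matrix; the report gives means and standard errors over
#' repeats.
#'
#' @param spec A [model_spec()].
#' @param X Feature tibble or matrix.
#' @param y Labels.
#' @param cv A [cv_config()].
#' @param select Optional `function(X_train, y_train)` returning the
#'   feature columns to keep, refitted per fold (see
#'   [selector_fscore_ifs()]).
#' @param refit_features Optional `function(train_idx, test_idx)` returning
#'   `list(train=, test=)` matrices, for encodings that must be refitted per
#'   fold (PWM features).
#' @param threshold Score threshold for calling a positive (default 0.5).
#' @return An object of class `"pseterm_cv"`: per-repeat metrics and a
#'   mean ± standard-error summary. `tidy()` and `glance()` methods apply.
#' @export
repeated_cv <- function(spec, X, y, cv = cv_config(), select = NULL,
                        refit_features = NULL, threshold = 0.5) {
  m <- if (is.data.frame(X)) features_as_matrix(X) else X
  y <- as_binary_labels(y)
  reps <- lapply(seq_len(cv$repeats), function(r) {
    folds_id <- make_folds(y, cv$folds, cv$stratified, cv$seed + 1000L * r)
    res <- cv_one_repeat(spec, m, y, folds_id, seed = cv$seed + r,
                         select = select, refit_features = refit_features)
    ok <- !is.na(res$scores)
    mr <- metrics_report(confusion_counts(y[ok], res$scores[ok] >= threshold))
    mr$auc <- roc_auc(y[ok], res$scores[ok])$auc
    mr$skipped_folds <- res$skipped
    mr
  })
  per_repeat <- dplyr::bind_rows(reps, .id = "repeat_id")
  new_cv_report(per_repeat, cv, spec)
}

new_cv_report <- function(per_repeat, cv, spec) {
  mets <- c("sn", "sp", "acc", "mcc", "auc")
  summary <- tibble::tibble(
    metric = mets,
    estimate = vapply(mets, function(k) mean(per_repeat[[k]]), numeric(1)),
    std.error = vapply(mets, function(k) {
      if (nrow(per_repeat) > 1) stats::sd(per_repeat[[k]]) / sqrt(nrow(per_repeat))
      else 0
    }, numeric(1))
  )
  structure(list(per_repeat = per_repeat, summary = summary, cv = cv,
                 spec = spec),
            class = "pseterm_cv")
}

#' @export
print.pseterm_cv <- function(x, ...) {
  cat("<pseterm_cv> ", x$cv$repeats, " x ", x$cv$folds, "-fold CV, model ",
      x$spec$algorithm, "\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-4s %.4f ± %.4f\n", s$metric[i], s$estimate[i],
                s$std.error[i]))
  }
  invisible(x)
}

#' Fast CV accuracy evaluator for incremental feature selection
#'
#' Returns a `function(X, y, seed)` giving mean out-of-fold accuracy of a
#' gradient-boosted tree ensemble — the default engine the IFS curve is
#' traced with. Deliberately lighter than the final model (fewer rounds)
#' since IFS runs it once per prefix.
#'
#' @param folds,repeats CV shape (default 5 x 5).
#' @param nrounds,max_depth,learning_rate Booster settings.
#' @return A function suitable for [incremental_selection()]'s `evaluator`.
#' @export
cv_evaluator <- function(folds = 5, repeats = 5, nrounds = 30, max_depth = 4,
                         learning_rate = 0.3) {
  spec <- model_spec("xgb", params = list(n_estimators = nrounds,
                                          max_depth = max_depth,
                                          learning_rate = learning_rate))
  function(X, y, seed) {
    accs <- vapply(seq_len(repeats), function(r) {
      folds_id <- make_folds(y, folds, TRUE, seed + 1000L * r)
      res <- cv_one_repeat(spec, X, y, folds_id, seed = seed + r)
      ok <- !is.na(res$scores)
      mean((res$scores[ok] >= 0.5) == y[ok])
    }, numeric(1))
    mean(accs)
  }
}

#' Per-fold F-score + IFS feature selector
#'
#' A selection hook for [repeated_cv()]: inside each fold it ranks the
#' training-fold features by F-score and keeps the IFS-optimal prefix.
#'
#' @param stride,max_features,evaluator Passed to [incremental_selection()].
#' @return A `function(X_train, y_train)` returning column indices.
#' @export
selector_fscore_ifs <- function(stride = "auto", max_features = NULL,
                                evaluator = cv_evaluator(folds = 3, repeats = 1)) {
  function(X_train, y_train) {
    rk <- f_scores(X_train, y_train)
    ifs <- incremental_selection(X_train, y_train, rk, evaluator = evaluator,
                                 stride = stride, max_features = max_features)
    rk$order[seq_len(ifs$best_size)]
  }
}

#' Exhaustive grid search
#'
#' Evaluates every point of the Cartesian hyperparameter grid by repeated
#' CV and returns the best by mean accuracy; ties prefer fewer
#' `n_estimators`, then smaller `learning_rate`, then declaration order.
#'
#' @param spec A [model_spec()]; its `grid` field defines the search space.
#' @param X,y Features and labels.
#' @param cv A [cv_config()] (default 5 x 5-fold; raise `repeats` towards
#'   100 for the full protocol).
#' @return A list: `best_params`, `best_report` (a `"pseterm_cv"`), and
#'   `results` (one row per grid point with mean accuracy).
#' @export
grid_search <- function(spec, X, y, cv = cv_config()) {
  if (length(spec$grid) == 0) {
    rep0 <- repeated_cv(spec, X, y, cv)
    return(list(best_params = list(), best_report = rep0,
                results = tibble::tibble(acc = rep0$summary$estimate[
                  rep0$summary$metric == "acc"])))
  }
  pts <- expand.grid(spec$grid, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  reports <- vector("list", nrow(pts))
  accs <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    sp <- spec
    sp$params <- utils::modifyList(spec$params, as.list(pts[i, , drop = FALSE]))
    reports[[i]] <- repeated_cv(sp, X, y, cv)
    accs[i] <- reports[[i]]$summary$estimate[
      reports[[i]]$summary$metric == "acc"]
  }
  ord <- order(-accs,
               if ("n_estimators" %in% names(pts)) pts$n_estimators else
                 rep(0, nrow(pts)),
               if ("learning_rate" %in% names(pts)) pts$learning_rate else
                 rep(0, nrow(pts)),
               seq_len(nrow(pts)))
  best <- ord[1]
  list(best_params = as.list(pts[best, , drop = FALSE]),
       best_report = reports[[best]],
       results = tibble::as_tibble(cbind(pts, acc = accs)))
}
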