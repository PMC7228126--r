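#' Configure the end-to-end terminator classification pipeline
#'
#' Bundles every stage: feature group, PseKNC settings, selection method,
#' IFS controls and the final model. The defaults reproduce the package's
#' reference pipeline: parallel + series Pse5NC with the 47-property
#' per-position encoding, F-score ranking with IFS, and extreme
#' gradient-boosted trees.
#'
#' @param families Feature families as in [extract_group()].
#' @param lambda,w,l_max,series_correlation Encoder settings
#'   (see [pseknc_config()], [nucleotidepro()]).
#' @param selection `"fscore"`, `"binomial"` or `"none"`.
#' @param ifs Run incremental feature selection after ranking (default
#'   `TRUE`; with `FALSE` and selection != "none" the ranking is kept whole).
#' @param ifs_stride,ifs_max_features Prefix controls for
#'   [incremental_selection()]; `"auto"` evaluates ~20 prefixes. The default
#'   prefix cap of 1024 keeps IFS over the multi-thousand-column groups
#'   tractable; set `NULL` to trace the curve to the full feature count.
#' @param ifs_folds,ifs_repeats,ifs_nrounds The IFS evaluator's internal CV
#'   shape and booster size.
#' @param model A [model_spec()].
#' @param threshold Positive-call threshold on the score (default 0.5).
#' @param seed Integer seed governing every stochastic stage.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(families = c("pseknc1(5)", "pseknc2(5)",
                                         "nucleotidepro"),
                            lambda = 5, w = 0.1, l_max = 82,
                            series_correlation = "sqdiff",
                            selection = c("fscore", "binomial", "none"),
                            ifs = TRUE, ifs_stride = "auto",
                            ifs_max_features = 1024,
                            ifs_folds = 3, ifs_repeats = 1, ifs_nrounds = 30,
                            model = model_spec("xgb"), threshold = 0.5,
                            seed = 1) {
  selection <- match.arg(selection)
  stopifnot(inherits(model, "model_spec"))
  structure(list(families = families, lambda = lambda, w = w, l_max = l_max,
                 series_correlation = series_correlation,
                 selection = selection, ifs = ifs, ifs_stride = ifs_stride,
                 ifs_max_features = ifs_max_features, ifs_folds = ifs_folds,
                 ifs_repeats = ifs_repeats, ifs_nrounds = ifs_nrounds,
                 model = model, threshold = threshold, seed = as.integer(seed)),
            class = "pipeline_config")
}

pipeline_pwm_ks <- function(families) {
  m <- regmatches(families, regexec("^kpwm\\((\\d+)\\)$", families))
  ks <- vapply(m, function(x) if (length(x)) as.integer(x[2]) else NA_integer_,
               integer(1))
  ks[families == "kpwm"] <- 1L
  ks[!is.na(ks)]
}

pipeline_features <- function(data, config, pwms, table) {
  extract_group(data, config$families, lambda = config$lambda, w = config$w,
                l_max = config$l_max, pwms = pwms, table = table,
                series_correlation = config$series_correlation)
}

#' Fit the full pipeline on labelled training sequences
#'
#' Trains, in order and on the training data only: per-k PWM profiles on
#' the positive class (when the group includes `kpwm`), the feature
#' encoders, the feature ranking (on unscaled features), IFS, the min-max
#' scaler (when the model wants one) and the classifier.
#'
#' @param train A labelled sequence tibble with both classes.
#' @param config A [pipeline_config()].
#' @param table A [load_property_table()] result.
#' @return An object of class `"pseterm_pipeline"`.
#' @export
fit_pipeline <- function(train, config = pipeline_config(),
                         table = default_property_table()) {
  stopifnot(inherits(config, "pipeline_config"))
  y <- as_binary_labels(train$label)
  if (!any(y) || all(y)) stop("training data needs both classes", call. = FALSE)
  ks <- pipeline_pwm_ks(config$families)
  pwms <- if (length(ks)) {
    pos <- train[y, , drop = FALSE]
    stats::setNames(lapply(ks, function(k) build_pwm(pos, k = k)),
                    as.character(ks))
  }
  X <- pipeline_features(train, config, pwms, table)
  m <- features_as_matrix(X)
  ranking <- switch(config$selection,
                    fscore = f_scores(m, y),
                    binomial = binomial_confidence(m, y),
                    none = NULL)
  ifs <- NULL
  selected <- colnames(m)
  if (!is.null(ranking)) {
    if (config$ifs) {
      ev <- cv_evaluator(folds = config$ifs_folds, repeats = config$ifs_repeats,
                         nrounds = config$ifs_nrounds)
      ifs <- incremental_selection(m, y, ranking, evaluator = ev,
                                   stride = config$ifs_stride,
                                   max_features = config$ifs_max_features,
                                   seed = config$seed)
      selected <- ifs$best_features
    } else {
      selected <- names(ranking$scores)[ranking$order]
    }
  }
  m_sel <- m[, selected, drop = FALSE]
  scaler <- NULL
  if (config$model$needs_scaling) {
    scaler <- minmax_fit(m_sel)
    m_sel <- minmax_apply(scaler, m_sel)
  }
  fit <- fit_model(config$model, m_sel, y, seed = config$seed)
  structure(list(config = config, pwms = pwms, ranking = ranking, ifs = ifs,
                 selected = selected, scaler = scaler, fit = fit,
                 version = "pseterm-pipeline-1"),
            class = "pseterm_pipeline")
}

#' @export
print.pseterm_pipeline <- function(x, ...) {
  cat("<pseterm_pipeline> ", paste(x$config$families, collapse = " + "),
      " -> ", x$config$selection,
      if (x$config$ifs && x$config$selection != "none") "+IFS",
      " -> ", x$config$model$algorithm, "; ",
      length(x$selected), " features retained\n", sep = "")
  invisible(x)
}

#' Predict terminator labels for new sequences
#'
#' @param object A fitted [fit_pipeline()] result.
#' @param newdata A sequence tibble.
#' @param table A [load_property_table()] result (must match the one used
#'   at fit time).
#' @param ... Unused.
#' @return A tibble `id`, `score` (positive-class probability), `label`
#'   (`"positive"`/`"negative"` by the configured threshold).
#' @export
predict.pseterm_pipeline <- function(object, newdata,
                                     table = default_property_table(), ...) {
  too_long <- nchar(newdata$sequence) > object$config$l_max
  if (any(too_long)) {
    stop("sequence '", newdata$id[which(too_long)[1]],
         "' exceeds the fitted l_max = ", object$config$l_max, call. = FALSE)
  }
  X <- pipeline_features(newdata, object$config, object$pwms, table)
  m <- features_as_matrix(X)[, object$selected, drop = FALSE]
  if (!is.null(object$scaler)) m <- minmax_apply(object$scaler, m)
  score <- predict_scores(object$fit, m)
  tibble::tibble(id = newdata$id, score = as.numeric(score),
                 label = ifelse(score >= object$config$threshold,
                                "positive", "negative"))
}

#' Evaluate a fitted pipeline on labelled sequences
#'
#' @param pipeline A fitted [fit_pipeline()] result.
#' @param data A labelled sequence tibble.
#' @param table Property table.
#' @return A one-row tibble `sn`, `sp`, `acc`, `mcc`, `auc`.
#' @export
evaluate_pipeline <- function(pipeline, data,
                              table = default_property_table()) {
  pred <- stats::predict(pipeline, data, table = table)
  y <- as_binary_labels(data$label)
  out <- metrics_report(confusion_counts(y, pred$label == "positive"))
  out$auc <- roc_auc(y, pred$score)$auc
  out
}

#' Train on one set, predict (and score) another
#'
#' Convenience wrapper for the benchmark / independent-set protocol: fits
#' the whole pipeline on `train`, freezes it, applies it to `test`.
#'
#' @param train Labelled sequence tibble.
#' @param test Sequence tibble; metrics are computed when it carries
#'   known labels.
#' @param config A [pipeline_config()].
#' @param table Property table.
#' @return A list: `pipeline`, `predictions` (tibble id/score/label) and
#'   `metrics` (`NULL` when test labels are unknown).
#' @export
train_predict <- function(train, test, config = pipeline_config(),
                          table = default_property_table()) {
  pipeline <- fit_pipeline(train, config, table = table)
  predictions <- stats::predict(pipeline, test, table = table)
  mets <- if (all(test$label %in% c("positive", "negative"))) {
    y <- as_binary_labels(test$label)
    out <- metrics_report(confusion_counts(y, predictions$label == "positive"))
    if (length(unique(y)) == 2) out$auc <- roc_auc(y, predictions$score)$auc
    out
  }
  list(pipeline = pipeline, predictions = predictions, metrics = mets)
}

#' Sequence-level repeated cross-validation of a pipeline
#'
#' Runs [repeated_cv()] where every fold refits the fold-dependent stages:
#' ranking, IFS and scaler always; the PWM profiles and PWM-score features
#' too when the group includes `kpwm` (other encodings are per-sequence and
#' fold-independent, so they are computed once).
#'
#' @param data Labelled sequence tibble.
#' @param config A [pipeline_config()].
#' @param cv A [cv_config()].
#' @param table Property table.
#' @return A `"pseterm_cv"` report.
#' @export
pipeline_cv <- function(data, config = pipeline_config(), cv = cv_config(),
                        table = default_property_table()) {
  y <- as_binary_labels(data$label)
  ks <- pipeline_pwm_ks(config$families)
  select <- if (config$selection != "none") {
    ev <- cv_evaluator(folds = config$ifs_folds, repeats = config$ifs_repeats,
                       nrounds = config$ifs_nrounds)
    rank_fun <- if (config$selection == "fscore") f_scores else
      binomial_confidence
    function(X_train, y_train) {
      rk <- rank_fun(X_train, y_train)
      if (config$ifs) {
        ifs <- incremental_selection(X_train, y_train, rk, evaluator = ev,
                                     stride = config$ifs_stride,
                                     max_features = config$ifs_max_features,
                                     seed = config$seed)
        rk$order[seq_len(ifs$best_size)]
      } else {
        rk$order
      }
    }
  }
  if (length(ks) == 0) {
    X <- pipeline_features(data, config, NULL, table)
    repeated_cv(config$model, X, y, cv, select = select,
                threshold = config$threshold)
  } else {
    refit <- function(tr, te) {
      pos <- data[tr, , drop = FALSE]
      pos <- pos[as_binary_labels(pos$label), , drop = FALSE]
      pwms <- stats::setNames(lapply(ks, function(k) build_pwm(pos, k = k)),
                              as.character(ks))
      Xtr <- pipeline_features(data[tr, , drop = FALSE], config, pwms, table)
      Xte <- pipeline_features(data[te, , drop = FALSE], config, pwms, table)
      list(train = features_as_matrix(Xtr), test = features_as_matrix(Xte))
    }
    repeated_cv(config$model, matrix(0, nrow(data), 0), y, cv,
                select = select, refit_features = refit,
                threshold = config$threshold)
  }
}

#' Save / load a fitted pipeline
#'
#' Serializes the fitted pipeline to a single file. Booster handles are
#' converted to raw bytes, so the file is self-contained and reloads with
#' bitwise-identical predictions across sessions (format
#' `pseterm-pipeline-1`, stable within minor versions).
#'
#' @param pipeline A fitted [fit_pipeline()] result.
#' @param path File to write / read.
#' @return `save_pipeline` returns `path` invisibly; `load_pipeline`
#'   returns the pipeline.
#' @export
save_pipeline <- function(pipeline, path) {
  stopifnot(inherits(pipeline, "pseterm_pipeline"))
  obj <- pipeline
  if (inherits(obj$fit$fit, "xgb.Booster")) {
    obj$fit$fit <- xgboost::xgb.save.raw(obj$fit$fit)
    obj$fit$serialized <- "xgb.raw"
  }
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_pipeline
#' @export
load_pipeline <- function(path) {
  obj <- readRDS(path)
  if (identical(obj$fit$serialized, "xgb.raw")) {
    obj$fit$fit <- xgboost::xgb.load.raw(obj$fit$fit)
    obj$fit$serialized <- NULL
  }
  obj
}
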