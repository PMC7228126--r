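ALGORITHMS <- c("svc", "naive_bayes", "logistic", "decision_tree", "mlp",
                "knn", "bagging", "adaboost", "gbm", "xgb")
MARGIN_BASES <- c("svc", "logistic", "knn", "mlp")

#' Declare a classifier
#'
#' The model zoo: six single models (support-vector classifier, naive
#' Bayes, logistic regression, decision tree, multi-layer perceptron,
#' k-nearest neighbour) and the ensembles bagging and AdaBoost around a
#' choice of base learner, plus gradient-boosted trees (`"gbm"`) and
#' extreme gradient boosting (`"xgb"`, the default model of the package).
#' Min-max scaling is applied automatically exactly to the margin/distance
#' learners (SVC, logistic, KNN, MLP and ensembles over them); tree and
#' probability models are scale-invariant and skip it.
#'
#' Hyperparameter names follow the conventional grids (see
#' [default_grid()]): `c`/`g` for the SVC, `alpha` (weight decay) for the
#' MLP, `min_sample_split`/`max_depth` for trees, `n_estimators` and
#' `learning_rate` for the ensembles. Parameters without an equivalent in
#' the R backend (e.g. the logistic `solver`) are accepted and ignored.
#'
#' @param algorithm One of `r paste0('"', ALGORITHMS, '"', collapse = ", ")`.
#' @param base Base learner for `"bagging"`/`"adaboost"`: `"decision_tree"`
#'   (default), `"svc"`, `"logistic"` or `"naive_bayes"`.
#' @param params Named list of hyperparameters.
#' @param grid Named list of value vectors for [grid_search()]; defaults to
#'   [default_grid()].
#' @return A list of class `"model_spec"`.
#' @examples
#' model_spec("xgb", params = list(n_estimators = 200))
#' model_spec("adaboost", base = "svc")
#' @export
model_spec <- function(algorithm = "xgb", base = NULL, params = list(),
                       grid = NULL) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  if (algorithm %in% c("bagging", "adaboost")) {
    base <- match.arg(base %||% "decision_tree",
                      c("decision_tree", "svc", "logistic", "naive_bayes"))
  } else if (!is.null(base)) {
    stop("`base` only applies to bagging/adaboost", call. = FALSE)
  }
  needs_scaling <- algorithm %in% MARGIN_BASES ||
    (!is.null(base) && base %in% MARGIN_BASES)
  structure(list(algorithm = algorithm, base = base, params = params,
                 grid = grid %||% default_grid(algorithm),
                 needs_scaling = needs_scaling),
            class = "model_spec")
}

#' Default hyperparameter grids
#'
#' The conventional search ranges per model: SVC cost and kernel width on
#' log2 grids, logistic regularization strengths, MLP weight decay, tree
#' split controls, and `n_estimators` in 10..1000 by 50 with
#' `learning_rate` in 0.1..1 by 0.1 for the boosted/bagged ensembles.
#'
#' @param algorithm Algorithm name as in [model_spec()].
#' @return Named list of value vectors (empty list when nothing is tuned).
#' @examples
#' length(default_grid("bagging")$n_estimators)  # 20 points
#' @export
default_grid <- function(algorithm) {
  switch(algorithm,
    svc = list(c = 2^seq(-5, 15, by = 2), g = 2^seq(-15, -5, by = 1)),
    logistic = list(c = seq(0.1, 1, by = 0.1),
                    solver = c("newton-cg", "lbfgs", "liblinear", "sag")),
    mlp = list(alpha = c(0.001, 0.01, 0.1, 0.5, 1, 1.5)),
    decision_tree = list(min_sample_split = seq(2, 30, by = 2),
                         max_depth = seq(1, 10)),
    bagging = list(n_estimators = seq(10, 1000, by = 50)),
    adaboost = list(n_estimators = seq(10, 1000, by = 50),
                    learning_rate = seq(0.1, 1, by = 0.1)),
    gbm = list(learning_rate = seq(0.1, 1, by = 0.1),
               n_estimators = seq(10, 1000, by = 50),
               max_depth = seq(1, 10)),
    xgb = list(n_estimators = seq(10, 1000, by = 50),
               learning_rate = seq(0.1, 1, by = 0.1)),
    list()
  )
}

pget <- function(params, name, default) params[[name]] %||% default

fit_xgb_like <- function(X, y, params, seed, gbm_style = FALSE) {
  pars <- list(objective = "binary:logistic",
               eta = pget(params, "learning_rate", if (gbm_style) 0.1 else 0.3),
               max_depth = pget(params, "max_depth", if (gbm_style) 3L else 4L),
               nthread = 1, seed = as.integer(seed) %% .Machine$integer.max)
  if (gbm_style) {
    # classic gradient boosting: no shrinkage-side regularisation terms
    pars$lambda <- 0; pars$alpha <- 0
  }
  dtrain <- xgboost::xgb.DMatrix(X, label = as.numeric(y))
  xgboost::xgb.train(params = pars, data = dtrain,
                     nrounds = pget(params, "n_estimators", 100L),
                     verbose = 0)
}

fit_base <- function(algorithm, X, y, params, seed, weights = NULL) {
  yf <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  switch(algorithm,
    svc = e1071::svm(X, yf, cost = pget(params, "c", 1),
                     gamma = pget(params, "g", 1 / ncol(X)),
                     kernel = "radial", probability = TRUE),
    naive_bayes = e1071::naiveBayes(as.data.frame(X), yf),
    logistic = {
      fit <- suppressWarnings(stats::glm.fit(cbind(1, X), as.numeric(y),
                                             weights = weights,
                                             family = stats::binomial()))
      list(coef = ifelse(is.na(fit$coefficients), 0, fit$coefficients))
    },
    decision_tree = {
      df <- data.frame(.y = yf, X, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "class", weights = weights,
                   control = rpart::rpart.control(
                     minsplit = pget(params, "min_sample_split", 20L),
                     maxdepth = pget(params, "max_depth", 30L),
                     cp = pget(params, "cp", 0.01), xval = 0))
    },
    mlp = with_seed(seed, nnet::nnet(X, as.numeric(y),
                                     size = pget(params, "size", 8L),
                                     decay = pget(params, "alpha", 0.01),
                                     maxit = pget(params, "maxit", 200L),
                                     entropy = TRUE, trace = FALSE,
                                     MaxNWts = 100000)),
    knn = list(X = X, y = yf, k = pget(params, "k", 5L)),
    stop("no base fitter for '", algorithm, "'", call. = FALSE)
  )
}

score_base <- function(algorithm, fit, X) {
  switch(algorithm,
    svc = {
      pr <- stats::predict(fit, X, probability = TRUE)
      attr(pr, "probabilities")[, "pos"]
    },
    naive_bayes = stats::predict(fit, as.data.frame(X), type = "raw")[, "pos"],
    logistic = as.vector(stats::plogis(cbind(1, X) %*% fit$coef)),
    decision_tree = stats::predict(fit, data.frame(X, check.names = FALSE),
                                   type = "prob")[, "pos"],
    mlp = as.vector(stats::predict(fit, X)),
    knn = {
      pr <- class::knn(fit$X, X, fit$y, k = fit$k, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "pos", p, 1 - p)
    },
    stop("no base scorer for '", algorithm, "'", call. = FALSE)
  )
}

#' Fit a declared model
#'
#' @param spec A [model_spec()].
#' @param X Numeric feature matrix (training rows). Scale beforehand when
#'   `spec$needs_scaling` (the pipeline and CV drivers do this for you).
#' @param y Labels (logical or `"positive"`/`"negative"`).
#' @param seed Integer seed for the stochastic learners.
#' @return An object of class `"pseterm_fit"`.
#' @export
fit_model <- function(spec, X, y, seed = 1) {
  stopifnot(inherits(spec, "model_spec"))
  y <- as_binary_labels(y)
  p <- spec$params
  fit <- switch(spec$algorithm,
    xgb = fit_xgb_like(X, y, p, seed),
    gbm = fit_xgb_like(X, y, p, seed, gbm_style = TRUE),
    bagging = {
      B <- pget(p, "n_estimators", 25L)
      with_seed(seed, lapply(seq_len(B), function(b) {
        idx <- sample.int(nrow(X), replace = TRUE)
        if (length(unique(y[idx])) < 2) idx <- seq_len(nrow(X))
        fit_base(spec$base, X[idx, , drop = FALSE], y[idx], p, seed + b)
      }))
    },
    adaboost = {
      B <- pget(p, "n_estimators", 25L)
      lr <- pget(p, "learning_rate", 1)
      w <- rep(1 / nrow(X), nrow(X))
      members <- list()
      with_seed(seed, for (b in seq_len(B)) {
        # weighted bootstrap: base learners need not support case weights
        idx <- sample.int(nrow(X), replace = TRUE, prob = w)
        if (length(unique(y[idx])) < 2) idx <- seq_len(nrow(X))
        fb <- fit_base(spec$base, X[idx, , drop = FALSE], y[idx], p, seed + b)
        pred <- score_base(spec$base, fb, X) > 0.5
        err <- sum(w * (pred != y))
        if (err >= 0.5) break
        alpha <- lr * 0.5 * log((1 - err) / max(err, 1e-10))
        members[[length(members) + 1]] <- list(fit = fb, alpha = alpha)
        w <- w * exp(alpha * ifelse(pred != y, 1, -1))
        w <- w / sum(w)
        if (err < 1e-10) break
      })
      members
    },
    fit_base(spec$algorithm, X, y, p, seed)
  )
  structure(list(spec = spec, fit = fit, features = colnames(X), seed = seed),
            class = "pseterm_fit")
}

#' Positive-class scores from a fitted model
#'
#' @param fit A [fit_model()] result.
#' @param X Feature matrix with the same columns the model was fitted on.
#' @return Numeric scores; for probabilistic backends these are
#'   positive-class probabilities.
#' @export
predict_scores <- function(fit, X) {
  stopifnot(inherits(fit, "pseterm_fit"))
  if (!is.null(fit$features) && !is.null(colnames(X))) {
    X <- X[, fit$features, drop = FALSE]
  }
  spec <- fit$spec
  switch(spec$algorithm,
    xgb = ,
    gbm = stats::predict(fit$fit, xgboost::xgb.DMatrix(X)),
    bagging = rowMeans(vapply(fit$fit, function(f)
      score_base(spec$base, f, X), numeric(nrow(X)))),
    adaboost = {
      if (length(fit$fit) == 0) return(rep(0.5, nrow(X)))
      a <- vapply(fit$fit, `[[`, numeric(1), "alpha")
      votes <- vapply(fit$fit, function(m)
        ifelse(score_base(spec$base, m$fit, X) > 0.5, 1, -1), numeric(nrow(X)))
      margin <- as.vector(if (is.matrix(votes)) votes %*% a else votes * a)
      stats::plogis(margin)
    },
    score_base(spec$algorithm, fit$fit, X)
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$algorithm,
      if (!is.null(x$base)) paste0("(", x$base, ")"),
      if (x$needs_scaling) " [scaled]", "\n", sep = "")
  invisible(x)
}
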