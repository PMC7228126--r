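test_that("min-max scaling maps training extrema to the range ends", {
  col <- matrix(c(0, 5, 10), ncol = 1, dimnames = list(NULL, "x"))
  sc <- minmax_fit(col)
  expect_equal(unname(minmax_apply(sc, col)[, 1]), c(0, 0.5, 1))
  sc2 <- minmax_fit(col, range = c(-1, 1))
  expect_equal(unname(minmax_apply(sc2, col)[, 1]), c(-1, 0, 1))
  const <- matrix(3, 3, 1, dimnames = list(NULL, "c"))
  expect_equal(unname(minmax_apply(minmax_fit(const), const)[, 1]),
               rep(0.5, 3))
  # unseen data may leave the range: not clipped
  expect_equal(unname(minmax_apply(sc, matrix(20, 1, 1,
                                              dimnames = list(NULL, "x")))[, 1]),
               2)
  expect_error(minmax_apply(list(), col), "fitted")
})

test_that("metrics match their hand-computed values", {
  perfect <- metrics_report(confusion_counts(c(TRUE, FALSE), c(TRUE, FALSE)))
  expect_equal(unlist(perfect), c(sn = 1, sp = 1, acc = 1, mcc = 1))
  m <- metrics_report(confusion_counts(rep(c(TRUE, FALSE), c(10, 10)),
                                       rep(c(TRUE, FALSE, TRUE, FALSE),
                                           c(8, 2, 1, 9))))
  expect_equal(m$sn, 0.8)
  expect_equal(m$sp, 0.9)
  expect_equal(m$acc, 0.85)
  expect_equal(m$mcc, 0.7035265, tolerance = 1e-6)
  expect_error(metrics_report(0, 5, 0, 0), "non-empty")
})

test_that("the error-rate metric forms equal the standard confusion formulas", {
  # oracle: the 'one minus error' rearrangement with its normalised root
  rearranged_mcc <- function(np, nn, fn, fp) {
    num <- 1 - (fn / np + fp / nn)
    f1 <- 1 + (fp - fn) / np
    f2 <- 1 + (fn - fp) / nn
    if (f1 <= 0 || f2 <= 0) return(NA_real_)
    num / sqrt(f1 * f2)
  }
  standard <- function(np, nn, fn, fp) {
    tp <- np - fn; tn <- nn - fp
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    if (den == 0) return(NA_real_)
    (tp * tn - fp * fn) / sqrt(den)
  }
  for (np in 1:6) for (nn in 1:6) for (fn in 0:np) for (fp in 0:nn) {
    r <- metrics_report(np, nn, fn, fp)
    expect_equal(r$sn, (np - fn) / np)
    expect_equal(r$sp, (nn - fp) / nn)
    expect_equal(r$acc, (np - fn + nn - fp) / (np + nn))
    s <- standard(np, nn, fn, fp)
    if (!is.na(s)) {
      expect_equal(r$mcc, s, tolerance = 1e-12)
      expect_equal(r$mcc, rearranged_mcc(np, nn, fn, fp), tolerance = 1e-12)
    } else {
      expect_equal(r$mcc, 0)  # degenerate tables by convention
    }
  }
})

test_that("AUC equals concordant-pair counting and respects ties", {
  expect_equal(roc_auc(c(TRUE, TRUE, FALSE), c(0.9, 0.8, 0.1))$auc, 1)
  expect_equal(roc_auc(rep(c(TRUE, FALSE), 5), rep(0.3, 10))$auc, 0.5)

  set.seed(81)
  y <- rep(c(TRUE, FALSE), each = 10)
  s <- sample(seq(0, 1, by = 0.25), 20, replace = TRUE)  # plenty of ties
  pairs <- 0
  for (i in which(y)) for (j in which(!y)) {
    pairs <- pairs + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  }
  r <- roc_auc(y, s)
  expect_equal(r$auc, pairs / 100, tolerance = 1e-12)
  # invariant under strictly monotone transforms
  expect_equal(roc_auc(y, exp(3 * s))$auc, r$auc)
  # curve endpoints
  expect_equal(r$curve$tpr[1], 0)
  expect_equal(utils::tail(r$curve$tpr, 1), 1)
  expect_error(roc_auc(rep(TRUE, 3), 1:3), "both classes")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(82)
  y <- rep(c(TRUE, FALSE), each = 15)
  s <- rnorm(30) + y
  expect_equal(roc_auc(y, s)$auc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("every model in the zoo fits and separates an easy task", {
  task <- separable_task(n = 40, seed = 9)
  specs <- list(
    model_spec("svc"), model_spec("naive_bayes"), model_spec("logistic"),
    model_spec("decision_tree"), model_spec("mlp", params = list(size = 4)),
    model_spec("knn", params = list(k = 3)),
    model_spec("gbm", params = list(n_estimators = 30)),
    model_spec("xgb", params = list(n_estimators = 30)),
    model_spec("bagging", base = "decision_tree",
               params = list(n_estimators = 10)),
    model_spec("adaboost", base = "decision_tree",
               params = list(n_estimators = 10)),
    model_spec("adaboost", base = "naive_bayes",
               params = list(n_estimators = 5)),
    model_spec("bagging", base = "logistic", params = list(n_estimators = 5))
  )
  for (sp in specs) {
    X <- task$X
    if (sp$needs_scaling) X <- minmax_apply(minmax_fit(X), X)
    fit <- fit_model(sp, X, task$y, seed = 2)
    acc <- mean((predict_scores(fit, X) > 0.5) == task$y)
    expect_gt(acc, 0.9)
  }
})

test_that("scaling policy follows the margin-versus-probability divide", {
  expect_true(model_spec("svc")$needs_scaling)
  expect_true(model_spec("logistic")$needs_scaling)
  expect_true(model_spec("knn")$needs_scaling)
  expect_true(model_spec("mlp")$needs_scaling)
  expect_true(model_spec("adaboost", base = "svc")$needs_scaling)
  expect_false(model_spec("decision_tree")$needs_scaling)
  expect_false(model_spec("naive_bayes")$needs_scaling)
  expect_false(model_spec("xgb")$needs_scaling)
  expect_false(model_spec("gbm")$needs_scaling)
  expect_false(model_spec("adaboost", base = "decision_tree")$needs_scaling)
})

test_that("repeated CV is seed-pure and hovers at chance on noise", {
  set.seed(83)
  X <- matrix(rnorm(60 * 5), 60, dimnames = list(NULL, paste0("f", 1:5)))
  y <- rep(c(TRUE, FALSE), 30)
  cv <- cv_config(folds = 5, repeats = 3, seed = 7)
  spec <- model_spec("xgb", params = list(n_estimators = 10))
  a <- repeated_cv(spec, X, y, cv)
  b <- repeated_cv(spec, X, y, cv)
  expect_identical(a$summary, b$summary)
  acc <- a$summary$estimate[a$summary$metric == "acc"]
  mcc <- a$summary$estimate[a$summary$metric == "mcc"]
  expect_lt(abs(acc - 0.5), 0.17)
  expect_lt(abs(mcc), 0.35)
  # means lie within the per-repeat envelope
  expect_gte(acc, min(a$per_repeat$acc))
  expect_lte(acc, max(a$per_repeat$acc))
})

test_that("standard errors shrink roughly as one over root repeats", {
  sim <- simulate_terminator_data(sim_config(n_pos = 40, n_neg = 40, seed = 23))
  X <- extract_group(sim, "basecontent")
  spec <- model_spec("xgb", params = list(n_estimators = 20))
  se_of <- function(reps) {
    r <- repeated_cv(spec, X, sim$label, cv_config(repeats = reps, seed = 31))
    r$summary$std.error[r$summary$metric == "acc"]
  }
  se4 <- se_of(4); se16 <- se_of(16)
  # expect about a factor 2; allow wide stochastic slack
  expect_lt(se16, se4 * 1.4)
})

test_that("grid search is exhaustive with documented tie-breaking", {
  task <- separable_task(n = 20, seed = 10)
  single <- model_spec("xgb", grid = list(n_estimators = 15))
  gs <- grid_search(single, task$X, task$y,
                    cv_config(folds = 3, repeats = 1, seed = 2))
  expect_equal(gs$best_params$n_estimators, 15)
  expect_equal(nrow(gs$results), 1)

  expect_length(default_grid("bagging")$n_estimators, 20)
  expect_length(default_grid("xgb")$n_estimators, 20)
  expect_length(default_grid("svc")$c, 11)

  small <- model_spec("xgb", grid = list(n_estimators = c(5, 10)))
  large <- model_spec("xgb", grid = list(n_estimators = c(5, 10, 20)))
  cv <- cv_config(folds = 3, repeats = 1, seed = 4)
  acc_small <- max(grid_search(small, task$X, task$y, cv)$results$acc)
  acc_large <- max(grid_search(large, task$X, task$y, cv)$results$acc)
  expect_gte(acc_large, acc_small)  # enlarging a grid never hurts the best
})

test_that("fold skipping under unstratified CV is reported, not fatal", {
  set.seed(85)
  X <- matrix(rnorm(12 * 2), 12, dimnames = list(NULL, c("a", "b")))
  y <- rep(c(TRUE, FALSE), c(2, 10))
  cv <- cv_config(folds = 6, repeats = 1, seed = 1, stratified = FALSE)
  suppressWarnings({
    r <- repeated_cv(model_spec("xgb", params = list(n_estimators = 5)),
                     X, y, cv)
  })
  expect_true(r$per_repeat$skipped_folds[1] >= 1)
})

test_that("the fitted pipeline is frozen: test data cannot influence it", {
  sim <- simulate_terminator_data(sim_config(n_pos = 20, n_neg = 20, seed = 27))
  test_a <- simulate_terminator_data(sim_config(n_pos = 8, n_neg = 8, seed = 28))
  test_b <- test_a
  test_b$label <- rev(test_b$label)  # permuted labels, same sequences
  cfg <- pipeline_config(families = c("basecontent", "kpwm(1)"),
                         selection = "none",
                         model = model_spec("xgb",
                                            params = list(n_estimators = 10)),
                         seed = 3)
  pa <- train_predict(sim, test_a, cfg)
  pb <- train_predict(sim, test_b, cfg)
  expect_identical(pa$predictions, pb$predictions)
})

test_that("pipelines train, predict, evaluate and survive serialization", {
  sim <- simulate_terminator_data(sim_config(n_pos = 25, n_neg = 25, seed = 29))
  cfg <- pipeline_config(families = c("basecontent", "pseknc1(4)"),
                         ifs_stride = "auto", ifs_nrounds = 10,
                         model = model_spec("xgb",
                                            params = list(n_estimators = 20)),
                         seed = 6)
  res <- train_predict(sim, sim, cfg)
  expect_equal(res$metrics$acc, 1)  # resubstitution on a separable task
  expect_named(res$predictions, c("id", "score", "label"))

  path <- withr::local_tempfile(fileext = ".rds")
  save_pipeline(res$pipeline, path)
  reloaded <- load_pipeline(path)
  expect_identical(predict(reloaded, sim), predict(res$pipeline, sim))

  ev <- evaluate_pipeline(reloaded, sim)
  expect_named(ev, c("sn", "sp", "acc", "mcc", "auc"))

  long <- seq_dataset("L", strrep("A", 100))
  expect_error(predict(res$pipeline, long), "l_max")
})

test_that("sequence-level CV refits PWM features inside each fold", {
  sim <- simulate_terminator_data(sim_config(n_pos = 50, n_neg = 50, seed = 33))
  cfg <- pipeline_config(families = c("basecontent", "kpwm(1)"),
                         selection = "none",
                         model = model_spec("xgb",
                                            params = list(n_estimators = 40)),
                         seed = 2)
  r <- pipeline_cv(sim, cfg, cv_config(folds = 4, repeats = 2, seed = 5))
  acc <- r$summary$estimate[r$summary$metric == "acc"]
  expect_gt(acc, 0.75)  # GC/poly-T composition + base profile carry signal
  r2 <- pipeline_cv(sim, cfg, cv_config(folds = 4, repeats = 2, seed = 5))
  expect_identical(r$summary, r2$summary)
})

test_that("tidiers expose rankings, curves, CV reports and ROC tidily", {
  set.seed(87)
  X <- matrix(rnorm(40), 10, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(c(TRUE, FALSE), 5)
  rk <- f_scores(X, y)
  td <- tidy(rk)
  expect_named(td, c("feature", "score", "rank"))
  expect_equal(td$score, sort(td$score, decreasing = TRUE))

  ifs <- incremental_selection(X, y, rk, function(X, y, seed) ncol(X) / 10)
  expect_named(tidy(ifs), c("n_features", "accuracy"))
  expect_equal(glance(ifs)$best_size, 4)

  r <- roc_auc(y, rnorm(10))
  expect_equal(glance(r)$auc, r$auc)
  p <- autoplot(ifs)
  expect_s3_class(p, "ggplot")
})
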