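# A linearly separable table and a null table, used across the ML tests.
make_xy <- function(n = 200, p = 4, signal = 0, prev = 0.25, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  lin <- signal * x[, 1]
  y <- runif(n) < plogis(lin + stats::qlogis(prev))
  list(x = x, y = y)
}

test_that("auc_score equals the rank-sum identity and the ROC oracle", {
  # frozen 8-row case: positives hold ranks 8, 7, 5, 2 -> U = 12, AUC = 0.75
  scores <- c(.9, .8, .7, .6, .5, .4, .3, .2)
  y <- c(1, 1, 0, 1, 0, 0, 1, 0)
  expect_equal(auc_score(scores, y), 0.75)
  expect_equal(auc_score(scores, rep(1, 8)), NA_real_)
  # perfect and inverted rankings
  expect_equal(auc_score(1:8, c(0, 0, 0, 0, 1, 1, 1, 1)), 1)
  expect_equal(auc_score(1:8, c(1, 1, 1, 1, 0, 0, 0, 0)), 0)
  # independent oracle: trapezoidal ROC integration from pROC
  set.seed(3)
  for (i in 1:20) {
    s <- sample(seq(0, 1, 0.05), 40, replace = TRUE)  # heavy ties
    yy <- rbinom(40, 1, 0.3)
    if (length(unique(yy)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(yy, s, quiet = TRUE, direction = "<")))
    expect_equal(auc_score(s, yy), ref, tolerance = 1e-12)
  }
})

test_that("smote balances exactly and synthesizes inside the minority envelope", {
  d <- make_xy(n = 400, prev = 0.05, seed = 11)
  set.seed(1)
  bal <- smote(d$x, d$y, k = 5)
  expect_equal(sum(bal$y), sum(!bal$y))
  expect_identical(bal$x[seq_len(nrow(d$x)), ], d$x)  # originals untouched
  syn <- bal$x[-seq_len(nrow(d$x)), , drop = FALSE]
  xm <- d$x[d$y, , drop = FALSE]
  for (j in seq_len(ncol(syn))) {
    expect_gte(min(syn[, j]), min(xm[, j]) - 1e-12)
    expect_lte(max(syn[, j]), max(xm[, j]) + 1e-12)
  }

  # balanced input passes through unchanged
  xb <- d$x[1:40, ]; yb <- rep(c(TRUE, FALSE), 20)
  expect_identical(smote(xb, yb), list(x = xb, y = yb))

  # tiny minority: k shrinks with a warning
  xs <- d$x[1:20, ]; ys <- c(rep(TRUE, 3), rep(FALSE, 17))
  expect_warning(b2 <- smote(xs, ys, k = 5), "k = 2")
  expect_equal(sum(b2$y), sum(!b2$y))
})

test_that("the preprocessing chain never touches the test partition", {
  d <- make_xy(n = 300, signal = 1.5, prev = 0.1, seed = 21)
  cfg <- ml_config(features = colnames(d$x), seed = 5)
  sp <- split_and_balance(d$x, d$y, cfg)
  expect_setequal(c(sp$train_idx, sp$test_idx), seq_along(d$y))
  # rerun the preprocess on the training rows alone (test partition deleted)
  seeds <- moodwatch:::derive_seeds(cfg$seed, 2)
  prep <- fit_preprocess(d$x[sp$train_idx, ], d$y[sp$train_idx], cfg,
                         seed = seeds[2])
  expect_identical(prep$scaler, sp$scaler)
  expect_identical(prep$train_balanced, sp$train_balanced)
  expect_identical(prep$train_original, sp$train_original)
  # scaler parameters come from training rows only
  expect_equal(sp$scaler$center,
               colMeans(d$x[sp$train_idx, ]), ignore_attr = TRUE)
})

test_that("tuning selects sensibly and is deterministic under a fixed seed", {
  sep <- make_xy(n = 120, signal = 20, prev = 0.5, seed = 31)
  one <- tune_and_fit(sep$x, sep$y, "logit",
                      grid = data.frame(lambda = 0.01), cv_folds = 3, seed = 1)
  expect_equal(one$params$lambda, 0.01)
  expect_gt(one$cv_auc_mean, 0.95)

  for (fam in c("logit", "svm", "rf", "xgb")) {
    grid <- utils::head(default_ml_grids()[[fam]], 2)
    t1 <- tune_and_fit(sep$x, sep$y, fam, grid, cv_folds = 3, seed = 9)
    expect_gt(t1$cv_auc_mean, 0.9)
    t2 <- tune_and_fit(sep$x, sep$y, fam, grid, cv_folds = 3, seed = 9)
    expect_identical(t1$params, t2$params)
    expect_equal(predict_scores <- moodwatch:::predict_scores(t1$model, sep$x),
                 moodwatch:::predict_scores(t2$model, sep$x), tolerance = 1e-12)
  }

  nul <- make_xy(n = 200, signal = 0, prev = 0.5, seed = 32)
  t0 <- tune_and_fit(nul$x, nul$y, "logit",
                     grid = data.frame(lambda = c(1, 0.01)), cv_folds = 5, seed = 2)
  expect_gt(t0$cv_auc_mean, 0.35)
  expect_lt(t0$cv_auc_mean, 0.65)
})

test_that("evaluation reports train and test metrics for the low class", {
  d <- make_xy(n = 160, signal = 10, prev = 0.3, seed = 41)
  cfg <- ml_config(seed = 3)
  sp <- split_and_balance(d$x, d$y, cfg)
  tn <- tune_and_fit(sp$train_balanced$x, sp$train_balanced$y, "logit",
                     grid = data.frame(lambda = 0.01), cv_folds = 3, seed = 4)
  m <- evaluate_model(tn$model, sp$train_original, sp$test)
  for (part in m) {
    expect_true(part$auc >= 0 && part$auc <= 1)
    expect_true(part$acc >= 0 && part$acc <= 1)
  }
  expect_gt(m$test$auc, 0.8)

  # single-class test set is flagged
  expect_warning(
    evaluate_model(tn$model, sp$train_original,
                   list(x = sp$test$x[sp$test$y, , drop = FALSE],
                        y = sp$test$y[sp$test$y])),
    "single-class")
})

test_that("permutation importance ranks the informative feature first", {
  d <- make_xy(n = 300, signal = 3, prev = 0.4, seed = 51)
  fit <- moodwatch:::fit_family("logit", d$x, d$y, data.frame(lambda = 0.01))
  imp <- permutation_importance(fit, d$x, d$y, n_iters = 30, seed = 6)
  expect_equal(imp$feature[1], "f1")
  # noise features lose almost nothing
  expect_lt(max(abs(imp$mean_acc_drop[imp$feature != "f1"])), 0.05)

  # a duplicated informative feature shares importance
  xdup <- cbind(d$x, f1b = d$x[, 1])
  fit2 <- moodwatch:::fit_family("logit", xdup, d$y, data.frame(lambda = 0.01))
  imp2 <- permutation_importance(fit2, xdup, d$y, n_iters = 30, seed = 6)
  expect_lt(imp2$mean_acc_drop[imp2$feature == "f1"],
            imp$mean_acc_drop[imp$feature == "f1"])
})

test_that("the chance test separates signal from null and flags degeneracy", {
  cfg <- ml_config(n_chance_reps = 40, seed = 2)
  sep <- make_xy(n = 150, signal = 10, prev = 0.4, seed = 61)
  ct <- chance_test(sep$x, sep$y, "logit", data.frame(lambda = 0.01), cfg, seed = 3)
  expect_gt(ct$mean_auc, 0.85)
  expect_lt(ct$p, 0.001)

  # constant features give constant scores: AUC pinned at 0.5, t-test
  # undefined and flagged (a forest with no split predicts one probability)
  xconst <- matrix(1, 80, 2, dimnames = list(NULL, c("a", "b")))
  yconst <- rep(c(TRUE, FALSE), 40)
  expect_warning(
    ct0 <- chance_test(xconst, yconst, "rf",
                       data.frame(num_trees = 50, max_depth = 3),
                       ml_config(n_chance_reps = 10, seed = 2), seed = 4),
    "degenerate")
  expect_equal(ct0$mean_auc, 0.5)
  expect_true(is.na(ct0$t))
})

test_that("run_ml is reproducible end to end on a small table", {
  pl <- default_cohort_pipeline()
  cfg <- ml_config(outcome = "low_mood",
                   features = c("n_troughs", "n_peaks", "sick", "male"),
                   families = "logit",
                   grids = list(logit = data.frame(lambda = c(0.1, 0.01))),
                   n_importance_iters = 20, n_chance_reps = 20, seed = 77)
  r1 <- run_ml(pl$features, cfg)
  r2 <- run_ml(pl$features, cfg)
  expect_equal(r1$families$logit$test, r2$families$logit$test)
  expect_identical(r1$families$logit$tuned_params, r2$families$logit$tuned_params)
  expect_equal(r1$families$logit$chance$aucs, r2$families$logit$chance$aucs)
  expect_gt(r1$families$logit$test$auc, 0.5)
  expect_equal(r1$n_rows, nrow(pl$features))
})
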