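#' Configuration for the classification stage
#'
#' @param outcome `"low_mood"` or `"low_energy"`.
#' @param features Feature columns; `NULL` (default) selects the predictors
#'   significant at p < .05 in the association stage plus the sick and male
#'   controls at [run_ml()] time.
#' @param families Model families to fit: any of `"logit"` (L2-regularized
#'   logistic regression), `"svm"` (RBF), `"rf"` (random forest), `"xgb"`
#'   (gradient boosted trees).
#' @param grids Named list of hyperparameter grids (data frames), one per
#'   family; see [default_ml_grids()].
#' @param test_fraction Held-out test fraction of the stratified split.
#' @param cv_folds Folds for hyperparameter tuning.
#' @param smote_neighbors k for SMOTE minority interpolation.
#' @param threshold Score threshold for accuracy/precision/recall.
#' @param n_importance_iters Permutation-importance iterations.
#' @param n_chance_reps Resampling repetitions of the chance test.
#' @param chance_train_fraction Training fraction inside each chance-test
#'   resample.
#' @param scale_before_split If `TRUE`, fit the z-score scaler on all rows
#'   before splitting (leaks test information; off by default).
#' @param seed Seed controlling the split, SMOTE, fold assignment and every
#'   stochastic fit.
#' @return A list of class `ml_config`.
#' @export
ml_config <- function(outcome = c("low_mood", "low_energy"),
                      features = NULL,
                      families = c("logit", "svm", "rf", "xgb"),
                      grids = default_ml_grids(),
                      test_fraction = 0.25,
                      cv_folds = 5,
                      smote_neighbors = 5,
                      threshold = 0.5,
                      n_importance_iters = 1000,
                      n_chance_reps = 100,
                      chance_train_fraction = 0.70,
                      scale_before_split = FALSE,
                      seed = 1) {
  outcome <- match.arg(outcome)
  families <- match.arg(families, several.ok = TRUE)
  stopifnot(test_fraction > 0, test_fraction < 1, cv_folds >= 2,
            chance_train_fraction > 0, chance_train_fraction < 1,
            smote_neighbors >= 1)
  structure(as.list(environment()), class = "ml_config")
}

#' Default hyperparameter grids
#'
#' @return Named list of data-frame grids for the four families: logit ridge
#'   penalty, SVM cost x gamma (as a multiple of 1/p), random-forest
#'   trees x depth (0 = unlimited), and boosted-tree depth x learning
#'   rate x rounds.
#' @export
default_ml_grids <- function() {
  list(
    logit = expand.grid(lambda = c(1, 0.1, 0.01, 0.001)),
    svm = expand.grid(cost = c(0.1, 1, 10), gamma_mult = c(0.5, 1, 2)),
    rf = expand.grid(num_trees = c(100, 300), max_depth = c(3, 5, 0)),
    xgb = expand.grid(max_depth = c(2, 3, 4), eta = c(0.05, 0.1, 0.3),
                      nrounds = c(100, 300)))
}

#' Area under the ROC curve
#'
#' Computed via the rank-sum (Mann-Whitney) identity, which equals the
#' trapezoidal area under the ROC curve and handles tied scores by midranks.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param y Logical or 0/1 labels.
#' @return AUC in \[0, 1\]; `NA` if only one class is present.
#' @export
auc_score <- function(scores, y) {
  y <- as.logical(y)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# --- scaling -----------------------------------------------------------------

fit_scaler <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s == 0] <- 1
  list(center = mu, scale = s)
}

apply_scaler <- function(scaler, x)
  scale(x, center = scaler$center, scale = scaler$scale)[, , drop = FALSE]

# --- SMOTE -------------------------------------------------------------------

#' Synthetic minority oversampling (SMOTE)
#'
#' Interpolates new minority-class rows between each sampled minority row
#' and one of its k nearest minority neighbours (Euclidean distance in the
#' given feature space) until the classes are exactly balanced. If the
#' minority class is already the same size as the majority the input is
#' returned unchanged. When fewer than `k + 1` minority rows exist, k is
#' reduced with a warning; a single minority row is replicated verbatim.
#'
#' @param x Numeric feature matrix (standardize first).
#' @param y Logical labels; the rarer class is oversampled.
#' @param k Number of nearest neighbours.
#' @return List with balanced `x` and `y` (original rows first, synthetic
#'   rows appended).
#' @export
smote <- function(x, y, k = 5) {
  y <- as.logical(y)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == n0) return(list(x = x, y = y))
  minority <- if (n1 < n0) y else !y
  need <- abs(n0 - n1)
  xm <- x[minority, , drop = FALSE]
  nm <- nrow(xm)
  if (nm == 1) {
    warning("smote: single minority row; replicating it verbatim")
    syn <- xm[rep(1, need), , drop = FALSE]
  } else {
    if (nm <= k) {
      warning("smote: minority class smaller than k + 1; using k = ", nm - 1)
      k <- nm - 1
    }
    d <- as.matrix(stats::dist(xm))
    diag(d) <- Inf
    nn <- apply(d, 1, function(row) order(row)[seq_len(k)])
    nn <- matrix(nn, nrow = k)  # k x nm
    base_i <- sample.int(nm, need, replace = TRUE)
    nb_i <- nn[cbind(sample.int(k, need, replace = TRUE), base_i)]
    u <- runif(need)
    syn <- xm[base_i, , drop = FALSE] +
      u * (xm[nb_i, , drop = FALSE] - xm[base_i, , drop = FALSE])
  }
  list(x = rbind(x, syn),
       y = c(y, rep(if (n1 < n0) TRUE else FALSE, need)))
}

# --- split + preprocess ------------------------------------------------------

#' Stratified split, scaling and SMOTE balancing
#'
#' Splits the rows into training and test sets stratified by class, fits
#' the z-score scaler on the training rows only, applies it to both sets,
#' and balances the scaled training set with [smote()]. The test set is
#' never touched by scaler fitting or SMOTE; the preprocessing is a pure
#' function of the training partition (see [fit_preprocess()]).
#'
#' @param x Numeric feature matrix.
#' @param y Logical labels (both classes must be present).
#' @param config An [ml_config()].
#' @return List with `train_balanced` (scaled + SMOTE), `train_original`
#'   (scaled, unbalanced), `test` (scaled with the train scaler), the
#'   fitted `scaler`, and the row indices of the split.
#' @export
split_and_balance <- function(x, y, config = ml_config()) {
  y <- as.logical(y)
  if (sum(y) < 2 || sum(!y) < 2)
    stop("split_and_balance: need at least 2 rows of each class")
  seeds <- derive_seeds(config$seed, 2)

  set.seed(seeds[1])
  idx_pos <- which(y); idx_neg <- which(!y)
  n_test_pos <- max(1, round(config$test_fraction * length(idx_pos)))
  n_test_neg <- max(1, round(config$test_fraction * length(idx_neg)))
  test_idx <- sort(c(sample(idx_pos, n_test_pos), sample(idx_neg, n_test_neg)))
  train_idx <- setdiff(seq_along(y), test_idx)

  if (config$scale_before_split) {
    scaler <- fit_scaler(x)
    xs <- apply_scaler(scaler, x)
    prep <- fit_preprocess(xs[train_idx, , drop = FALSE], y[train_idx],
                           config, seed = seeds[2], scale = FALSE)
    prep$scaler <- scaler
    prep$test <- list(x = xs[test_idx, , drop = FALSE], y = y[test_idx])
  } else {
    prep <- fit_preprocess(x[train_idx, , drop = FALSE], y[train_idx],
                           config, seed = seeds[2])
    prep$test <- list(x = apply_scaler(prep$scaler, x[test_idx, , drop = FALSE]),
                      y = y[test_idx])
  }
  prep$train_idx <- train_idx
  prep$test_idx <- test_idx
  prep
}

#' Fit the preprocessing chain on training rows only
#'
#' Scaler fitting and SMOTE are functions of the training partition alone,
#' so deleting the test set cannot change any fitted parameter. Exposed
#' separately so that leakage can be audited.
#'
#' @param x_train,y_train The training partition.
#' @param config An [ml_config()].
#' @param seed Seed for the SMOTE draws.
#' @param scale Fit and apply the z-score scaler (default) or assume `x_train`
#'   is already scaled.
#' @return List with `train_balanced`, `train_original` and `scaler`.
#' @export
fit_preprocess <- function(x_train, y_train, config = ml_config(), seed = 1,
                           scale = TRUE) {
  scaler <- if (scale) fit_scaler(x_train) else
    list(center = setNames(rep(0, ncol(x_train)), colnames(x_train)),
         scale = setNames(rep(1, ncol(x_train)), colnames(x_train)))
  xs <- apply_scaler(scaler, x_train)
  set.seed(seed)
  bal <- smote(xs, y_train, k = config$smote_neighbors)
  list(train_balanced = bal,
       train_original = list(x = xs, y = as.logical(y_train)),
       scaler = scaler)
}

# --- model families ----------------------------------------------------------

fit_family <- function(family, x, y, params, seed = 1) {
  y <- as.logical(y)
  set.seed(seed)
  fit <- switch(family,
    # fit along a short decreasing path ending at the requested penalty:
    # single-lambda ridge fits converge poorly in glmnet
    logit = glmnet::glmnet(x, factor(y), family = "binomial", alpha = 0,
                           lambda = params$lambda * c(64, 8, 1)),
    svm = e1071::svm(x, factor(y), kernel = "radial", cost = params$cost,
                     gamma = params$gamma_mult / ncol(x), probability = TRUE),
    rf = ranger::ranger(x = x, y = factor(y), num.trees = params$num_trees,
                        max.depth = params$max_depth, probability = TRUE,
                        num.threads = 1, seed = seed),
    xgb = xgboost::xgb.train(
      params = list(max_depth = params$max_depth, eta = params$eta,
                    objective = "binary:logistic", nthread = 1),
      data = xgboost::xgb.DMatrix(x, label = as.numeric(y), nthread = 1),
      nrounds = params$nrounds, verbose = 0),
    stop("unknown family: ", family))
  structure(list(family = family, fit = fit, params = params,
                 feature_names = colnames(x)), class = "mw_model")
}

# Positive-class probability for every family.
predict_scores <- function(model, x) {
  x <- as.matrix(x)
  switch(model$family,
    logit = as.numeric(predict(model$fit, x, s = model$params$lambda,
                               type = "response")),
    svm = {
      pr <- attr(predict(model$fit, x, probability = TRUE), "probabilities")
      as.numeric(pr[, "TRUE"])
    },
    rf = as.numeric(predict(model$fit, data = x, num.threads = 1)$predictions[, "TRUE"]),
    xgb = as.numeric(predict(model$fit, xgboost::xgb.DMatrix(x, nthread = 1))))
}

classification_metrics <- function(scores, y, threshold = 0.5) {
  y <- as.logical(y)
  pred <- scores >= threshold
  tp <- sum(pred & y); fp <- sum(pred & !y); fn <- sum(!pred & y)
  list(auc = auc_score(scores, y),
       acc = mean(pred == y),
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' Tune hyperparameters by stratified cross-validation and refit
#'
#' Exhaustive search over the grid: each candidate is scored by its mean
#' out-of-fold AUC over stratified folds of the (balanced) training set; the
#' best candidate (ties: first in grid order) is refit on the full training
#' set.
#'
#' @param x,y The balanced training set.
#' @param family One of `"logit"`, `"svm"`, `"rf"`, `"xgb"`.
#' @param grid Data frame of candidates (default from [default_ml_grids()]).
#' @param cv_folds Number of folds.
#' @param seed Seed for fold assignment and stochastic fits.
#' @return List with the fitted `model`, the chosen `params`, `cv_auc_mean`
#'   and `cv_auc_sd` of the winner, and the full `cv_table`.
#' @export
tune_and_fit <- function(x, y, family, grid = default_ml_grids()[[family]],
                         cv_folds = 5, seed = 1) {
  stopifnot(nrow(grid) >= 1)
  y <- as.logical(y)
  seeds <- derive_seeds(seed, 2 + nrow(grid))
  set.seed(seeds[1])
  fold <- integer(length(y))
  for (cls in c(TRUE, FALSE)) {
    i <- which(y == cls)
    fold[i] <- sample(rep_len(seq_len(cv_folds), length(i)))
  }
  cv <- vapply(seq_len(nrow(grid)), function(gi) {
    aucs <- vapply(seq_len(cv_folds), function(f) {
      tr <- fold != f
      m <- fit_family(family, x[tr, , drop = FALSE], y[tr], grid[gi, , drop = FALSE],
                      seed = seeds[2 + gi])
      auc_score(predict_scores(m, x[!tr, , drop = FALSE]), y[!tr])
    }, numeric(1))
    c(mean(aucs, na.rm = TRUE), sd(aucs, na.rm = TRUE))
  }, numeric(2))
  best <- which.max(cv[1, ])
  model <- fit_family(family, x, y, grid[best, , drop = FALSE], seed = seeds[2])
  list(model = model, params = grid[best, , drop = FALSE],
       cv_auc_mean = cv[1, best], cv_auc_sd = cv[2, best],
       cv_table = cbind(grid, cv_auc = cv[1, ], cv_auc_sd = cv[2, ]))
}

#' Evaluate a fitted model on the pre-SMOTE training data and the test set
#'
#' AUC from the predicted scores plus accuracy, precision and recall at the
#' configured threshold, with the low (positive) class as the target.
#'
#' @param model A fitted model from [tune_and_fit()] / `fit_family`.
#' @param train_original The scaled, unbalanced training partition
#'   (`list(x, y)`).
#' @param test The scaled test partition (`list(x, y)`).
#' @param threshold Classification threshold.
#' @return List with `train` and `test` metric lists; a single-class test
#'   set yields `NA` AUC with a warning.
#' @export
evaluate_model <- function(model, train_original, test, threshold = 0.5) {
  tr <- classification_metrics(predict_scores(model, train_original$x),
                               train_original$y, threshold)
  te <- classification_metrics(predict_scores(model, test$x), test$y, threshold)
  if (is.na(te$auc)) warning("evaluate_model: single-class test set, AUC undefined")
  list(train = tr, test = te)
}

#' Permutation feature importance
#'
#' For each feature, the values of that column are shuffled (preserving its
#' marginal distribution) and the decrement in accuracy relative to the
#' unshuffled data is recorded; the mean decrement over `n_iters` shuffles
#' is the importance.
#'
#' @param model A fitted model.
#' @param x,y Evaluation data (typically the test partition).
#' @param n_iters Shuffle iterations per feature.
#' @param threshold Classification threshold for accuracy.
#' @param seed Seed for the shuffles.
#' @return A tibble sorted by decreasing importance: feature,
#'   `mean_acc_drop`, `sd_acc_drop`.
#' @export
permutation_importance <- function(model, x, y, n_iters = 1000,
                                   threshold = 0.5, seed = 1) {
  y <- as.logical(y)
  set.seed(seed)
  base_acc <- mean((predict_scores(model, x) >= threshold) == y)
  p <- ncol(x)
  drops <- matrix(NA_real_, n_iters, p, dimnames = list(NULL, colnames(x)))
  for (it in seq_len(n_iters)) {
    for (j in seq_len(p)) {
      xp <- x
      xp[, j] <- x[sample.int(nrow(x)), j]
      drops[it, j] <- base_acc - mean((predict_scores(model, xp) >= threshold) == y)
    }
  }
  out <- tibble::tibble(feature = colnames(x),
                        mean_acc_drop = colMeans(drops),
                        sd_acc_drop = apply(drops, 2, sd))
  dplyr::arrange(out, dplyr::desc(.data$mean_acc_drop))
}

#' Resampling test of discrimination against chance
#'
#' Repeatedly draws a random training subset (without replacement) of
#' `chance_train_fraction` of the rows, fits the family with the supplied
#' (already tuned) hyperparameters, records the AUC on the held-out rows,
#' and compares the AUC distribution to 0.5 with a two-sided one-sample
#' t-test. Resamples leaving a single class in either part are re-drawn
#' (and counted).
#'
#' @param x,y The full (unscaled) feature matrix and labels.
#' @param family Model family.
#' @param params Hyperparameters to reuse in every resample.
#' @param config An [ml_config()] (uses `n_chance_reps`,
#'   `chance_train_fraction`, `smote_neighbors`).
#' @param seed Seed for the resamples.
#' @return List with the vector of `aucs`, `mean_auc`, `t`, `p` (both `NA`
#'   with a warning if the AUCs are degenerate) and `n_redraws`.
#' @export
chance_test <- function(x, y, family = "logit",
                        params = data.frame(lambda = 0.01),
                        config = ml_config(), seed = 1) {
  y <- as.logical(y)
  n <- length(y)
  n_train <- round(config$chance_train_fraction * n)
  seeds <- derive_seeds(seed, config$n_chance_reps)
  aucs <- numeric(config$n_chance_reps)
  n_redraws <- 0L
  if (sum(y) < 2 || sum(!y) < 2)
    stop("chance_test: need at least 2 rows of each class")
  for (r in seq_len(config$n_chance_reps)) {
    set.seed(seeds[r])
    repeat {
      tr <- sample.int(n, n_train)
      if (min(table(y[tr])) >= 2 && length(unique(y[tr])) == 2 &&
          length(unique(y[-tr])) == 2) break
      n_redraws <- n_redraws + 1L
      if (n_redraws > 1000L * config$n_chance_reps)
        stop("chance_test: cannot draw resamples containing both classes")
    }
    scaler <- fit_scaler(x[tr, , drop = FALSE])
    m <- fit_family(family, apply_scaler(scaler, x[tr, , drop = FALSE]), y[tr],
                    params, seed = seeds[r])
    aucs[r] <- auc_score(predict_scores(m, apply_scaler(scaler, x[-tr, , drop = FALSE])),
                         y[-tr])
  }
  if (sd(aucs) == 0) {
    warning("chance_test: degenerate AUC distribution, t-test undefined")
    return(list(aucs = aucs, mean_auc = mean(aucs), t = NA_real_, p = NA_real_,
                n_redraws = n_redraws))
  }
  tt <- t.test(aucs, mu = 0.5)
  list(aucs = aucs, mean_auc = mean(aucs), t = unname(tt$statistic),
       p = tt$p.value, n_redraws = n_redraws)
}

#' Run the full classification protocol
#'
#' For each requested family: stratified split, train-only scaling, SMOTE
#' balancing, grid tuning by cross-validation, evaluation on the pre-SMOTE
#' training data and the held-out test set, permutation feature importance
#' on the test set, and the chance resampling test with the tuned
#' hyperparameters.
#'
#' @param table Analysis table from [build_daily_features()].
#' @param config An [ml_config()]. If `config$features` is `NULL` the
#'   feature set is the association-stage predictors significant at p < .05
#'   (for the matching outcome) plus sick and male.
#' @return An object of class `ml_report`: per-family results plus the
#'   feature set and row accounting.
#' @export
run_ml <- function(table, config = ml_config()) {
  outcome_col <- config$outcome
  if (is.null(config$features)) {
    assoc <- association_table(table,
                               if (outcome_col == "low_mood") "mood" else "energy")
    config$features <- c(assoc$predictor[assoc$p < 0.05], "sick", "male")
    if (length(config$features) == 2)
      stop("run_ml: no significant predictors; supply features explicitly")
  }
  dat <- as.data.frame(table)[, c(config$features, outcome_col)]
  keep <- complete.cases(dat)
  dat <- dat[keep, ]
  x <- as.matrix(data.frame(lapply(dat[config$features], as.numeric)))
  y <- as.logical(dat[[outcome_col]])

  split <- split_and_balance(x, y, config)
  seeds <- derive_seeds(config$seed + 1, 3 * length(config$families))
  fams <- list()
  for (i in seq_along(config$families)) {
    fam <- config$families[i]
    tuned <- tune_and_fit(split$train_balanced$x, split$train_balanced$y, fam,
                          grid = config$grids[[fam]],
                          cv_folds = config$cv_folds, seed = seeds[3 * i - 2])
    metrics <- evaluate_model(tuned$model, split$train_original, split$test,
                              config$threshold)
    imp <- permutation_importance(tuned$model, split$test$x, split$test$y,
                                  n_iters = config$n_importance_iters,
                                  threshold = config$threshold,
                                  seed = seeds[3 * i - 1])
    chance <- chance_test(x, y, fam, tuned$params, config, seed = seeds[3 * i])
    fams[[fam]] <- list(family = fam, tuned_params = tuned$params,
                        cv_auc_mean = tuned$cv_auc_mean,
                        cv_auc_sd = tuned$cv_auc_sd,
                        train = metrics$train, test = metrics$test,
                        importance = imp, chance = chance,
                        model = tuned$model)
  }
  structure(list(outcome = outcome_col, features = config$features,
                 n_rows = length(y), n_positive = sum(y),
                 n_train = length(split$train_idx), n_test = length(split$test_idx),
                 families = fams, config = config),
            class = "ml_report")
}

#' @export
print.ml_report <- function(x, ...) {
  cat(sprintf("<ml_report> outcome %s: %d rows (%d positive), features: %s\n",
              x$outcome, x$n_rows, x$n_positive,
              paste(x$features, collapse = ", ")))
  for (f in x$families) {
    cat(sprintf("  %-5s test AUC %.3f ACC %.3f prec %.3f rec %.3f | train AUC %.3f | CV %.3f +/- %.3f | chance t=%.1f p=%.2g\n",
                f$family, f$test$auc, f$test$acc,
                f$test$precision %||% NA, f$test$recall %||% NA,
                f$train$auc, f$cv_auc_mean, f$cv_auc_sd,
                f$chance$t, f$chance$p))
  }
  invisible(x)
}
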