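#' Tuning specification for the dose regressors
#'
#' Bundles the repeated cross-validation settings and hyperparameter grid
#' used by [tune_and_fit_rf()] and [tune_and_fit_xgb()]. The study setting
#' is threefold cross-validation with 100 repeats scored by RMSE.
#'
#' Default grids: random forest — `mtry` in `{p/3, p/2, 2p/3, p}` (floored,
#' deduplicated), `splitrule` in `{variance, extratrees}`, `min.node.size`
#' in `{1, 5, 10}`; boosting — `max_depth` in `{2, 3, 4}`, `eta` in
#' `{0.05, 0.1, 0.3}`, `subsample = 0.8`, up to `max_rounds` boosting rounds
#' with early stopping on the held-out fold.
#'
#' @param cv_folds number of folds, `>= 2`.
#' @param cv_repeats number of CV repeats.
#' @param grid data frame of hyperparameter combinations, or `NULL` for the
#'   family default (built when the model is fitted, since the RF grid
#'   depends on the number of predictors).
#' @param num_trees trees in the final random forest (study setting: 2000).
#' @param num_trees_cv trees per CV fit (smaller for speed; RMSE ranking of
#'   grid points is stable well below the final forest size).
#' @param max_rounds cap on boosting rounds.
#' @param seed integer seed making the tuning deterministic.
#' @return list of class `mn_tuning_spec`.
#' @export
tuning_spec <- function(cv_folds = 3, cv_repeats = 100, grid = NULL,
                        num_trees = 2000, num_trees_cv = 500,
                        max_rounds = 1000, seed = 1) {
  stopifnot(cv_folds >= 2, cv_repeats >= 1)
  structure(list(cv_folds = cv_folds, cv_repeats = cv_repeats, grid = grid,
                 num_trees = num_trees, num_trees_cv = num_trees_cv,
                 max_rounds = max_rounds, seed = seed),
            class = "mn_tuning_spec")
}

default_rf_grid <- function(p) {
  mtry <- unique(pmax(1L, floor(p * c(1 / 3, 1 / 2, 2 / 3, 1))))
  expand.grid(mtry = mtry, splitrule = c("variance", "extratrees"),
              min.node.size = c(1L, 5L, 10L),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

default_xgb_grid <- function() {
  expand.grid(max_depth = c(2L, 3L, 4L), eta = c(0.05, 0.1, 0.3),
              subsample = 0.8, KEEP.OUT.ATTRS = FALSE)
}

#' Stratified random train/test split
#'
#' Splits a feature matrix into disjoint, exhaustive training and testing
#' sets. With `stratify = TRUE` (default) sampling is stratified on neutron
#'-dose quantile bins so both halves span the dose range, mirroring
#' outcome-stratified partitioning. Deterministic given `seed`.
#'
#' @param features data frame with a `neutron_dose` column.
#' @param fraction training fraction in (0, 1).
#' @param seed integer seed.
#' @param stratify stratify on neutron-dose quantile bins.
#' @param n_bins number of quantile bins for stratification.
#' @return list with data frames `train` and `test`.
#' @export
split_train_test <- function(features, fraction = 0.5, seed = 1,
                             stratify = TRUE, n_bins = 5) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n <- nrow(features)
  if (n < 4) stop("at least 4 samples required")
  set.seed(seed)
  if (stratify) {
    y <- features$neutron_dose
    bins <- if (length(unique(y)) <= n_bins) {
      as.integer(factor(y))
    } else {
      qs <- unique(stats::quantile(y, probs = seq(0, 1,
                                                  length.out = n_bins + 1)))
      if (length(qs) > 2) {
        cut(y, breaks = qs, include.lowest = TRUE, labels = FALSE)
      } else rep(1L, n)
    }
    idx <- unlist(lapply(split(seq_len(n), bins), function(ix) {
      take <- round(length(ix) * fraction)
      take <- max(min(take, length(ix) - 1L), 1L)
      if (length(ix) == 1) return(ix)
      sample(ix, take)
    }), use.names = FALSE)
  } else {
    idx <- sample(n, round(n * fraction))
  }
  idx <- sort(idx)
  list(train = features[idx, , drop = FALSE],
       test = features[-idx, , drop = FALSE])
}

model_xy <- function(data, predictors) {
  miss <- setdiff(predictors, names(data))
  if (length(miss)) {
    stop("missing predictor column(s): ", paste(miss, collapse = ", "))
  }
  x <- data[, predictors, drop = FALSE]
  if (anyNA(x)) stop("missing values in predictors")
  x
}

cv_fold_ids <- function(n, folds) {
  sample(rep_len(seq_len(folds), n))
}

new_dose_model <- function(family, fit, predictors, hyper, cv_rmse,
                           cv_table = NULL, importance = NULL) {
  structure(list(family = family, fit = fit, predictors = predictors,
                 chosen_hyperparameters = hyper,
                 training_cv_rmse = cv_rmse, cv_table = cv_table,
                 importance = importance),
            class = "mn_dose_model")
}

#' @export
print.mn_dose_model <- function(x, ...) {
  cat(sprintf("mn_dose_model [%s], %d predictors\n", x$family,
              length(x$predictors)))
  if (length(x$chosen_hyperparameters)) {
    cat("hyperparameters:",
        paste(names(x$chosen_hyperparameters),
              unlist(x$chosen_hyperparameters),
              sep = " = ", collapse = ", "), "\n")
  }
  if (!is.na(x$training_cv_rmse)) {
    cat(sprintf("training CV RMSE: %.3f Gy\n", x$training_cv_rmse))
  }
  invisible(x)
}

#' Tune and fit the random-forest neutron dose regressor
#'
#' Exhaustive grid search over random-forest hyperparameters (`mtry`,
#' `splitrule` in variance/extratrees, `min.node.size`), each combination
#' scored by its mean held-out RMSE over `cv_repeats` repetitions of
#' `cv_folds`-fold cross-validation on the training data. The winning
#' combination is refit on all training rows with `num_trees` trees
#' (study setting 2000) and permutation importances are stored. A fold whose
#' training part has constant neutron dose is skipped with a warning.
#'
#' @param train training feature matrix with a `neutron_dose` column.
#' @param predictors character vector of predictor columns.
#' @param spec a [tuning_spec()].
#' @return an `mn_dose_model` (family `"random_forest"`).
#' @export
tune_and_fit_rf <- function(train, predictors, spec = tuning_spec()) {
  x <- model_xy(train, predictors)
  y <- train$neutron_dose
  grid <- spec$grid %||% default_rf_grid(length(predictors))
  stopifnot(nrow(grid) >= 1)
  if (nrow(grid) > 1 || spec$force_cv %||% FALSE) {
    cv <- cv_score_grid(grid, spec, n = nrow(x), function(g, tr, te, s) {
      fit <- ranger::ranger(y = y[tr], x = x[tr, , drop = FALSE],
                            num.trees = spec$num_trees_cv,
                            mtry = min(g$mtry, length(predictors)),
                            splitrule = as.character(g$splitrule),
                            min.node.size = g$min.node.size,
                            seed = s, num.threads = 1)
      stats::predict(fit, x[te, , drop = FALSE])$predictions
    }, y = y)
    best <- cv$best
    cv_rmse <- cv$rmse[best]
    cv_table <- cbind(grid, mean_cv_rmse = cv$rmse)
  } else {
    best <- 1L
    cv_rmse <- NA_real_
    cv_table <- NULL
  }
  g <- grid[best, , drop = FALSE]
  fit <- ranger::ranger(y = y, x = x, num.trees = spec$num_trees,
                        mtry = min(g$mtry, length(predictors)),
                        splitrule = as.character(g$splitrule),
                        min.node.size = g$min.node.size,
                        importance = "permutation",
                        seed = spec$seed, num.threads = 1)
  new_dose_model("random_forest", fit, predictors,
                 list(mtry = g$mtry, splitrule = as.character(g$splitrule),
                      min.node.size = g$min.node.size,
                      num.trees = spec$num_trees),
                 cv_rmse, cv_table,
                 importance = sort(fit$variable.importance,
                                   decreasing = TRUE))
}

# shared repeated-CV grid scorer; predict_fun(gridrow, train_idx, test_idx,
# seed) returns held-out predictions
cv_score_grid <- function(grid, spec, n, predict_fun, y) {
  sq_err <- matrix(0, nrow(grid), 1)
  counts <- numeric(nrow(grid))
  set.seed(spec$seed)
  for (r in seq_len(spec$cv_repeats)) {
    folds <- cv_fold_ids(n, spec$cv_folds)
    for (f in seq_len(spec$cv_folds)) {
      tr <- which(folds != f)
      te <- which(folds == f)
      if (stats::var(y[tr]) == 0) {
        warning("skipping degenerate CV fold (constant target)")
        next
      }
      for (gi in seq_len(nrow(grid))) {
        pred <- predict_fun(grid[gi, , drop = FALSE], tr, te,
                            s = spec$seed + 1000L * r + f)
        sq_err[gi] <- sq_err[gi] + sum((y[te] - pred)^2)
        counts[gi] <- counts[gi] + length(te)
      }
    }
  }
  if (all(counts == 0)) stop("all CV folds degenerate (constant target)")
  rmse <- sqrt(sq_err[, 1] / counts)
  list(rmse = rmse, best = which.min(rmse))
}

#' Tune and fit the gradient-boosting neutron dose regressor
#'
#' Same repeated-CV grid search as [tune_and_fit_rf()], over boosted-tree
#' hyperparameters (`max_depth`, `eta`, `subsample`). The number of boosting
#' rounds is chosen by early stopping (20 stagnant rounds) on each held-out
#' fold, up to `spec$max_rounds`; the final model uses the median best
#' iteration of the winning combination.
#'
#' @inheritParams tune_and_fit_rf
#' @return an `mn_dose_model` (family `"xgboost"`).
#' @export
tune_and_fit_xgb <- function(train, predictors, spec = tuning_spec()) {
  x <- as.matrix(model_xy(train, predictors))
  y <- train$neutron_dose
  grid <- spec$grid %||% default_xgb_grid()
  stopifnot(nrow(grid) >= 1)
  best_iters <- vector("list", nrow(grid))
  xgb_fold <- function(g, tr, te, s) {
    dtr <- xgboost::xgb.DMatrix(x[tr, , drop = FALSE], label = y[tr])
    dte <- xgboost::xgb.DMatrix(x[te, , drop = FALSE], label = y[te])
    fit <- xgboost::xgb.train(
      params = list(max_depth = g$max_depth, eta = g$eta,
                    subsample = g$subsample,
                    objective = "reg:squarederror", nthread = 1,
                    seed = s),
      data = dtr, nrounds = spec$max_rounds,
      evals = list(val = dte), early_stopping_rounds = 20L, verbose = 0)
    bi <- as.integer(xgboost::xgb.attributes(fit)$best_iteration)
    gi <- attr(g, "grid_index")
    if (!is.null(gi)) best_iters[[gi]] <<- c(best_iters[[gi]], bi)
    stats::predict(fit, dte)
  }
  if (nrow(grid) > 1) {
    cv <- cv_score_grid(grid, spec, n = nrow(x), function(g, tr, te, s) {
      attr(g, "grid_index") <- as.integer(rownames(g))
      xgb_fold(g, tr, te, s)
    }, y = y)
    best <- cv$best
    cv_rmse <- cv$rmse[best]
  } else {
    # single combination: one CV pass just to pick the round count
    cv <- cv_score_grid(grid, tuning_spec(cv_folds = spec$cv_folds,
                                          cv_repeats = 1,
                                          seed = spec$seed,
                                          max_rounds = spec$max_rounds),
                        n = nrow(x), function(g, tr, te, s) {
                          attr(g, "grid_index") <- as.integer(rownames(g))
                          xgb_fold(g, tr, te, s)
                        }, y = y)
    best <- 1L
    cv_rmse <- cv$rmse[1]
  }
  g <- grid[best, , drop = FALSE]
  nrounds <- max(10L, as.integer(stats::median(best_iters[[best]])))
  fit <- xgboost::xgb.train(
    params = list(max_depth = g$max_depth, eta = g$eta,
                  subsample = g$subsample,
                  objective = "reg:squarederror", nthread = 1,
                  seed = spec$seed),
    data = xgboost::xgb.DMatrix(as.matrix(x), label = y),
    nrounds = nrounds, verbose = 0)
  new_dose_model("xgboost", fit, predictors,
                 list(max_depth = g$max_depth, eta = g$eta,
                      subsample = g$subsample, nrounds = nrounds),
                 cv_rmse)
}

#' Robust linear baseline for neutron dose
#'
#' Huber M-estimation regression (tuning constant 1.345) of neutron dose on
#' the retained predictors — the sanity-check baseline against which the
#' tree ensembles are compared. Rank-deficient predictor sets are rejected
#' with the collinear columns named.
#'
#' @inheritParams tune_and_fit_rf
#' @return an `mn_dose_model` (family `"robust_linear"`).
#' @export
fit_robust_linear <- function(train, predictors) {
  x <- model_xy(train, predictors)
  y <- train$neutron_dose
  if (nrow(x) <= length(predictors)) stop("need more samples than predictors")
  xm <- cbind(`(Intercept)` = 1, as.matrix(x))
  qr_x <- qr(xm)
  if (qr_x$rank < ncol(xm)) {
    bad <- colnames(xm)[qr_x$pivot[(qr_x$rank + 1):ncol(xm)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  df <- cbind(data.frame(neutron_dose = y), x)
  fit <- MASS::rlm(neutron_dose ~ ., data = df, psi = MASS::psi.huber,
                   k = 1.345, maxit = 100)
  new_dose_model("robust_linear", fit, predictors,
                 list(psi = "huber", k = 1.345), NA_real_)
}

#' Reconstruct neutron doses for new samples
#'
#' Applies a fitted dose model to a feature matrix. Predictions are clamped
#' at 0 Gy (dose is physically non-negative; only the linear family can go
#' negative) and the number of clamped values is reported in the
#' `"n_clamped"` attribute.
#'
#' @param model an `mn_dose_model`.
#' @param samples feature matrix containing all model predictors.
#' @return numeric vector of neutron dose estimates (Gy).
#' @export
reconstruct_dose <- function(model, samples) {
  x <- model_xy(samples, model$predictors)
  pred <- switch(model$family,
    random_forest = stats::predict(model$fit, x)$predictions,
    xgboost = stats::predict(model$fit,
                             xgboost::xgb.DMatrix(as.matrix(x))),
    robust_linear = as.numeric(stats::predict(model$fit, newdata = x)),
    stop("unknown model family: ", model$family))
  n_clamped <- sum(pred < 0)
  pred <- pmax(pred, 0)
  attr(pred, "n_clamped") <- n_clamped
  pred
}
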