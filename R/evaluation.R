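#' R-squared and RMSE between actual and reconstructed doses
#'
#' `RMSE = sqrt(mean((actual - predicted)^2))`; `R^2 = 1 - SSE/SST` with SST
#' taken about the mean of `actual` — the coefficient-of-determination form,
#' not a squared correlation, so miscalibrated predictions are penalized.
#' A constant `actual` vector leaves R^2 undefined (`NA` with a warning).
#'
#' @param actual,predicted numeric dose vectors (Gy), equal length `>= 2`.
#' @return list with `r_squared` and `rmse_gy`.
#' @export
score_predictions <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted), length(actual) >= 2)
  rmse <- sqrt(mean((actual - predicted)^2))
  sst <- sum((actual - mean(actual))^2)
  if (sst == 0) {
    warning("constant actual doses: R-squared undefined")
    r2 <- NA_real_
  } else {
    r2 <- 1 - sum((actual - predicted)^2) / sst
  }
  list(r_squared = r2, rmse_gy = rmse)
}

#' Calibration regression of actual on reconstructed dose
#'
#' Ordinary least squares of `actual ~ predicted`. An unbiased
#' reconstruction has intercept 0 and slope 1; the standard errors let both
#' be tested.
#'
#' @param actual,predicted numeric dose vectors, `>= 3` points,
#'   non-constant `predicted`.
#' @return list with `intercept`, `intercept_se`, `slope`, `slope_se`.
#' @export
calibration_regression <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted), length(actual) >= 3)
  if (stats::var(predicted) == 0) stop("constant predicted doses")
  fit <- stats::lm(actual ~ predicted)
  cf <- summary(fit)$coefficients
  list(intercept = cf[1, 1], intercept_se = cf[1, 2],
       slope = cf[2, 1], slope_se = cf[2, 2])
}

#' Error diagnostics: photon-dose independence and worst-case size
#'
#' Two diagnostics of reconstruction errors: the Pearson correlation
#' between photon dose and the absolute reconstruction error (near zero
#' when neutron reconstruction is undisturbed by even large photon doses),
#' and the median of the five largest absolute errors (the heavy-tail
#' summary of worst cases).
#'
#' @param actual,predicted neutron doses (Gy), length `>= 5`.
#' @param photon_doses photon doses (Gy), same length.
#' @return list with `pearson_photon_abs_error` (`NA` when all errors are
#'   identical) and `top5_mae_median_gy`.
#' @export
error_diagnostics <- function(actual, predicted, photon_doses) {
  stopifnot(length(actual) == length(predicted),
            length(actual) == length(photon_doses), length(actual) >= 5)
  abs_err <- abs(actual - predicted)
  r <- if (stats::var(abs_err) == 0 || stats::var(photon_doses) == 0) {
    NA_real_
  } else {
    stats::cor(photon_doses, abs_err)
  }
  top5 <- stats::median(sort(abs_err, decreasing = TRUE)[1:5])
  list(pearson_photon_abs_error = r, top5_mae_median_gy = top5)
}

#' Repeated random-split robustness evaluation
#'
#' The robustness harness: for each of `n_splits` seeded stratified
#' half-splits of the data, fit the chosen model family on the training half
#' with *fixed, previously tuned* hyperparameters (a single-row grid; no
#' re-tuning inside the loop) and score the testing half. Split `s` uses
#' seed `base_seed + s` for auditability. Per-split R^2, RMSE, calibration
#' coefficients and error diagnostics are returned together with their
#' mean/SD/range aggregates. The study setting is 300 splits.
#'
#' @param features feature matrix with dose columns.
#' @param predictors predictor columns to use.
#' @param family `"random_forest"`, `"xgboost"` or `"robust_linear"`.
#' @param n_splits number of random splits.
#' @param spec a [tuning_spec()] whose `grid` has exactly one row for the
#'   tree families (the frozen hyperparameters); ignored for the linear
#'   family.
#' @param base_seed integer; split `s` uses seed `base_seed + s`.
#' @param fraction training fraction.
#' @return list of class `mn_split_evaluation` with `per_split` (data
#'   frame) and `aggregate` (list of mean/sd/min/max for R^2 and RMSE).
#' @export
repeated_split_evaluation <- function(features, predictors,
                                      family = c("random_forest", "xgboost",
                                                 "robust_linear"),
                                      n_splits = 300,
                                      spec = tuning_spec(),
                                      base_seed = 1, fraction = 0.5) {
  family <- match.arg(family)
  stopifnot(n_splits >= 1)
  if (family != "robust_linear") {
    if (is.null(spec$grid) || nrow(spec$grid) != 1) {
      stop("repeated_split_evaluation needs a single-row grid of frozen ",
           "hyperparameters (tune once, then evaluate)")
    }
  }
  rows <- lapply(seq_len(n_splits), function(s) {
    seed <- base_seed + s
    halves <- split_train_test(features, fraction = fraction, seed = seed)
    sp <- tuning_spec(cv_folds = spec$cv_folds, cv_repeats = 1,
                      grid = spec$grid, num_trees = spec$num_trees,
                      num_trees_cv = spec$num_trees_cv,
                      max_rounds = spec$max_rounds, seed = seed)
    model <- switch(family,
      random_forest = tune_and_fit_rf(halves$train, predictors, sp),
      xgboost = tune_and_fit_xgb(halves$train, predictors, sp),
      robust_linear = fit_robust_linear(halves$train, predictors))
    pred <- reconstruct_dose(model, halves$test)
    sc <- score_predictions(halves$test$neutron_dose, pred)
    cal <- calibration_regression(halves$test$neutron_dose, pred)
    dg <- error_diagnostics(halves$test$neutron_dose, pred,
                            halves$test$photon_dose)
    data.frame(seed = seed, r_squared = sc$r_squared, rmse_gy = sc$rmse_gy,
               calib_intercept = cal$intercept,
               calib_intercept_se = cal$intercept_se,
               calib_slope = cal$slope, calib_slope_se = cal$slope_se,
               pearson_photon_abs_error = dg$pearson_photon_abs_error,
               top5_mae_median_gy = dg$top5_mae_median_gy)
  })
  per_split <- do.call(rbind, rows)
  agg <- function(v) list(mean = mean(v), sd = stats::sd(v),
                          min = min(v), max = max(v))
  structure(list(per_split = per_split,
                 aggregate = list(r_squared = agg(per_split$r_squared),
                                  rmse_gy = agg(per_split$rmse_gy)),
                 family = family, n_splits = n_splits),
            class = "mn_split_evaluation")
}

#' @export
print.mn_split_evaluation <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("%s over %d random splits:\n", x$family, x$n_splits))
  cat(sprintf("  mean R2   %.3f (SD %.3f, range %.3f to %.3f)\n",
              a$r_squared$mean, a$r_squared$sd, a$r_squared$min,
              a$r_squared$max))
  cat(sprintf("  mean RMSE %.3f Gy (SD %.3f, range %.3f to %.3f)\n",
              a$rmse_gy$mean, a$rmse_gy$sd, a$rmse_gy$min, a$rmse_gy$max))
  invisible(x)
}
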