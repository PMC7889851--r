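test_that("scoring matches closed forms", {
  a <- c(0, 1, 2)
  expect_equal(score_predictions(a, a), list(r_squared = 1, rmse_gy = 0))
  # mean-only predictor: R2 = 0, RMSE = population SD
  sc <- score_predictions(a, rep(mean(a), 3))
  expect_equal(sc$r_squared, 0)
  expect_equal(sc$rmse_gy, sqrt(mean((a - mean(a))^2)))
  expect_equal(score_predictions(a, c(0, 1, 3))$rmse_gy, sqrt(1 / 3),
               tolerance = 1e-12)
  expect_warning(sc0 <- score_predictions(c(1, 1, 1), c(1, 2, 3)),
                 "constant")
  expect_true(is.na(sc0$r_squared))
})

test_that("calibration regression recovers identity and scaling", {
  p <- c(0.2, 0.7, 1.1, 1.9, 3.5)
  # exact fits trigger lm's perfect-fit note; the coefficients are the point
  cal <- suppressWarnings(calibration_regression(p, p))
  expect_equal(cal$intercept, 0, tolerance = 1e-12)
  expect_equal(cal$slope, 1, tolerance = 1e-12)
  cal2 <- suppressWarnings(calibration_regression(2 * p, p))
  expect_equal(cal2$slope, 2, tolerance = 1e-12)
  expect_error(calibration_regression(p, rep(1, 5)), "constant")
  # calibrated noisy predictor: slope within 3 SE of 1 in most replicates
  set.seed(13)
  cover <- replicate(100, {
    prd <- runif(60, 0, 4)
    act <- prd + rnorm(60, sd = 0.3)   # noise on the outcome side only
    cl <- calibration_regression(act, prd)
    abs(cl$slope - 1) <= 3 * cl$slope_se
  })
  expect_gt(mean(cover), 0.9)
})

test_that("error diagnostics summarize tails and photon independence", {
  dg <- error_diagnostics(c(1, 2, 3, 4, 5, 6),
                          c(1.1, 2.2, 3.3, 4.4, 5.5, 6.6) - 1e-9,
                          photon_doses = c(0, 1, 2, 3, 4, 5))
  expect_equal(dg$top5_mae_median_gy, 0.4, tolerance = 1e-6)
  z <- rep(0.5, 6)
  dg0 <- error_diagnostics(z, z, photon_doses = 1:6)
  expect_true(is.na(dg0$pearson_photon_abs_error))
  expect_equal(dg0$top5_mae_median_gy, 0)
  # photon dose independent of injected error: correlation near zero
  set.seed(19)
  r <- replicate(200, {
    err <- rnorm(100)
    error_diagnostics(rep(1, 100), 1 + err,
                      photon_doses = runif(100, 0, 15))$pearson_photon_abs_error
  })
  expect_lt(abs(mean(r)), 0.05)
})

test_that("repeated splits are reproducible and aggregate correctly", {
  fm <- sim_features()
  preds <- c("LnVar", "Ln3Frac", "LL_exp_Pois_dif", "LnMean", "LnFD")
  spec <- tuning_spec(grid = data.frame(mtry = 3L, splitrule = "variance",
                                        min.node.size = 1L,
                                        stringsAsFactors = FALSE),
                      num_trees = 300)
  ev <- repeated_split_evaluation(fm, preds, family = "random_forest",
                                  n_splits = 4, spec = spec, base_seed = 50)
  expect_equal(nrow(ev$per_split), 4)
  expect_equal(ev$per_split$seed, 51:54)
  expect_true(all(ev$per_split$rmse_gy >= 0))
  expect_true(all(ev$per_split$r_squared <= 1))
  # aggregates recomputable from the per-split rows
  expect_equal(ev$aggregate$r_squared$mean, mean(ev$per_split$r_squared))
  expect_equal(ev$aggregate$rmse_gy$sd, sd(ev$per_split$rmse_gy))
  ev2 <- repeated_split_evaluation(fm, preds, family = "random_forest",
                                   n_splits = 4, spec = spec,
                                   base_seed = 50)
  expect_identical(ev$per_split, ev2$per_split)
  # singleton aggregation equals the single split
  ev1 <- repeated_split_evaluation(fm, preds, family = "random_forest",
                                   n_splits = 1, spec = spec, base_seed = 50)
  expect_equal(ev1$aggregate$r_squared$mean, ev1$per_split$r_squared[1])
  # tree families demand frozen hyperparameters
  expect_error(repeated_split_evaluation(fm, preds, spec = tuning_spec()),
               "single-row grid")
})

test_that("mean split R2 rises with the simulator's signal strength", {
  r2_at <- function(track_rate) {
    cfg <- sim_config(samples_per_combination = 4,
                      neutron_track_rate = track_rate)
    fm <- compute_feature_matrix(simulate_dataset(cfg, seed = 77))
    spec <- tuning_spec(grid = data.frame(mtry = 3L, splitrule = "variance",
                                          min.node.size = 1L,
                                          stringsAsFactors = FALSE),
                        num_trees = 200)
    ev <- repeated_split_evaluation(fm,
                                    c("LnVar", "Ln3Frac",
                                      "LL_exp_Pois_dif", "LnMean", "LnFD"),
                                    family = "random_forest", n_splits = 3,
                                    spec = spec, base_seed = 7)
    ev$aggregate$r_squared$mean
  }
  r2 <- vapply(c(0.02, 0.18, 0.6), r2_at, numeric(1))
  expect_true(r2[1] < r2[2] && r2[2] < r2[3])
})
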