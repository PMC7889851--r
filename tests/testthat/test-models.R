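# predictors with real signal on the simulated feature matrix
sim_predictors <- c("LnVar", "Ln3Frac", "LnMean", "LnFD",
                    "LL_exp_Pois_dif", "LL_exp_Pois_dif_p", "Frac_2",
                    "SEK")

test_that("split_train_test is disjoint, exhaustive, stratified, seeded", {
  fm <- sim_features()
  h <- split_train_test(fm, fraction = 0.5, seed = 9)
  expect_equal(nrow(h$train) + nrow(h$test), nrow(fm))
  expect_length(intersect(h$train$sample_id, h$test$sample_id), 0)
  expect_equal(abs(nrow(h$train) - nrow(h$test)) <= 6, TRUE)
  # both halves span the dose range (stratification)
  expect_equal(range(h$train$neutron_dose), range(fm$neutron_dose))
  expect_equal(range(h$test$neutron_dose), range(fm$neutron_dose))
  h2 <- split_train_test(fm, fraction = 0.5, seed = 9)
  expect_identical(h$train$sample_id, h2$train$sample_id)
  # two-bin toy case: each half gets one of each dose
  toy <- data.frame(neutron_dose = c(0, 0, 4, 4), x = 1:4)
  ht <- split_train_test(toy, 0.5, seed = 1)
  expect_setequal(ht$train$neutron_dose, c(0, 4))
  expect_setequal(ht$test$neutron_dose, c(0, 4))
  expect_error(split_train_test(fm, fraction = 1.2), "fraction")
})

test_that("tuned RF beats the mean-only predictor and stays in range", {
  fm <- sim_features()
  h <- split_train_test(fm, 0.5, seed = 2)
  spec <- tuning_spec(cv_repeats = 2, num_trees = 500, num_trees_cv = 150,
                      grid = expand.grid(mtry = c(3L, 8L),
                                         splitrule = "variance",
                                         min.node.size = c(1L, 10L),
                                         stringsAsFactors = FALSE),
                      seed = 5)
  m <- tune_and_fit_rf(h$train, sim_predictors, spec)
  expect_s3_class(m, "mn_dose_model")
  expect_true(all(c("mtry", "splitrule", "min.node.size") %in%
                    names(m$chosen_hyperparameters)))
  # training CV RMSE well below the SD of the target doses
  expect_lt(m$training_cv_rmse, 0.6 * sd(h$train$neutron_dose))
  pred <- reconstruct_dose(m, h$test)
  expect_true(all(is.finite(pred)))
  expect_true(all(pred >= 0))
  # RF cannot extrapolate beyond the training dose range
  expect_true(all(pred <= max(h$train$neutron_dose)))
  sc <- score_predictions(h$test$neutron_dose, pred)
  null_rmse <- sqrt(mean((h$test$neutron_dose -
                            mean(h$train$neutron_dose))^2))
  expect_lt(sc$rmse_gy, null_rmse)
  # near-interpolation on its own training rows
  tr_rmse <- score_predictions(h$train$neutron_dose,
                               reconstruct_dose(m, h$train))$rmse_gy
  expect_lt(tr_rmse, sc$rmse_gy)
  # permutation importances stored for every predictor
  expect_setequal(names(m$importance), sim_predictors)
})

test_that("single-combination grids fit directly and deterministically", {
  fm <- sim_features()
  h <- split_train_test(fm, 0.5, seed = 3)
  g <- data.frame(mtry = 4L, splitrule = "variance", min.node.size = 1L,
                  stringsAsFactors = FALSE)
  m1 <- tune_and_fit_rf(h$train, sim_predictors,
                        tuning_spec(grid = g, num_trees = 300, seed = 7))
  m2 <- tune_and_fit_rf(h$train, sim_predictors,
                        tuning_spec(grid = g, num_trees = 300, seed = 7))
  expect_true(is.na(m1$training_cv_rmse))
  expect_identical(reconstruct_dose(m1, h$test),
                   reconstruct_dose(m2, h$test))
})

test_that("boosted trees track RF performance on strong-signal data", {
  fm <- sim_features()
  h <- split_train_test(fm, 0.5, seed = 4)
  mx <- tune_and_fit_xgb(h$train, sim_predictors,
                         tuning_spec(cv_repeats = 1, max_rounds = 300,
                                     grid = data.frame(max_depth = 3L,
                                                       eta = 0.1,
                                                       subsample = 0.8),
                                     seed = 6))
  expect_equal(mx$family, "xgboost")
  px <- reconstruct_dose(mx, h$test)
  scx <- score_predictions(h$test$neutron_dose, px)
  mr <- tune_and_fit_rf(h$train, sim_predictors,
                        tuning_spec(grid = data.frame(
                          mtry = 4L, splitrule = "variance",
                          min.node.size = 1L, stringsAsFactors = FALSE),
                          num_trees = 500, seed = 6))
  scr <- score_predictions(h$test$neutron_dose,
                           reconstruct_dose(mr, h$test))
  expect_lt(abs(scx$r_squared - scr$r_squared), 0.1)
})

test_that("robust linear regression recovers a planted linear model", {
  set.seed(31)
  n <- 300
  x1 <- runif(n, 0, 2); x2 <- rnorm(n)
  y <- 0.5 + 1.5 * x1 - 0.8 * x2 + rnorm(n, sd = 0.2)
  out <- sample(n, 15)                      # 5% gross outliers
  y[out] <- y[out] + rnorm(15, sd = 5)
  df <- data.frame(neutron_dose = y, x1 = x1, x2 = x2)
  m <- fit_robust_linear(df, c("x1", "x2"))
  cf <- coef(m$fit)
  se <- sqrt(diag(vcov(m$fit)))
  expect_lt(abs(cf[["x1"]] - 1.5), 3 * se[["x1"]])
  expect_lt(abs(cf[["x2"]] + 0.8), 3 * se[["x2"]])
  # noiseless data: residuals essentially zero
  df2 <- data.frame(neutron_dose = 1 + 2 * x1, x1 = x1, x2 = x2)
  # noiseless data: the M-scale shrinks to 0, so rlm warns about convergence
  m2 <- suppressWarnings(fit_robust_linear(df2, c("x1", "x2")))
  expect_lt(max(abs(stats::residuals(m2$fit))), 1e-8)
  # collinear design is refused with the column named
  df3 <- df; df3$x3 <- df3$x1
  expect_error(fit_robust_linear(df3, c("x1", "x2", "x3")), "x3")
})

test_that("reconstruct_dose validates inputs and clamps at zero", {
  fm <- sim_features()
  h <- split_train_test(fm, 0.5, seed = 12)
  m <- fit_robust_linear(h$train, sim_predictors)
  expect_error(reconstruct_dose(m, h$test[, 1:5]), "LnVar")
  pred <- reconstruct_dose(m, h$test)
  expect_true(all(pred >= 0))
  # constant features give constant predictions
  const <- h$test[rep(1, 6), ]
  expect_lt(diff(range(reconstruct_dose(m, const))), 1e-10)
})
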