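test_that("worked example histogram reproduces the hand-computed moments", {
  f <- compute_features(c(`0` = 3, `1` = 2, `2` = 1))
  expect_equal(f[["Frac_0"]], 0.5)
  expect_equal(f[["Frac_1"]], 1 / 3)
  expect_equal(f[["Frac_2"]], 1 / 6)
  expect_equal(f[["Ln3Frac"]], 0)
  # M = V = 2/3 exactly, so ln(V/M) = 0
  expect_equal(f[["LnVarMean"]], 0, tolerance = 1e-12)
  expect_equal(f[["LnFD"]], log(1 / 12), tolerance = 1e-12)
  expect_equal(f[["LL_exp_Pois_dif"]], -0.0692, tolerance = 1e-3)
})

test_that("definitional identities hold on arbitrary histograms", {
  for (seed in 1:25) {
    f <- compute_features(cells_to_histogram(random_histogram(seed)))
    expect_equal(unname(f[paste0("Frac_sq_", 0:5)]),
                 unname(f[paste0("Frac_", 0:5)]^2), tolerance = 1e-14)
    expect_equal(f[["LnFD_neg"]], -f[["LnFD"]])
    expect_equal(f[["LnVarMean"]], f[["LnVar"]] - f[["LnMean"]],
                 tolerance = 1e-12)
    expect_equal(f[["LnVar_p"]], exp(f[["LnVar"]])^6, tolerance = 1e-9)
    expect_equal(f[["LnVarMean_p"]], 10 * f[["LnVarMean"]]^6,
                 tolerance = 1e-9)
    expect_equal(f[["Ln3Frac_p"]], 1e6 * f[["Ln3Frac"]]^6, tolerance = 1e-9)
    expect_equal(f[["LL_exp_Pois_dif_p"]],
                 1e6 * f[["LL_exp_Pois_dif"]]^6, tolerance = 1e-9)
    expect_true(all(f[paste0("Frac_", 0:5)] >= 0 &
                      f[paste0("Frac_", 0:5)] <= 1))
    expect_lte(sum(f[paste0("Frac_", 0:5)]), 1 + 1e-12)
  }
})

test_that("two-point symmetric histogram has excess kurtosis -2", {
  f <- compute_features(c(`0` = 1, `1` = 1))
  expect_equal(f[["SEK"]], -2)
})

test_that("every feature matches the brute-force per-cell oracle", {
  for (seed in 1:200) {
    cells <- random_histogram(seed)
    f <- compute_features(cells_to_histogram(cells))
    expect_equal(as.numeric(f), unname(oracle_features(cells)),
                 tolerance = 1e-10,
                 info = paste("histogram seed", seed))
  }
})

test_that("features are representation-invariant (long vs wide input)", {
  cells <- random_histogram(42)
  wide <- cells_to_histogram(cells)
  long_path <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,neutron_dose,photon_dose,mn_count",
               sprintf("s1,0,0,%d", cells)), long_path)
  d_long <- read_mn_dataset(long_path, dialect = "long")
  expect_identical(compute_features(d_long$histogram[[1]]),
                   compute_features(wide))
})

test_that("degenerate histograms are floored and flagged, never NaN", {
  f <- compute_features(c(`0` = 10))        # M = 0, V = 0
  expect_false(any(is.nan(f)))
  expect_setequal(attr(f, "flagged"),
                  c("LnMean", "LnVar", "LnVarMean", "LnFD", "SEK", "LnSkew"))
  # left-skewed sample: m3 < 0 floors LnSkew only
  f2 <- compute_features(c(`0` = 1, `3` = 1, `4` = 8))
  expect_true("LnSkew" %in% attr(f2, "flagged"))
  expect_false(any(is.nan(f2)))
  expect_error(compute_features(c(`0` = 1)), "2 cells")
})

test_that("adding a 5-MN cell to an all-zero sample raises spread metrics", {
  base <- compute_features(c(`0` = 50))
  bumped <- compute_features(c(`0` = 50, `5` = 1))
  expect_gt(bumped[["LnVar"]], base[["LnVar"]])
  expect_gt(bumped[["Ln3Frac"]], base[["Ln3Frac"]])
  expect_gt(bumped[["LnMean"]], base[["LnMean"]])
})

test_that("feature matrix is one row per sample in fixed column order", {
  d <- tiny_dataset()
  fm <- compute_feature_matrix(d)
  expect_equal(dim(fm), c(3, 30))
  expect_equal(names(fm),
               c("sample_id", "neutron_dose", "photon_dose",
                 mn_feature_names()))
  # permuting samples permutes rows only
  fm_rev <- compute_feature_matrix(d[3:1, ])
  expect_equal(fm_rev$sample_id, rev(fm$sample_id))
  expect_equal(unname(as.matrix(fm_rev[, mn_feature_names()])),
               unname(as.matrix(fm[3:1, mn_feature_names()])))
  # empty dataset keeps the full header
  empty <- mn_dataset(character(), numeric(), numeric(), list())
  expect_equal(dim(compute_feature_matrix(empty)), c(0, 30))
  # errors carry sample context
  bad <- mn_dataset("tiny", 0, 0, list(c(`0` = 1)))
  expect_error(compute_feature_matrix(bad), "tiny")
})
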