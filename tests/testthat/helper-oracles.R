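# Brute-force oracles: expand the histogram to an explicit per-cell list and
# compute every quantity naively, independent of the package's histogram
# arithmetic. The log-floor convention (1e-12) mirrors the documented one.

oracle_floor_log <- function(a) log(max(a, 1e-12))

oracle_features <- function(cells) {
  n <- length(cells)
  M <- mean(cells)
  V <- stats::var(cells)
  sd_n <- sqrt(mean((cells - M)^2))
  m3 <- mean((cells - M)^3)
  fr <- vapply(0:5, function(k) mean(cells == k), numeric(1))
  f3 <- mean(cells >= 3)
  klnM <- ifelse(cells == 0, 0, cells * log(M))
  if (M == 0) {
    ll_exp <- ll_pois <- 0
  } else {
    ll_exp <- sum(-(cells + 1) * log(1 + M) + klnM)
    ll_pois <- sum(klnM - M - lfactorial(cells))
  }
  lldif <- (ll_exp - ll_pois) / n
  lnvar <- oracle_floor_log(V)
  lnmean <- oracle_floor_log(M)
  lnfd <- if (M > 0) {
    oracle_floor_log((((n - 1) * V / M - n) / sqrt(2 * n))^2)
  } else oracle_floor_log(0)
  sek <- if (sd_n > 0) mean(((cells - M) / sd_n)^4) - 3 else -3
  lnskew <- if (sd_n > 0) oracle_floor_log(m3 / sd_n^3) else
    oracle_floor_log(0)
  ln3 <- log(1 + f3)
  out <- c(fr, fr^2, log(n), lnmean, lnvar, exp(lnvar)^6, lnvar - lnmean,
           10 * (lnvar - lnmean)^6, log(1 + fr[1]), ln3, 1e6 * ln3^6,
           lnfd, -lnfd, sek, lnskew, lldif, 1e6 * lldif^6)
  names(out) <- mn_feature_names()
  out
}

# random small histogram covering Poisson-ish, heavy-tailed and edge shapes
random_histogram <- function(seed) {
  set.seed(seed)
  n <- sample(5:120, 1)
  cells <- switch(sample(3, 1),
                  stats::rpois(n, stats::runif(1, 0.05, 1.5)),
                  stats::rgeom(n, 1 / (1 + stats::runif(1, 0.1, 1.2))),
                  sample(0:7, n, replace = TRUE,
                         prob = c(8, 4, 2, 1, 1, 0.5, 0.3, 0.2)))
  if (stats::var(cells) == 0) cells[1] <- cells[1] + 1L  # avoid degenerate
  cells
}

cells_to_histogram <- function(cells) {
  tb <- table(factor(cells, levels = 0:max(cells)))
  stats::setNames(as.integer(tb), names(tb))
}

# small deterministic dataset for io/pipeline tests
tiny_dataset <- function() {
  mn_dataset(sample_id = c("s1", "s2", "s3"),
             neutron_dose = c(0, 1, 2),
             photon_dose = c(0.5, 0, 3),
             histograms = list(c(`0` = 3, `1` = 1),
                               c(`0` = 2, `1` = 1, `2` = 1),
                               c(`0` = 5, `2` = 2, `4` = 1)))
}

# compact simulated feature matrix shared across model/evaluation tests
sim_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(samples_per_combination = 6)
      d <- simulate_dataset(cfg, seed = 101)
      cache <<- compute_feature_matrix(d)
    }
    cache
  }
})
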