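#' Canonical predictor names
#'
#' The fixed, documented column order of the 27 engineered MN-distribution
#' predictors.
#'
#' @return character vector of length 27.
#' @export
mn_feature_names <- function() {
  c(paste0("Frac_", 0:5), paste0("Frac_sq_", 0:5),
    "LnSum", "LnMean", "LnVar", "LnVar_p", "LnVarMean", "LnVarMean_p",
    "LnZeroFrac", "Ln3Frac", "Ln3Frac_p", "LnFD", "LnFD_neg",
    "SEK", "LnSkew", "LL_exp_Pois_dif", "LL_exp_Pois_dif_p")
}

# floor for logs of non-positive arguments; tree models are insensitive to
# the exact value, the flag records that the floor was used
.log_floor <- 1e-12

guarded_log <- function(x, feature, flags) {
  if (x <= 0) {
    flags$hit(feature)
    x <- .log_floor
  }
  log(x)
}

#' Compute the 27 engineered predictors for one sample
#'
#' Distribution-shape metrics of the MN-per-cell histogram used as
#' machine-learning predictors of neutron dose:
#' \describe{
#'   \item{Frac_0..Frac_5}{fraction of cells with exactly 0..5 MN;
#'     `Frac_sq_k` are their squares.}
#'   \item{LnSum}{`ln` of the number of scored cells `n`.}
#'   \item{LnMean, LnVar}{`ln` of the sample mean `M` and of the sample
#'     variance `V` (denominator `n - 1`); `LnVar_p = V^6`,
#'     `LnVarMean = LnVar - LnMean`, `LnVarMean_p = 10 LnVarMean^6`.}
#'   \item{LnZeroFrac, Ln3Frac}{`ln(1 + Frac_0)` and `ln(1 + f3)` with `f3`
#'     the fraction of cells carrying 3 or more MN;
#'     `Ln3Frac_p = 1e6 Ln3Frac^6`.}
#'   \item{LnFD}{log squared standardized Fisher dispersion statistic,
#'     `ln([ (1/sqrt(2n)) ((n-1) V / M - n) ]^2)`; `LnFD_neg = -LnFD`.}
#'   \item{SEK}{sample excess kurtosis `(1/n) sum z_i^4 - 3`, `z`
#'     standardized with the n-denominator SD.}
#'   \item{LnSkew}{`ln(m3 / SD^3)` with `m3` the third central moment and
#'     `SD` the n-denominator standard deviation.}
#'   \item{LL_exp_Pois_dif}{per-cell log-likelihood difference of the
#'     discrete-Exponential vs Poisson fit ([ll_exp_pois_dif()]);
#'     `LL_exp_Pois_dif_p = 1e6 LL_exp_Pois_dif^6`.}
#' }
#'
#' Cells with more than 5 MN contribute to `n`, `M`, `V`, `f3` and the
#' moment features but to none of `Frac_0..Frac_5`. Logarithms of
#' non-positive arguments (e.g. `M = 0`, `V = 0`, negative skewness) are
#' floored at `1e-12` and the affected feature recorded in the `"flagged"`
#' attribute rather than returned as `NaN`.
#'
#' @param histogram MN histogram (any form accepted by
#'   [canonical_histogram()]); needs at least 2 cells.
#' @return named numeric vector of length 27 with attribute `flagged`
#'   (character vector of features whose log argument was floored).
#' @export
compute_features <- function(histogram) {
  h <- canonical_histogram(histogram)
  n <- sum(h)
  if (n < 2) stop("at least 2 cells are required to compute features")
  k <- as.numeric(names(h))
  flagged <- character(0)
  flags <- list(hit = function(f) flagged <<- c(flagged, f))

  M <- sum(k * h) / n
  V <- sum(h * (k - M)^2) / (n - 1)          # n-1 sample variance
  Vn <- sum(h * (k - M)^2) / n               # n-denominator variance
  sd_n <- sqrt(Vn)
  m3 <- sum(h * (k - M)^3) / n

  frac <- vapply(0:5, function(j) {
    if (j <= max(k)) sum(h[k == j]) / n else 0
  }, numeric(1))
  f3 <- sum(h[k >= 3]) / n

  out <- numeric(27)
  names(out) <- mn_feature_names()
  out[paste0("Frac_", 0:5)] <- frac
  out[paste0("Frac_sq_", 0:5)] <- frac^2
  out["LnSum"] <- log(n)
  out["LnMean"] <- guarded_log(M, "LnMean", flags)
  out["LnVar"] <- guarded_log(V, "LnVar", flags)
  out["LnVar_p"] <- exp(out[["LnVar"]])^6
  # the LnVar - LnMean identity is kept even when one side was floored
  out["LnVarMean"] <- out[["LnVar"]] - out[["LnMean"]]
  if (M <= 0 || V <= 0) flags$hit("LnVarMean")
  out["LnVarMean_p"] <- 10 * out[["LnVarMean"]]^6
  out["LnZeroFrac"] <- log1p(frac[1])
  out["Ln3Frac"] <- log1p(f3)
  out["Ln3Frac_p"] <- 1e6 * out[["Ln3Frac"]]^6
  if (M > 0) {
    fd_inner <- ((n - 1) * V / M - n) / sqrt(2 * n)
    out["LnFD"] <- guarded_log(fd_inner^2, "LnFD", flags)
  } else {
    flags$hit("LnFD")
    out["LnFD"] <- log(.log_floor)
  }
  out["LnFD_neg"] <- -out[["LnFD"]]
  if (sd_n > 0) {
    out["SEK"] <- sum(h * ((k - M) / sd_n)^4) / n - 3
    out["LnSkew"] <- guarded_log(m3 / sd_n^3, "LnSkew", flags)
  } else {
    # zero-variance sample: kurtosis/skewness moments are undefined
    flags$hit("SEK")
    out["SEK"] <- -3
    flags$hit("LnSkew")
    out["LnSkew"] <- log(.log_floor)
  }
  ll <- ll_exp_pois_dif(h)
  out["LL_exp_Pois_dif"] <- ll$ll_diff_per_cell
  out["LL_exp_Pois_dif_p"] <- 1e6 * ll$ll_diff_per_cell^6
  attr(out, "flagged") <- unique(flagged)
  out
}

#' Compute the predictor matrix for a dataset
#'
#' One row per sample, columns `sample_id`, `neutron_dose`, `photon_dose`
#' followed by the 27 predictors in the order of [mn_feature_names()]. Any
#' degeneracy floors applied per sample are aggregated into the
#' `"degeneracy_log"` attribute (a data frame of sample_id/feature pairs).
#'
#' @param dataset an [mn_dataset()] whose samples all have `>= 2` cells.
#' @return data frame of features with dose columns.
#' @export
compute_feature_matrix <- function(dataset) {
  feats <- lapply(seq_len(nrow(dataset)), function(i) {
    tryCatch(compute_features(dataset$histogram[[i]]),
             error = function(e) {
               stop("sample ", dataset$sample_id[i], ": ",
                    conditionMessage(e), call. = FALSE)
             })
  })
  mat <- if (length(feats)) do.call(rbind, feats) else
    matrix(numeric(0), 0, 27, dimnames = list(NULL, mn_feature_names()))
  out <- data.frame(sample_id = dataset$sample_id,
                    neutron_dose = dataset$neutron_dose,
                    photon_dose = dataset$photon_dose,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(mat))
  degen <- do.call(rbind, lapply(seq_along(feats), function(i) {
    fl <- attr(feats[[i]], "flagged")
    if (length(fl)) data.frame(sample_id = dataset$sample_id[i],
                               feature = fl, stringsAsFactors = FALSE)
  }))
  attr(out, "degeneracy_log") <- degen %||%
    data.frame(sample_id = character(), feature = character())
  out
}
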