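#' Spearman correlation screen
#'
#' First, manual-style screening stage of predictor selection: computes the
#' full Spearman rank-correlation matrix (with pairwise p-values) between
#' all predictors and the neutron and photon doses, then
#' \enumerate{
#'   \item drops predictors whose rank correlation with neutron dose is
#'     weaker than `weak_threshold` in absolute value, and
#'   \item among pairs of surviving predictors with `|rho| >`
#'     `redundancy_threshold`, keeps the member more strongly correlated
#'     with neutron dose.
#' }
#' Constant predictor columns (undefined correlation) are dropped with
#' reason `"constant"`. Every removal is recorded with its reason.
#'
#' @param features feature matrix as from [compute_feature_matrix()]
#'   (columns `neutron_dose`, `photon_dose` and predictors; `sample_id`
#'   ignored if present).
#' @param weak_threshold minimum `|rho|` with neutron dose, in (0,1).
#' @param redundancy_threshold pairwise `|rho|` above which two predictors
#'   are considered redundant, in (0,1).
#' @return list of class `mn_screen` with elements `spearman_rho`,
#'   `spearman_p` (matrices over predictors + doses), `screened_out` (data
#'   frame of predictor/reason), and `retained` (character vector).
#' @export
spearman_screen <- function(features, weak_threshold = 0.20,
                            redundancy_threshold = 0.95) {
  stopifnot(weak_threshold > 0, weak_threshold < 1,
            redundancy_threshold > 0, redundancy_threshold < 1)
  if (nrow(features) < 3) stop("at least 3 samples required")
  pred_names <- intersect(mn_feature_names(), names(features))
  if (!length(pred_names)) {
    pred_names <- setdiff(names(features),
                          c("sample_id", "neutron_dose", "photon_dose"))
  }
  vars <- c(pred_names, "neutron_dose", "photon_dose")
  x <- as.matrix(features[, vars])

  constant <- vapply(pred_names, function(v) stats::var(x[, v]) == 0,
                     logical(1))
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  p <- matrix(NA_real_, length(vars), length(vars),
              dimnames = list(vars, vars))
  for (i in seq_along(vars)) {
    for (j in seq_len(i - 1)) {
      if (!is.na(rho[i, j])) {
        pv <- suppressWarnings(
          stats::cor.test(x[, i], x[, j], method = "spearman",
                          exact = FALSE)$p.value)
        p[i, j] <- p[j, i] <- pv
      }
    }
  }
  diag(p) <- 0

  screened_out <- data.frame(predictor = character(), reason = character(),
                             stringsAsFactors = FALSE)
  drop <- function(v, reason) {
    screened_out <<- rbind(screened_out,
                           data.frame(predictor = v, reason = reason,
                                      stringsAsFactors = FALSE))
  }
  for (v in pred_names[constant]) drop(v, "constant")
  alive <- pred_names[!constant]

  rho_n <- abs(rho[alive, "neutron_dose"])
  weak <- alive[is.na(rho_n) | rho_n < weak_threshold]
  for (v in weak) {
    drop(v, sprintf("weak correlation with neutron dose (|rho| = %.3f)",
                    abs(rho[v, "neutron_dose"])))
  }
  alive <- setdiff(alive, weak)

  # greedy redundancy pruning: visit survivors by decreasing |rho| with
  # neutron dose; drop any later predictor too correlated with a kept one
  alive <- alive[order(-abs(rho[alive, "neutron_dose"]))]
  kept <- character(0)
  for (v in alive) {
    clash <- kept[abs(rho[v, kept]) > redundancy_threshold]
    if (length(clash)) {
      drop(v, sprintf("redundant with %s (|rho| = %.3f)", clash[1],
                      abs(rho[v, clash[1]])))
    } else {
      kept <- c(kept, v)
    }
  }
  structure(list(spearman_rho = rho, spearman_p = p,
                 screened_out = screened_out,
                 retained = kept[order(match(kept, pred_names))]),
            class = "mn_screen")
}

#' Shadow-feature (Boruta-style) predictor ranking
#'
#' All-relevant feature selection by iterative comparison of each
#' predictor's random-forest permutation importance against the importance
#' of "shadow" features — shuffled copies of the predictors, re-created at
#' every iteration. A predictor scores a *hit* in an iteration when its
#' importance exceeds the maximum shadow importance; hits are tested against
#' a Binomial(iterations, 1/2) null with two-sided significance `alpha`,
#' Bonferroni-corrected over predictors. Significantly-better predictors are
#' confirmed; significantly-worse ones are consecutively dropped from
#' subsequent iterations. Predictors still undecided after `max_iter`
#' iterations are treated as rejected (and logged as tentative).
#'
#' The whole procedure is repeated `n_repeats` times from different seeds;
#' each predictor is scored by the median over repeats of its median
#' importance within a repeat, a predictor's final decision is
#' `"confirmed"` when it was confirmed in a majority of repeats, and the
#' retained list is the confirmed predictors ordered by decreasing median
#' importance.
#'
#' @param features feature matrix (as in [spearman_screen()]) or any data
#'   frame of numeric predictor columns.
#' @param target numeric response (neutron dose, Gy); defaults to
#'   `features$neutron_dose`.
#' @param predictors predictor names to rank; defaults to the screen-style
#'   predictor columns of `features`.
#' @param n_repeats number of independent repeats (study setting: 100).
#' @param alpha two-sided significance level for the hit-count test.
#' @param max_iter iteration cap within one repeat.
#' @param num_trees trees per importance forest.
#' @param seed integer seed; the whole procedure is deterministic given
#'   (`seed`, `n_repeats`).
#' @return list of class `mn_boruta`: `importance` (data frame with
#'   per-predictor median importance, decision, times confirmed), `retained`
#'   (ordered character vector; may be empty), `n_repeats`, `alpha`.
#' @export
boruta_rank <- function(features, target = NULL, predictors = NULL,
                        n_repeats = 100, alpha = 0.01, max_iter = 100,
                        num_trees = 500, seed = 1) {
  if (is.null(target)) target <- features$neutron_dose
  if (is.null(predictors)) {
    predictors <- intersect(mn_feature_names(), names(features))
    if (!length(predictors)) {
      predictors <- setdiff(names(features),
                            c("sample_id", "neutron_dose", "photon_dose"))
    }
  }
  stopifnot(n_repeats >= 1, length(target) == nrow(features))
  x <- as.matrix(features[, predictors, drop = FALSE])
  if (anyNA(x) || anyNA(target)) stop("missing values not allowed")

  reps <- lapply(seq_len(n_repeats), function(r) {
    boruta_once(x, target, alpha = alpha, max_iter = max_iter,
                num_trees = num_trees, seed = seed + 7919L * (r - 1L))
  })
  imp_mat <- matrix(vapply(reps, `[[`, numeric(ncol(x)), "median_importance"),
                    nrow = ncol(x))
  med_imp <- apply(imp_mat, 1, stats::median)
  conf_count <- rowSums(matrix(vapply(reps,
                                      function(r) r$decision == "confirmed",
                                      logical(ncol(x))), nrow = ncol(x)))
  decision <- ifelse(conf_count > n_repeats / 2, "confirmed", "rejected")
  imp <- data.frame(predictor = predictors,
                    median_importance = med_imp,
                    times_confirmed = conf_count,
                    decision = decision,
                    stringsAsFactors = FALSE)
  imp <- imp[order(-imp$median_importance), ]
  rownames(imp) <- NULL
  retained <- imp$predictor[imp$decision == "confirmed"]
  structure(list(importance = imp, retained = retained,
                 n_repeats = n_repeats, alpha = alpha),
            class = "mn_boruta")
}

# one Boruta repeat: returns per-predictor median importance over the
# iterations in which the predictor was alive, and a decision
boruta_once <- function(x, y, alpha, max_iter, num_trees, seed) {
  set.seed(seed)
  p <- ncol(x)
  status <- rep("undecided", p)          # undecided / confirmed / rejected
  hits <- integer(p)
  imp_hist <- vector("list", p)
  bonf <- alpha / p
  iter <- 0L
  while (any(status == "undecided") && iter < max_iter) {
    iter <- iter + 1L
    alive <- which(status != "rejected")
    xa <- x[, alive, drop = FALSE]
    shadows <- apply(xa, 2, sample)
    # keep at least 5 shadow columns so the max-shadow null is stable
    while (ncol(shadows) < 5) {
      shadows <- cbind(shadows, apply(xa, 2, sample))
    }
    colnames(shadows) <- paste0("shadow_", seq_len(ncol(shadows)))
    df <- as.data.frame(cbind(xa, shadows))
    fit <- ranger::ranger(y = y, x = df, num.trees = num_trees,
                          importance = "permutation",
                          seed = seed + iter, num.threads = 1)
    imp <- fit$variable.importance
    shadow_max <- max(imp[grepl("^shadow_", names(imp))])
    real_imp <- imp[colnames(xa)]
    for (j in seq_along(alive)) {
      imp_hist[[alive[j]]] <- c(imp_hist[[alive[j]]], real_imp[[j]])
    }
    hit <- alive[real_imp > shadow_max]
    hits[hit] <- hits[hit] + 1L
    und <- which(status == "undecided")
    p_better <- stats::pbinom(hits[und] - 1L, iter, 0.5, lower.tail = FALSE)
    p_worse <- stats::pbinom(hits[und], iter, 0.5)
    status[und[p_better < bonf]] <- "confirmed"
    status[und[p_worse < bonf]] <- "rejected"
  }
  med <- vapply(imp_hist, function(v) {
    if (length(v)) stats::median(v) else NA_real_
  }, numeric(1))
  # tentative-after-cap predictors are treated as rejected
  decision <- ifelse(status == "confirmed", "confirmed", "rejected")
  list(median_importance = med, decision = decision, n_iter = iter,
       tentative = colnames(x)[status == "undecided"])
}

#' @export
print.mn_boruta <- function(x, ...) {
  cat(sprintf("shadow-feature ranking over %d repeats (alpha = %g)\n",
              x$n_repeats, x$alpha))
  cat(sprintf("retained %d of %d predictors\n",
              length(x$retained), nrow(x$importance)))
  print(utils::head(x$importance, 12))
  invisible(x)
}
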