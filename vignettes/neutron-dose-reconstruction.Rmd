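---
title: "Reconstructing neutron dose from micronucleus count distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing neutron dose from micronucleus count distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mndose)
```

## The problem

After a mixed neutron + photon exposure — the scenario expected around an
improvised nuclear device detonation — triage needs the *neutron* component
of the absorbed dose, because neutrons are several-fold more biologically
damaging per gray than photons. The cytokinesis-block micronucleus (CBMN)
assay scores micronuclei (MN) in binucleated lymphocytes and its mean yield
calibrates total dose well, but the mean alone cannot tell radiation
qualities apart.

What does distinguish them is the *shape* of the per-cell MN count
distribution. Sparsely ionizing photons spread damage thinly and
independently across cells, giving near-Poisson counts. A densely ionizing
neutron track deposits its energy in one cell and can produce several MN at
once, so neutron exposure inflates the variance and the tail of the
distribution at a given mean — overdispersion, pushing the distribution
toward a discrete-Exponential (geometric) shape. `mndose` turns that
contrast into a quantitative regression problem: engineer distribution-shape
statistics per blood sample, select the informative ones, and train an
ensemble regressor to map them to neutron dose in Gy.

## The statistics

For a sample of `n` cells with counts `k_i`, mean `M` and variance `V`
(denominator `n - 1`), the 27 predictors of `mn_feature_names()` comprise
the fractions of cells with exactly 0–5 MN and their squares, `ln n`,
`ln M`, `ln V` and power transforms, `ln(1 + Frac_0)`, `ln(1 + f3)` for the
fraction with ≥ 3 MN, the log squared standardized Fisher dispersion
statistic

    LnFD = ln[ ( (1/sqrt(2n)) ((n-1) V / M - n) )^2 ],

sample excess kurtosis and log skewness (both standardized with the
`n`-denominator SD), and the per-cell log-likelihood contrast between the
two one-parameter count models sharing the plug-in mean `M`:

    P_Pois(k) = M^k exp(-M) / k!,     P_Exp(k) = (1 + 1/M)^(-k) / (1 + M)
    LL_exp_Pois_dif = (LLexp - LLPois) / n.

Positive `LL_exp_Pois_dif` means the heavy-tailed model fits better — a
neutron signature; photon-only samples sit at negative values. Several
predictors are monotone transforms of one another by design: a random
forest uses random predictor subsets per tree, so redundant encodings let
the same concept reach more trees.

## Design choices in the feature layer

* **Variance denominators.** `V` uses `n - 1`, consistent with the
  `(n-1)V/M` term inside `LnFD` and with the default of `var()` in R. The
  kurtosis standardization is explicitly defined with the `n`-denominator
  SD, and we use the same SD for the skewness for internal consistency (its
  definition does not pin the denominator down).
* **Plug-in likelihoods.** Both log-likelihoods plug in the sample mean
  rather than maximizing separately. For these two families the MLE of the
  mean *is* the sample mean, so nothing is lost, and the statistic stays a
  closed form.
* **Degenerate samples.** Logs of non-positive arguments (all-zero
  histograms give `M = V = 0`; left-skewed samples give `m3 < 0`; a sample
  with `V/M` ratio exactly at the Poisson expectation zeroes the `LnFD`
  inner term) are floored at `1e-12` and the feature is flagged rather than
  returned as `NaN`/`-Inf`. Tree models are insensitive to the exact floor;
  keeping the matrix complete matters more. Flags are aggregated per run in
  the feature matrix's `degeneracy_log` attribute.
* **Counts above 5 MN** contribute to `n`, `M`, `V`, `f3` and the moment
  features, but to none of `Frac_0..Frac_5`, whose definition stops at 5.

## Predictor selection

Selection is two-stage, both stages computed on the training half only.
The Spearman screen drops predictors with `|rho| < 0.20` against neutron
dose and prunes pairs with `|rho| > 0.95`, keeping the member more
correlated with the target. The source methodology applied this step by
expert inspection of the correlation matrix without publishing thresholds;
0.20/0.95 are this package's defaults, chosen as the conventional
"negligible association" and "effectively duplicated" marks, and both are
arguments of `spearman_screen()`.

The shadow-feature stage (`boruta_rank()`) implements the canonical
all-relevant selection loop: shuffled copies of every live predictor are
appended, a 500-tree random forest scores permutation importance, each real
predictor scores a hit when it beats the *maximum* shadow importance, and
hit counts are tested against Binomial(iterations, 1/2) at two-sided
`alpha = 0.01` with Bonferroni correction across predictors. Rejected
predictors leave the model; the loop stops when nothing is undecided or at
100 iterations, after which still-undecided ("tentative") predictors are
treated as rejected and logged. The whole loop is repeated (100 repeats in
the source methodology) and predictors are ranked by the median over
repeats of their median within-repeat importance — the literal reading of
"median of median importance scores".

## Dose regressors and tuning

The primary model is a 2000-tree random forest (`ranger`), tuned by
exhaustive grid search over `mtry`, `splitrule` (variance or extremely
randomized split points) and `min.node.size`, scored by mean held-out RMSE
over repeated 3-fold cross-validation. CV forests default to 500 trees
(`num_trees_cv`): the RMSE *ranking* of grid points stabilizes well below
the final forest size, and only the winner is refit at 2000 trees.
Comparators are gradient-boosted trees (`xgboost`; depth/learning-rate grid
with early stopping choosing the round count on held-out folds) and a
Huber M-estimation linear baseline (`MASS::rlm`, tuning constant 1.345 —
the conventional 95%-efficiency choice). Predictions are clamped at 0 Gy;
only the linear family can go negative, and the clamp count is reported.

Robustness is assessed by `repeated_split_evaluation()`: hyperparameters
are tuned once on the first training half and *frozen*, then the data are
re-split at random (stratified halving on neutron-dose quantile bins, split
`s` seeded `base_seed + s`) and the model is refit and rescored per split —
300 splits in the source methodology. Reported per split: test `R^2`
(the `1 - SSE/SST` form, not a squared correlation — the two differ
whenever calibration is imperfect), RMSE, the OLS calibration line of
actual on predicted dose, the Pearson correlation between photon dose and
absolute error (a check that photons do not contaminate the neutron
estimate), and the median of the five largest absolute errors. The harness
reuses one retained predictor set across splits, matching the
"previously optimized parameters" framing; re-selection per split can be
had by calling the selection functions inside a loop.

## The simulator

`simulate_dataset()` generates the mixed-field structure the method
exploits, so every stage is testable without access to any proprietary
data. Per cell,

    MN = Poisson(A * (b + a_g Dg + b_g Dg^2))  +  sum over tracks of Poisson(mu),
    tracks ~ Poisson(A * nu * Dn),     A = exp(-s (Dn + Dg)),

i.e. a Poisson photon/background component plus a compound-Poisson
(Neyman type-A) neutron component, both attenuated by a proliferation-loss
factor `A`. The compound mechanism is motivated by track structure: one
neutron track hits one cell and yields a burst of MN, giving
variance/mean `= 1 + mu` for a pure neutron field, while photon-only
samples stay exactly Poisson under thinning. The saturation factor makes
mean MN/cell rise and then fall at high dose, reproducing the reduced
proliferation of heavily damaged cells.

Defaults (`sim_config()`): background 0.06 MN/cell, photon response
`a_g = 0.08`/Gy and `b_g = 0.008`/Gy², track rate `nu = 0.18`/cell/Gy,
burst mean `mu = 1.0` MN/track, saturation `s = 0.15`/Gy; 44 dose
combinations (photons to 15 Gy, neutrons to 4 Gy, no high-high corners) ×
12 replicates; cells per sample log-normal (median ≈ 700, log-SD 0.8)
truncated to [33, 3561]. These were calibrated once so that the simulated
mean MN/cell spans roughly 0.06–0.54 across the design and the per-sample
cell counts match the scale of real automated-scoring CBMN datasets; they
are the package's fixed reference conditions, not tuning knobs. An 18%
gamma contamination of the neutron beam can be switched on via
`neutron_gamma_fraction` (off by default).

What the simulator deliberately omits: donor-to-donor variability, scoring
and imaging artifacts, cell-cycle kinetics, and any dose-rate effects.
Passing tests on simulated data therefore show that the *pipeline* works
when the overdispersion assumption holds — they do not validate the
radiobiology of any particular real dataset.

## Problem sizes used by the test and acceptance runs

The shipped checks run a 616-sample design (44 combinations × 14
replicates), 5 shadow-selection repeats, a 4-point RF grid under 3-fold CV
(100 repeats in the test harness, 25 in the acceptance script), and a
30-split robustness evaluation; the permutation-guard evaluation uses
500-tree forests. These sizes are the package's chosen desk-scale defaults
for reproducible examples; the full-scale settings of the source
methodology (100 selection repeats, full grid, 300 splits, 2000-tree CV)
are all reachable through the same arguments.

## Known limitations

* Random forests cannot extrapolate: estimates never exceed the largest
  training neutron dose, so doses outside the 0–4 Gy design are reported at
  the boundary.
* The discrete-Exponential contrast loses power at low mean MN/cell: at
  `M = 0.3` and 500 cells the per-sample sign is correct ~95% of the time,
  and less at lower means — one reason the ≥ 300-cells-per-sample subset
  performs better.
* The Spearman-screen thresholds are conventions, not published values;
  different choices change the intermediate predictor set, though the
  shadow-feature stage is robust to carrying extra predictors.
* `LnSkew` is undefined for left-skewed samples; the floor-and-flag
  behavior is a package decision for matrix completeness.
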