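# mndose

Quantitative reconstruction of the **neutron dose component** of a mixed
neutron + photon radiation exposure, from the distribution of micronuclei
(MN) per binucleated cell in the cytokinesis-block micronucleus (CBMN)
assay.

## Who this is for

Radiation biodosimetry groups working on triage after large-scale
radiological events (e.g. an improvised nuclear device detonation, whose
field mixes densely ionizing neutrons with photons). Mean MN yield
calibrates *total* dose well but carries no information about radiation
quality. The neutron component matters clinically — neutrons are several
times more damaging per gray — and this package estimates it from the
*shape* of the per-cell MN count distribution.

## The idea

Photon damage spreads thinly and independently over cells, so MN counts in
photon-only samples are close to Poisson,

```
P_Pois(k) = M^k exp(-M) / k! .
```

A neutron track deposits its energy in one cell and can produce a burst of
several MN, which overdisperses the counts toward a discrete-Exponential
(geometric) shape at the same mean,

```
P_Exp(k) = (1 + 1/M)^(-k) / (1 + M) .
```

From each blood sample's histogram the package computes 27 engineered
shape statistics (`mn_feature_names()`): MN-fraction features, log moments,
the log squared standardized Fisher dispersion statistic `LnFD`, excess
kurtosis `SEK`, log skewness, and the per-cell log-likelihood contrast
`LL_exp_Pois_dif = (LLexp − LLPois)/n` between the two models above.
Predictors are screened by Spearman correlation, ranked by a shadow-feature
(Boruta-style) selection loop, and fed to a 2000-tree random forest
(comparators: gradient-boosted trees and a Huber robust-linear baseline)
tuned by repeated 3-fold cross-validation and assessed over hundreds of
random train/test splits. A compound-Poisson simulator of mixed-field CBMN
datasets makes the whole pipeline testable end to end.

See `vignettes/neutron-dose-reconstruction.Rmd` for the model, the design
choices and the simulator's assumptions.

## Worked example

```r
library(mndose)

dataset  <- simulate_dataset(sim_config(samples_per_combination = 6), seed = 42)
dataset
#> mn_dataset: 264 samples, 238,928 cells total
#> provenance: simulated (seed 42, 44 combinations x 6)

features <- compute_feature_matrix(dataset)
halves   <- split_train_test(features, 0.5, seed = 1)
screen   <- spearman_screen(halves$train)
sel      <- boruta_rank(halves$train, predictors = screen$retained,
                        n_repeats = 5, seed = 2)
sel
#> shadow-feature ranking over 5 repeats (alpha = 0.01)
#> retained 11 of 11 predictors
#>            predictor median_importance times_confirmed  decision
#> 1            Ln3Frac        0.20750673               5 confirmed
#> 2    LL_exp_Pois_dif        0.17675117               5 confirmed
#> 3              LnVar        0.16308380               5 confirmed
#> ...

model <- tune_and_fit_rf(halves$train, sel$retained,
                         tuning_spec(cv_repeats = 10, num_trees_cv = 200,
                                     seed = 3))
model
#> mn_dose_model [random_forest], 11 predictors
#> hyperparameters: mtry = 7, splitrule = extratrees, min.node.size = 1, num.trees = 2000
#> training CV RMSE: 0.425 Gy

pred <- reconstruct_dose(model, halves$test)
unlist(score_predictions(halves$test$neutron_dose, pred))
#> r_squared   rmse_gy
#> 0.8437368 0.3426619
unlist(calibration_regression(halves$test$neutron_dose, pred))
#>    intercept intercept_se        slope     slope_se
#>  -0.05497769   0.04580125   1.02698401   0.03849310
```

Reading: on held-out simulated samples the forest explains 84% of the
neutron-dose variance with a 0.34 Gy root-mean-squared error, and the
actual-vs-reconstructed calibration line (intercept −0.05 Gy, slope 1.03)
is statistically indistinguishable from the ideal (0, 1) — reconstruction
is essentially unbiased. The distribution-shape statistics (`Ln3Frac`,
`LL_exp_Pois_dif`, `LnVar`) dominate the importance ranking, as the
overdispersion mechanism predicts.

`run_pipeline(pipeline_config(...))` chains all stages (with a
training-half-only guard on selection and tuning) and can write every
artifact — feature matrix, selection report, model, per-split metrics,
resolved config — to a run directory. A thin command-line wrapper lives at
`inst/cli/mndose.R`.

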