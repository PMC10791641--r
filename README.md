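# trophicstate

Classify lake trophic state from satellite surface reflectance with the
Nutrient-Color Paradigm (NCP).

## The problem

Trophic state — oligotrophic ("blue"), eutrophic ("green"), dystrophic
("brown"), mixotrophic ("murky") — summarizes a lake's productivity and color
regime. The NCP defines it from two in situ measurements: total phosphorus
(TP) and true color, with the quadrant rule

```
state(TP, color) =  oligotrophic   if TP <  30 µg/L and color <  20 PCU
                    eutrophic      if TP >= 30 µg/L and color <  20 PCU
                    dystrophic     if TP <  30 µg/L and color >= 20 PCU
                    mixotrophic    if TP >= 30 µg/L and color >= 20 PCU
```

Field surveys measure TP and color for a few thousand lakes; satellite
archives observe tens of thousands of lakes for decades. This package
transfers NCP labels from surveyed lakes to all lakes with imagery:

1. **Label** — classify in situ visits with the quadrant rule, average
   within-campaign duplicates, merge eutrophic + mixotrophic into `eu/mixo`
   (their spectra are nearly identical from orbit).
2. **Featurize** — per lake-year, median June–August reflectance per band
   (red, green, blue, NIR), normalized by the four-band sum to *relative*
   reflectances `r_b = m_b / Σ m_b`, then z-scored.
3. **Model** — a three-family ensemble (multinomial logistic regression, a
   single-hidden-layer perceptron, gradient boosted trees) evaluated under
   lake-level *spatial* 5-fold cross-validation: all rows of a lake share a
   fold, so test lakes are never seen in training. Early stopping on a
   90:10 class-stratified inner split (patience 20 epochs/rounds).
4. **Ensemble** — per class, the mean and sample variance of the three
   models' probabilities; the categorical call is the argmax of the means.
5. **QC** — confusion/balanced-accuracy metrics, one-vs-rest ROC AUC, exact
   (2⁴-coalition) Shapley feature attributions, Type II sum-of-squares ANOVA
   of lake properties on family × correctness × state, NCP threshold-
   proximity profiles and group-wise state proportions.

A seeded synthetic-data generator emulates the three input tables (in situ
chemistry, per-overpass reflectances, lake attributes) with known ground
truth, so the whole pipeline is testable offline.

## Worked example

```r
library(trophicstate)

cfg <- lts_sim_config(n_lakes = 150, years = c(2007L, 2012L, 2017L), seed = 11)
sim <- simulate_lts_dataset(cfg, campaigns = c(2007L, 2012L, 2017L))
features <- aggregate_overpasses(sim$overpasses)       # lake-year features
tab <- build_training_table(sim$insitu, features, lakes = sim$lakes)
fit <- lts(tab, k = 5, seed = 1)                       # the ensemble
fit
#> Lake trophic-state ensemble classifier
#>   training rows: 431 (145 lakes)   spatial folds: 5   seed: 1
#>   mlr  CV accuracy 0.984   balanced 0.964   macro AUC 0.943
#>   mlp  CV accuracy 0.991   balanced 0.994   macro AUC 0.992
#>   xgb  CV accuracy 0.991   balanced 0.994   macro AUC 0.991
```

Those three lines are pooled held-out metrics on *unseen lakes*: overall
accuracy (confusion-matrix trace over total), macro balanced accuracy
(one-vs-rest (TPR+TNR)/2 averaged over the three classes) and macro
one-vs-rest AUC. The simulation's default conditions are well separated, so
accuracies are high; real archives are much noisier. Predictions for every
lake-year, in the published schema:

```r
head(predict(fit, features)[, 1:6], 4)
#>   Hylak_id year categorical_ts mean_prob_dys mean_prob_eumixo mean_prob_oligo
#> 1        1 2007        eu/mixo   0.008297386        0.9812322     0.010470473
#> 2        1 2012        eu/mixo   0.008466079        0.9802659     0.011267979
#> 3        1 2017        eu/mixo   0.007873009        0.9833279     0.008799122
#> 4        2 2007        eu/mixo   0.013831061        0.9685906     0.017578382
```

`mean_prob_*` average the three models; `var_prob_*` (columns 7–9) expose
their disagreement so users can filter predictions by confidence.
Within-summer stability of revisited lakes:

```r
transition_summary(sim$insitu)
#> Within-summer trophic state transitions (45 multiply-sampled lake-campaigns)
#>   stable: 82.2%
```

The whole run is also available as one seeded, logged call
(`lts_run(lts_pipeline_config(out_dir = "run1", seed = 1))`) or from a shell
via `inst/scripts/run_pipeline.R --config config.yaml`.

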