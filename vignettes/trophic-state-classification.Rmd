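---
title: "Classifying lake trophic state from satellite reflectance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying lake trophic state from satellite reflectance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trophicstate)
```

## The classification problem

Lake trophic state summarizes a lake's characteristic productivity and color
regime. The Nutrient-Color Paradigm (NCP) crosses two in situ axes — total
phosphorus (TP, a nutrient/productivity proxy, in micrograms per liter) and
true color (a colored-dissolved-organic-matter proxy, in platinum-cobalt
units, PCU) — into four quadrants: oligotrophic ("blue": low TP, low color),
eutrophic ("green": high TP, low color), dystrophic ("brown": low TP, high
color) and mixotrophic ("murky": high on both axes).

This package classifies lakes on those axes from space. Field campaigns
measure TP and color for a few thousand lake visits; satellite archives carry
four-band (red, green, blue, near-infrared) surface reflectance for tens of
thousands of lakes over decades. The package links the two: in situ
measurements define reference trophic states, per lake-year summer
reflectance summaries become predictors, and an ensemble of three classifiers
transfers the labels to every lake-year with imagery.

## The labeling rule

`classify_ncp()` applies TP and color cutoffs of 30 µg/L and 20 PCU. The
literature rule describes "low" as strictly below a cutoff and "high" as
strictly above it, which leaves values exactly on a threshold unassigned. We
close the rule by counting a value **at or above** the threshold as high; the
boundary has measure zero in practice and the rule becomes total and
deterministic, which matters for property testing. `merge_eumixo()` collapses
eutrophic and mixotrophic into a single `eu/mixo` class because their
spectral signatures are nearly indistinguishable from orbit, giving the
three-state vocabulary (`dys`, `eu/mixo`, `oligo`, fixed in this alphabetical
order for every probability matrix the package emits).

Lakes visited twice within a campaign are averaged (`average_duplicates()`,
unweighted mean of TP and of color, earliest visit date kept) — justified by
`transition_summary()`, which shows that the large majority of revisited
lakes keep one state within a summer, and that those that change sit near the
NCP thresholds.

## From overpasses to predictors

For each lake-year, `aggregate_overpasses()`:

1. keeps records dated June–August (the a-priori summer window;
   configurable via `summer_months`);
2. takes the per-band **median** over the surviving records (robust to
   residual cloud/glint outliers);
3. divides each band median by the sum of the four — the *relative*
   reflectance vector, which sums to 1 and captures spectral shape rather
   than brightness;
4. records `n_images`, the summer record count. A lake-year with no summer
   image is dropped (count reported via attribute); we emit rows with
   `n_images >= 1` and export the column so users can filter harder.

Normalization happens **after** the median, following the stated order of
operations of the upstream protocol. `zscore_fit()`/`zscore_apply()`
standardize the four relative bands; the scaler is fit on the labeled
training table only and reused unchanged for prediction data, which prevents
information leakage from the prediction set into the predictors.

## The model ensemble

`lts()` fits up to three families on the four z-scored relative bands:

- **`mlr`** — multinomial logistic regression (via `nnet::multinom`),
  unpenalized, fit to convergence;
- **`mlp`** — a single-hidden-layer perceptron implemented in the package:
  ReLU hidden layer, softmax output, categorical cross-entropy loss, Adam
  updates on shuffled mini-batches of 32, early stopping when validation
  loss fails to improve for 20 consecutive epochs (weights from the best
  epoch are kept). The hidden-layer width and learning rate are the tuned
  values 20 and 0.001; the searched grid is {5, 10, 20} × {0.01, 0.001,
  0.0005};
- **`xgb`** — gradient boosted trees (via `xgboost`), multiclass softmax
  objective, early-stopped on validation log-loss with 20-round patience.
  Tuned values: depth 4, subsample 0.5, column sample 0.5, step size 0.01,
  minimum child weight 1, from the grid {2, 3, 4} × {0.5, 0.8}² ×
  {0.01, 0.1} × {1, 3}.

Where a tuning protocol mentions "hidden layers" of 5, 10 or 20 alongside an
optimum of "20 hidden units", we read the grid as the **width of one hidden
layer**; a 20-layer network over four predictors is neither tractable nor
consistent with the tuning summary. The optimizer, batch size and activation
are not dictated by the protocol; ReLU + Adam + batch 32 are the standard
modern defaults and are documented here as this package's choice.

### Spatial cross-validation

Model evaluation uses lake-level grouped 5-fold cross-validation
(`make_spatial_folds()`): lakes — not rows — are partitioned, so a lake
observed in several campaign years never straddles the train/test boundary
and test metrics describe genuinely unseen lakes. Inside each fold's training
part, a 90:10 class-stratified split (`stratified_holdout()`) supplies the
early-stopping validation set. Pooled held-out predictions cover every row
exactly once; the no-leakage property is asserted at run time on every fold.
The final full-data models (`finalize_model()`) reuse the tuned
hyperparameters and train for a fixed budget — the rounded **median** of the
per-fold best epochs/rounds (the aggregation rule is not dictated upstream;
the median is robust to one divergent fold). The logit needs no budget and is
refit to convergence.

### Ensembling

`ensemble_predictions()` averages the three families' class probabilities per
lake-year and reports their **sample** variance (divisor n − 1 = 2; the
divisor is documented and trivially convertible). The categorical call is the
argmax of the means; exact ties — measure zero with continuous probabilities
— break by the fixed precedence `eu/mixo` > `oligo` > `dys`. Output tables
follow the published schemas exactly (`write_lts_outputs()`), keyed by
(`Hylak_id`, `year`).

## The synthetic-data generator

Real training data require multi-gigabyte external downloads, so the package
carries a generator (`lts_sim_config()`, `simulate_lakes()`,
`simulate_insitu()`, `simulate_overpasses()`) that emulates the three input
tables with known ground truth. Its defaults are fixed study conditions, not
tuning knobs:

- **Class mix** 35% oligotrophic, 40% eutrophic, 10% dystrophic, 15%
  mixotrophic — eutrophic and oligotrophic lakes common, dystrophic rare, as
  in temperate-lake surveys.
- **Chemistry**: per-state lognormal TP and color; medians 12/80/15/90 µg/L
  and 8/10/60/55 PCU (oligo/eu/dys/mixo), log-sd 0.30. Medians sit well
  inside their NCP quadrants; the log-sd puts roughly 1% of draws across a
  threshold, so labels carry a little realistic noise.
- **Spectra**: per-state mean relative signatures encoding the qualitative
  ordering reported for real lakes — oligotrophic blue > green > red ≥ NIR;
  eutrophic/mixotrophic green > red > blue > NIR; dystrophic NIR > red >
  green > blue. Raw band values are `raw_scale` (1000) times the signature
  plus Gaussian noise (sd 25), truncated at zero.
- **Cadence**: Poisson summer overpass counts with era means 3.04 (1984–1998,
  one sensor), 5.64 (1999–2012) and 5.42 (2013–2020; the 2013–2019 mean is
  reused because no 2020-specific figure exists), plus Poisson(1) off-summer
  records to exercise the summer filter. Spatial variation in the rate is
  not modeled.
- **Campaign structure**: one visit per lake per campaign; 10% of lakes are
  revisited within the summer; 14.9% of revisited lakes transition state
  before the second visit, with destinations weighted the way changing lakes
  move in surveys (predominantly toward eutrophic/mixotrophic; the merged
  eu/mixo class only ever transitions to oligotrophic).
- **Attributes**: lognormal area and depths, normal elevation, shoreline
  development ≥ 1, and a generic `group_label` standing in for an ecoregion.
  These are plumbing for the diagnostic battery, not claims about real lakes.

What the generator does **not** emulate: sensor changes and harmonization
artifacts, cloud/ice/shadow contamination, bottom and adjacency effects in
shallow or small lakes, spatial autocorrelation among neighboring lakes, and
secular trends. Passing tests on synthetic data therefore demonstrate that
the pipeline's logic is correct and that it recovers known structure — not
that real-data accuracy will match the clean-simulation numbers, which are
far higher than what heterogeneous national archives yield.

The default conditions are deliberately well-separated: with signature gaps
of 0.06–0.2 in relative units and noise sd 0.025 of the raw scale, the
classes are recoverable at ≥ 95% accuracy, and with every noise source off
(`spectra_noise_sd = 0`, `tp_sdlog = 0`, `color_sdlog = 0`,
`transition_prob = 0`) recovery must be exact — the zero-noise limit is the
pipeline's identifiability check. The "zero-noise" condition switches off
chemistry noise too: with spectral noise alone removed, threshold-crossing
chemistry draws would still mislabel about 1% of training rows and exact
recovery would be impossible by construction.

## The diagnostic battery

- `confusion_and_accuracy()`: overall accuracy is the confusion-matrix trace
  over the total; balanced accuracy is implemented one-vs-rest as
  (TPR + TNR)/2 per class plus an unweighted macro mean — the standard
  normalized reading of "sum of true positive and true negative results".
- `roc_auc_ovr()`: one-vs-rest AUC through the midrank Mann–Whitney
  statistic (ties counted 1/2), macro-averaged without class weights. The
  tests pin it to an O(n²) pairwise-comparison oracle.
- `shap_exact()`: with only four predictors, Shapley attributions are
  computed exactly by enumerating all 16 coalitions, with absent features
  marginalized interventionally over a seeded background sample (default 200
  training rows). No sampling approximation is involved; efficiency, dummy
  and symmetry hold by construction and are asserted in tests. Attributions
  are computed on class probabilities (not logits).
- `anova_type2()`: Type II sums of squares for additive (no-interaction)
  models of log-transformed lake properties on model family, correctness and
  trophic state, via `car::Anova` on an `lm` fit; the test suite pins every
  factor's SS to the defining residual-sum-of-squares difference computed
  from scratch. The log transform uses the natural log and refuses
  non-positive responses rather than offsetting them; p values are reported
  unadjusted, for use against a fixed α.
- `ncp_misclassification_profile()`: medians, ranges and threshold distances
  of TP and color by correctness stratum, plus the fraction of each stratum
  inside boundary bands (defaults 15–45 µg/L, 11–29 PCU).
- `group_proportions()`: per (group, year, state) composition from predicted
  and reference sources with signed/absolute differences, with and without a
  minimum-lakes-per-group filter (default 10).

## Numerical choices and degenerate inputs

- Class columns are always ordered `dys`, `eu/mixo`, `oligo`; probability
  rows are softmax/tree outputs and sum to 1 within 1e−6 (asserted).
- An all-zero median spectrum cannot be normalized; such rows are excluded
  and counted, never imputed. A zero-variance band makes z-scoring
  impossible and is an error naming the band.
- Determinism: every stochastic step (simulation, folds, splits, MLP
  initialization and batching, xgboost with `nthread = 1`) is seeded; one
  global seed derives per-stage seeds by fixed offsets. Two runs with the
  same configuration produce byte-identical artifacts.
- Problem sizes in the test battery (500 lakes × 3 campaigns for end-to-end
  recovery, 10,000 lake-years for cadence checks, n ≤ 500 for quadratic
  oracles) were chosen as the smallest scales at which the statistical
  checks have adequate power.

## Known limitations

The package classifies from four relative bands only — no temporal, spatial
or morphometric predictors — matching the upstream design but leaving known
failure modes in place: shallow clear lakes with bright lakebeds imitate
productive spectra, and dystrophic lakes (rare and spectrally close to
oligotrophic ones) remain the hardest class. The generator's clean
class-conditional world cannot surface those effects; they must be studied
on real archives. Upstream image processing (water masking, cloud filtering,
Chebyshev-center extraction) is out of scope: the package starts from the
tabular per-overpass reflectance records such processing produces.
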