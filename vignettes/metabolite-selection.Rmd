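---
title: "Genetic-algorithm selection of metabolite panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic-algorithm selection of metabolite panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Untargeted LC-MS lipidomics yields hundreds of metabolite features per serum
sample. In a cohort spanning the type 2 diabetes progression — Control,
Prediabetes, T2DM, diabetic nephropathy (DN) — the question is which small
panel of metabolites separates each consecutive pair of stages, and which
metabolites keep reappearing across stage pairs. Metabolites recurring in
several pairwise comparisons are the interesting ones: their discriminative
value persists along the progression, which is what one wants from a
progression biomarker.

`metaboga` implements this analysis as a wrapper feature selection: a
genetic algorithm (GA) searches the space of fixed-size metabolite subsets,
scoring each subset by the cross-validated accuracy of a classifier trained
on it alone. Three classifiers serve as interchangeable fitness functions —
k-nearest neighbours (KNN), nearest centroid (NEARCENT) and a radial-kernel
SVM — and the analysis is run per stage comparison and per classifier,
15 runs in all.

## Pipeline

`run_pipeline()` chains the stages:

1. **Inclusion filtering** (`apply_inclusion()`): samples must carry one of
   the four recognized stage labels and a complete metabolite profile; every
   exclusion is logged with its rule.
2. **Probabilistic quotient normalization** (`pqn_normalize()`): each
   sample's per-feature quotients against a reference spectrum are
   aggregated into one most-likely quotient that estimates the sample's
   dilution; the sample is divided by it. Normalization runs once on the
   full table, before any splitting.
3. **Comparison splits** (`make_comparisons()`): the five two-class
   sub-datasets Control-Prediabetes, Control-T2DM, Prediabetes-T2DM,
   Control-DN, T2DM-DN.
4. **GA blast** (`run_blast()`): many independent "bigbang" searches per
   comparison and classifier; final chromosomes are aggregated into gene
   frequencies and a gene rank.
5. **Forward selection** (`forward_select()`): nested models built by
   adding features in rank order; the smallest model within a tolerance of
   the accuracy maximum is the reported, "most compact and accurate" model.
6. **Intersections** (`within_comparison_sets()`, `cross_comparison()`):
   metabolites common to the three classifiers' models within a comparison,
   and metabolites recurring in two or more comparisons (the progression
   candidates).

```{r, eval = FALSE}
library(metaboga)
ds <- generate_dataset(synthetic_spec(seed = 1))
res <- run_pipeline(ds, pipeline_config(bigbangs = 50, seed = 1),
                    out_dir = "report")
res$summary
res$cross$progression_candidates
```

## The fitness function

Fitness of a chromosome (a set of `chromosome_size = 5` distinct feature
indices) is the mean held-out accuracy of the classifier restricted to
those features over a stratified `n_splits x n_repeats` cross-validation
(default 5 x 4, seeded and therefore deterministic). Two data-scale
decisions sit inside this contract:

* **Log scale.** Intensity matrices are `log1p`-transformed before
  anything else. LC-MS intensities are log-normal; on the raw scale the
  heavy right tail dominates Euclidean distances and drags class centroids,
  which measurably degrades nearest-centroid accuracy on features that are
  cleanly separated on the log scale. Matrices containing negative values
  are assumed already transformed and pass through.
* **Per-fold standardization.** Features are z-scored using training-fold
  statistics only, so no test-fold information leaks into distances.

Classifier defaults: KNN uses `k = 3` (small odd k avoids vote ties in
binary problems); vote ties that can still arise for even k break by nearer
summed distance, then lexicographically smaller label. The SVM uses cost 1
and, unless given, a kernel width from the median heuristic on pairwise
training distances. Leave-one-out CV is available (`n_splits` = class size)
but not the default, as it is prone to optimistic selection on small
cohorts.

## GA settings

Headline defaults are the standard GALGO-style configuration: 5-feature
chromosomes, goal fitness 1 (a search stops as soon as a subset classifies
every held-out sample correctly), 200 generations, 2100 bigbangs,
population 50, per-gene mutation rate 0.05, 2 elites,
fitness-proportional (roulette) parent selection, uniform gene crossover
with duplicate repair. Elitism makes the best-so-far fitness non-decreasing
within a search. One documented seed-splitting rule (a master seed spawns
one child seed per bigbang) makes reduced-bigbang runs exact prefixes of
full runs.

Two engineering points matter in practice:

* **Fitness caching.** Identical subsets recur constantly across bigbangs;
  fitness is memoised on the sorted gene set. This cannot change any result
  and is what makes thousands of bigbangs tractable.
* **Many short searches beat few long ones for ranking.** The gene rank is
  built from the best chromosome of each bigbang. Long, strongly converged
  searches concentrate frequency mass on a few genes and let hitchhiking
  noise genes into every solution; many short searches sample more
  independent near-optima and rank redundant discriminative features more
  faithfully. Desk-scale analyses in the tests therefore use on the order
  of 50 bigbangs x 10 generations with a population of 30.

## Forward selection and reporting

The size curve evaluates the top-s ranked features for s = 1..`max_size`
(default 30, above the largest published panel of 28). `chosen_size` is the
smallest s whose accuracy is within `tolerance` (default 0.01 absolute) of
the curve maximum; exact ties go to the smaller model. `best_models_table()`
flags the best classifier per comparison, ties shared. Metabolite identity
in intersection reports is exact string match after whitespace
normalization plus one healing rule — a dot between word characters becomes
a space — because published tables occasionally carry that formatting
artifact ("Butyl.methacrylate"). Names with genuine decimal points would be
altered; lipid nomenclature does not use them.

## The synthetic cohort generator

No public cohort exists for this analysis, so `generate_dataset()` draws
one with the statistical structure the method assumes: 20 samples per
stage, 717 metabolite features, log-normal intensities around per-feature
baseline log-means (N(12, 1.5)), per-sample dilution factors uniform in
[0.5, 2], and planted features whose mean log-intensity shifts between the
two stages of a comparison. The default planted map shares five lipid
species between two or more comparisons — mimicking how genuine progression
biomarkers recur — and tops up each comparison to five planted features.

Chosen-once defaults, with rationale:

* `noise_sd = 0.1` log-units. Feature tables of this kind have passed a QC
  relative-standard-deviation filter (RSD > 20% removed), leaving roughly
  10% technical CV on retained features. This figure deliberately models a
  clean, QC-filtered table; real biological between-subject variation is
  larger, and properties that depend on noise (notably dilution recovery
  below) degrade gracefully as it grows.
* `effect = 0.3` log-units (about a 35% fold change, 3 SD at that noise), a
  typical magnitude for reported serum lipid markers.
* Ground truth (planted map, dilution factors) is returned alongside the
  table and written only to a JSON sidecar, never into the data file.

What the generator does **not** emulate: correlated lipid families, batch
and run-order drift, missing values, heteroscedastic noise, annotation
ambiguity. Passing recovery tests on this generator shows the machinery is
correct under its assumptions, not that the method would perform equally on
a real cohort.

## Numerical choices and degenerate inputs

* PQN reference and quotient aggregation each default to the **median**
  (the standard robust choice); the mean is selectable for both. Under pure
  dilution with no group effects the mean/mean variant is the more
  efficient estimator — the median carries the usual ~1.25 asymptotic
  efficiency penalty, which matters because the quotient error scales as
  `sd(log-noise)/sqrt(n_features)` and the 1%-recovery checks sit near that
  scale. The median defaults are kept because robustness matters exactly
  when group effects and outliers exist.
* PQN quotients are exactly idempotent only for exactly multiplicative
  (noise-free) profiles; on noisy data a second pass changes quotients by
  an amount on the order of the per-sample estimation error.
* Features with zero reference intensity are excluded from quotients with
  a warning; a sample with no usable nonzero feature is an error.
* Constant features inside a CV fold get unit scale instead of dividing by
  zero. Gene-rank ties, including the all-zero-frequency tail, break by
  feature index so reports are deterministic.
* The rank-stability dispersion of a feature is the SD of its rank over the
  trailing window of per-bigbang snapshots; it is exactly zero only once
  the set of features with nonzero frequency has stopped growing.

## Problem sizes in the test-suite

The structural and recovery checks run at desk scale, chosen so the whole
suite stays interactive: GA recovery uses a 40 x 100 two-stage cohort with
five planted features at 2 SD effect, 50 bigbangs x 10 generations,
population 30, 5-fold x 2 CV; the exhaustive-oracle comparison enumerates
all 220 3-of-12 subsets; pipeline determinism runs the full 80 x 717
default cohort with 2 bigbangs x 2 generations. The headline configuration
(2100 bigbangs x 200 generations) is the package default and runs the same
code paths.

## Known limitations

* Binary comparisons only; no multi-class staging model.
* Accuracy is the sole fitness and validation metric, by design; no AUC or
  probability calibration.
* The GA is a stochastic search: at full scale it reliably ranks
  discriminative features, but individual runs are only reproducible under
  a fixed master seed, and the published 2100-bigbang setting is
  computationally substantial on a single core.
* Intersection logic matches metabolite names as strings; it cannot
  reconcile annotation synonyms.
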