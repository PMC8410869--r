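---
title: "Projecting plankton diversity under climate change: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting plankton diversity under climate change: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package models

`plankdiv` estimates present and end-of-century habitat suitability for
marine phyto- and zooplankton species from presence-only occurrence
records and monthly gridded environmental climatologies, and derives
from the stacked suitabilities the community-level quantities that
matter for climate-impact assessment: potential species richness (SR),
its projected percentage change, the replacement (true turnover) and
nestedness components of temporal beta diversity, co-occurrence
association networks, range-shift velocities, and a severity
regionalisation of the combined change signal.

The core modelling assumptions are the standard ones of correlative
species distribution modelling (SDM) at macroecological scale:

* species ranges are not dispersal-limited at the scale of ocean
  basins, so the realised environmental niche can be estimated from
  occurrences pooled across decades;
* distributions are primarily shaped by environmental conditions, with
  biotic interactions leaving a comparatively small imprint at 1-degree
  to 10-degree grain;
* niches are conserved over the projection horizon, so a model trained
  on contemporary conditions can be pushed through future forcing.

Because only presences are available, pseudo-absences ("background")
must be simulated, and the way they are placed controls how survey bias
enters the model. The package uses the target-group approach: a
species' background is drawn from the sites where the wider taxonomic
group was sampled, stratified along the SST and mixed-layer-depth
gradients so that stratum weights mirror the survey-effort
distribution. Absences are then "absences given that someone looked".

## The pipeline, stage by stage

1. **Quality control** (`filter_occurrences()`): records are dropped, in
   a frozen order, for missing coordinates, incomplete dates, years
   before 1800, missing depths, non-species-level names, fossil or
   sediment sources, salinity below 20 (brackish seas), bathymetry
   shallower than 200 m (shelf), and net tows deeper than 500 m. The
   per-step removal counts are order-dependent; the filter report makes
   the order explicit instead of hiding it. Duplicates (same species,
   depth, date and 0.25-degree cell) are removed first-wins, and the
   survivors are binned to monthly grid presences: a species' "presence
   count" everywhere downstream is its number of distinct (cell, month)
   pairs.
2. **Predictors** (`derive_predictors()`): nitrate excess
   N\* = NO3 − 16·PO4, silicate excess Si\* = Si(OH)4 − NO3, the annual
   SST range dSST (per-cell max − min over months), mixed-layer PAR
   under exponential attenuation, eddy kinetic energy
   EKE = ½(u'² + v'²), and log-transformed skewed fields.
   `screen_collinearity()` computes Spearman correlations at the
   presence points and, above |ρ| = 0.70, drops the member of a pair
   whose distribution is further from normal. The eight final predictor
   sets (four per trophic group) are frozen constants
   (`predictor_sets()`).
3. **Background and training sets** (`stratify_environment()`,
   `draw_background()`): ten background sites per presence, allocated
   across SST × MLD strata by largest-remainder rounding, never on the
   focal species' own presences; presences carry weight 1 and background
   rows weight n_presence/n_background, so both classes carry equal
   total weight.
4. **The SDM ensemble** (`run_sdm_design()`): four families — a
   binomial-logit GLM with linear+quadratic terms and bidirectional
   stepwise selection, a binomial GAM with basis-dimension-5 splines and
   no interactions, a 750-tree probability random forest with terminal
   node size 10 and ⌊p/3⌋ candidate variables per split, and a
   single-hidden-layer neural network whose size and weight decay are
   chosen by 5-fold cross-validation (≤200 iterations). Each species ×
   family × predictor set is evaluated over ten stratified 80/20
   splits with TSS (max over 0.01-step thresholds of
   sensitivity + specificity − 1) and rank-statistic AUC. Species are
   retained when mean TSS is strictly above 0.30 and presences number at
   least 75 (the presence rule is frozen inclusive: 75 presences against
   5–6 predictors keeps the presence-to-predictor ratio near 15).
5. **Projection** (`apply_delta()`, `project_hsi()`,
   `stack_richness()`): future climatologies are built by the delta
   method — observed fields plus (ESM future − ESM baseline) monthly
   anomalies on the linear scale, derived predictors recomputed
   afterwards. dSST follows its own rule: its delta is the difference
   between the ESM's annual ranges, added to the observed annual range.
   Suitability is predicted per member (averaging the ten split fits),
   summed over species into monthly SR and annually averaged over the
   months with data (the winter-gap convention). The present ensemble
   has 4 × 4 = 16 members; the future one, with five forcing models,
   4 × 4 × 5 = 80.
6. **Change statistics** (`ensemble_change()`,
   `turnover_ensemble()`, `score_associations()`): per-cell member-level
   %ΔSR with ensemble mean/median/IQR/sd, sign-agreement stippling at
   90%, and main-effect variance shares across the member factorial;
   the temporal Jaccard dissimilarity partitioned exactly into
   replacement (β~jtu~ = 2·min(b,c)/(a+2·min(b,c))) and nestedness
   (β~jne~ = β~jac~ − β~jtu~) over SDM-specific threshold ranges; and
   signed Dunning G² co-occurrence scores with the 75th-percentile
   significance rule and present/future interactome comparison.
7. **Diagnostics** (`mte_fit()`, `range_shift()`,
   `severity_cluster()`, `weighted_trait_structure()`,
   `service_overlap_tests()`): metabolic-theory slopes of ln(SR) against
   1/(kT); suitability-weighted range centroids, haversine shift
   distances and velocities; PCA + k-medoids severity regions with
   Calinski–Harabasz/silhouette profiles; HSI-weighted community trait
   medians; and Kruskal–Wallis / pairwise-Wilcoxon (Bonferroni) overlap
   tests against ecosystem-service covariates.

## The synthetic world

Real occurrence archives and climatologies are bulky, access-limited
and slow; every stage of the package is therefore exercised against a
synthetic world with known ground truth (`generate_environment()`,
`generate_species()`, `sample_occurrences()`,
`generate_future_anomalies()`).

What it emulates: a latitudinal SST gradient with hemisphere-phased
sinusoidal seasonality; nutrients, chlorophyll and oxygen coupled to
temperature at realistic strengths (pairwise |ρ| ≈ 0.6–0.9, achieved by
adding eastern-boundary-style upwelling bands and independent
cell-level noise so no field is a pure function of latitude); species
with product-of-Gaussian niches whose centres sit inside the observed
environmental range; spatially and seasonally biased sampling effort
(uniform-plus-bump mixture mimicking North-Atlantic oversampling); a
configurable contamination rate of records designed to be caught by
each QC rule; and additive future anomalies with per-pseudo-ESM
amplitudes, emulating the spread of climate sensitivities across
forcing models.

What it does not emulate: ocean dynamics, real basin geometry and land,
taxonomic error structure, the empirical density distribution of OBIS-
or GBIF-style archives, or abundance. Passing recovery tests on this
world therefore demonstrates that the estimators are correct and
recover planted structure under realistic bias and collinearity — not
that any particular real-world number is reproduced.

Default generator conditions (chosen once, as the package's study
conditions): equator-to-pole annual-mean SST from 29 °C to −1 °C,
polar seasonal amplitude 4 °C, SST cell noise sd 0.5 °C; the noise is
cell-level (month-constant) so a zero seasonal amplitude yields exactly
zero annual SST range, giving the null-forcing tests a clean zero.
Species niche breadths default to 8–20% of the observed predictor
range; size–temperature coupling is a Gaussian copula with rank
correlation −0.5 ("warm means small").

## Numerical choices and frozen conventions

These points were genuinely open in the design and are frozen here for
reproducibility:

* **Grid membership** is half-open [west, east) × [south, north), with
  longitudes wrapped into the grid span; a record at exactly the north
  edge is out of bounds and dropped with a warning.
* **Net-depth fallback**: the maximal net depth is used when present,
  the average depth otherwise; the phytoplankton QC profile disables
  the net-depth rule (those datasets are pre-restricted to the mixed
  layer). The fossil/sediment keyword list is configurable
  (`qc_rules()`), since no canonical list exists.
* **Collinearity tie-break**: "closest to normal" is measured as
  |skewness| + |excess kurtosis|; logs are natural (base 10 available
  by option) with a 10⁻⁶ floor before logging. The mixed-layer PAR
  attenuation coefficient defaults to 0.1 m⁻¹ and is exposed in
  `derive_predictors()`.
* **Stratification** defaults to 10 × 10 equal-frequency SST × MLD
  bins (reduced with a warning when a gradient has fewer distinct
  values); the pooled-target-group background is the default. Stepwise
  GLM selection uses AIC; the ANN search grid is hidden sizes
  {2, 4, 6, 8} × decay {0.1, 0.01, 0.001}; evaluation splits are
  stratified by class so every test fold contains presences.
* **Division guards**: %ΔSR is masked where present SR < 0.5;
  zero-change members are excluded from the sign-agreement count;
  months without data are dropped from annual means.
* **Binarisation** uses ≥ at each threshold, applied to annual-mean
  suitability, over [0.25, 0.40] for GLM/GAM/ANN and [0.10, 0.25] for
  the random forest; an empty-versus-empty comparison scores all
  Jaccard components zero.
* **Association significance** uses the type-7 (linear interpolation)
  75th percentile of the positive scores, computed per scenario
  (period × member); a scenario with a single positive score retains
  nothing and is flagged. Cross-trophic subsets are obtained by
  filtering pair labels afterwards.
* **Range shifts** divide by 6.9 decades (period midpoints 2021.5 and
  2090.5); centroids are computed on the hemisphere holding the larger
  suitability mass, so bipolar ranges do not cancel at the equator;
  longitudes average circularly. Velocity summaries are emitted both
  over all species and over poleward shifters, with both sd and IQR,
  since the headline "median ± spread" convention is ambiguous.
* **Severity**: only the PCA + Euclidean + PAM clustering path is
  implemented (the one retained after comparing strategies); the
  retained components are the first four principal components, raised
  if needed so that ≥95% of variance is kept; severity is the absolute
  variance-share-weighted sum of PC scores, which makes it invariant to
  PC sign flips. k defaults to the Calinski–Harabasz argmax and can be
  fixed by the user.
* **Weighted medians** interpolate to the midpoint when the cumulative
  weight hits exactly one half, so they reduce to ordinary medians
  under equal weights.
* **Global change summaries** are emitted both as the median over cells
  of the ensemble mean and as the median over member × cell values,
  labelled, since the two readings differ in general.

## Problem sizes used by the test-suite experiments

All tests run on the 10-degree synthetic world (36 × 18 cells, 12
months), a size chosen so that the complete suite — including fitting
full four-family ensembles — runs in minutes on a single core: niche
recovery uses 20 species with every family at its frozen settings;
poleward-shift detection uses 30 species under a spatially uniform
+3 °C anomaly; the end-to-end null-forcing run uses 50 generated
species, two pseudo-ESMs with zero warming, two predictor sets, two
evaluation splits and a reduced neural-network search grid (the
reduction changes speed, not the zero-propagation property being
checked). Grid size, species counts and split counts are configuration,
not code.

## Known limitations

* The basin-imbalance screen of predictor selection is a diagnostic
  report in spirit only: the synthetic world has no real basins, and
  the frozen predictor sets already exclude the fields that screen
  would remove (pCO2, SSS).
* Gridded interchange is plain wide CSV plus a JSON grid sidecar;
  there is no NetCDF reader/writer.
* The GLM/GAM response curves are deliberately low-complexity; species
  whose realised niche is strongly multimodal will be fitted poorly by
  every family, and the TSS > 0.30 retention rule is what removes them
  from ensembles.
* Species whose niche centre sits near the edge of the realised
  environmental range have truncated response curves; their fitted
  optima drift toward the range boundary (a well-known SDM artefact),
  which is why the niche-recovery checks report the median error
  across species rather than the maximum.
* LLR association scores say nothing about the direction or mechanism
  of an interaction; they flag co-occurrence beyond (or below) the
  independence expectation, nothing more.
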