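---
title: "An ensemble species distribution modeling workflow for data-limited taxa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An ensemble species distribution modeling workflow for data-limited taxa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Many tropical plant taxa — the design case for this package is Southeast
Asian climbing palms (rattans) — are known from a few dozen vetted
occurrence records, yet conservation planning needs spatially explicit
estimates of where they could persist. The standard answer is a
presence–background species distribution model (SDM): presences are
contrasted against pseudo-absence points sampled from the landscape, several
model families are fitted to environmental predictors, and their predictions
are combined into a consensus suitability surface. With so few records,
every choice (thinning, background design, collinearity screening,
evaluation scheme) materially changes the answer, so the package fixes each
one explicitly and makes the whole chain reproducible from one master seed.

This vignette documents the model, the tunable parameters and their
defaults, the synthetic-data generator used for validation, the numerical
conventions, and the known limitations.

## Workflow and model

`run_pipeline()` executes, per species:

1. **Occurrence vetting** (`clean_records`, `filter_extent`,
   `thin_to_grid`). Records lacking coordinates, fossil material, records
   dated before 1800 and exact duplicates are dropped; surviving records
   must fall in a terrestrial cell of the study grid; at most one record is
   kept per grid cell. Thinning at the modeling resolution removes
   pixel-level clustering that would otherwise inflate apparent skill. The
   within-cell tie-break (earliest year, then input order) is arbitrary but
   fixed, so thinning is deterministic. Every stage logs in/out counts in a
   provenance record.
2. **Pseudo-absence design** (`sample_pseudo_absences`). Ten sets of
   background points at a 10:1 background:presence ratio, drawn uniformly
   without replacement from terrestrial cells that contain no presence and
   whose center is more than 1 km (great-circle) from every presence. No
   environmental stratification or bias correction is applied: the uniform
   background represents the available environment. At 0.04° resolution the
   1 km buffer mainly excludes the presence cells themselves; that is the
   intended, documented behaviour.
3. **Collinearity screening** (`vif_filter`). Iterative variance inflation
   factors, VIF_j = 1/(1 − R²_j) with R²_j from an ordinary least-squares
   regression of predictor j on the other retained predictors; while any
   VIF ≥ 5 the worst offender is removed (ties: the later column). VIF is
   computed on the combined presence + background rows of the first
   modeling table. Note that an exactly compositional sand/silt/clay
   triplet (summing to 100) is perfectly collinear, so screening always
   removes one of the three — expected behaviour, not a defect.
4. **Model fitting** (`sdm_fit`). Four families with pinned defaults:
   unpenalized logistic GLM (with a weakly ridge-penalized fallback and a
   warning under perfect separation); GAM with penalized cubic regression
   splines, ~10 basis functions per predictor, smoothness by GCV (mgcv);
   elastic-net logistic regression, mixing 0.5, penalty by internal 5-fold
   cross-validation (glmnet); random forest with 500 trees and
   floor(sqrt(p)) split candidates (randomForest). No class weighting — the
   1:10 imbalance is part of the design. No per-species tuning: a fixed
   protocol is the defensible choice when some species have a dozen
   records.
5. **Replicated evaluation** (`replicate_evaluate`). Subsampling
   (stratified 70/30) and bootstrap (out-of-bag testing) replicates per
   family and background set, scored by rank-based AUC, point-biserial
   correlation, TSS (maximized over all observed thresholds, smallest
   maximizing threshold on ties) and mean scaled binomial deviance with
   probabilities clipped to [1e-6, 1 − 1e-6]. The replicate count is a
   config (`n_reps`, default 10; 3 is common when runtime matters — both
   conventions appear in the applied literature, so the package makes it
   explicit rather than silently choosing).
6. **Spatial block cross-validation** (`assign_spatial_blocks`,
   `spatial_cv`). Square blocks (default 200 km) in a local equirectangular
   projection about the data centroid are randomly allocated to k = 5
   folds (re-drawn until every fold has both classes); each fold is
   predicted by a model fitted on the others. The gap between random-split
   and spatially blocked AUC measures optimism due to spatial
   autocorrelation. The local projection distorts block geometry by well
   under 1% at 200 km scales, which is immaterial for fold construction.
7. **Null-model significance** (`null_model_test`). The full fit-and-
   evaluate closure is re-run on `n_null = 99` sets of uniformly random
   terrestrial presences; the observed AUC is significant when it exceeds
   the empirical 95th percentile of the null distribution. Randomization is
   restricted to land cells (the calibration domain), the more conservative
   of the two possible conventions.
8. **TSS-weighted ensemble** (`tss_weights`, `ensemble_predict`). Family
   weights are mean test TSS across replicates, schemes and background
   sets, floored at zero and normalized; the ensemble map is the per-cell
   weighted mean of the member maps, each member refitted on the full
   modeling table of one background set (`ensemble_set`, default the
   first) — refitting gives a single deterministic surface rather than an
   average over replicate-level fits.
9. **Permutation importance** (`permutation_importance`). Mean decrease in
   AUC over `n_perm` within-column permutations, per family, aggregated by
   the ensemble weights. AUC is used as the accuracy measure because it is
   the workflow's primary skill metric; raw (possibly slightly negative)
   aggregates are retained alongside a zero-floored reporting copy.
10. **Habitat classification and areas** (`presence_threshold`,
    `classify_habitat`, `class_area_summary`). Unsuitable below the 10th
    percentile of ensemble suitability at the training presences (linear
    interpolation between order statistics); marginal in the closed
    interval [p10, 0.40]; core strictly above 0.40. Cell areas use the
    exact spherical band formula on a sphere of radius 6371.0088 km, so
    per-class areas partition the land exactly. On strong-signal fixtures
    the p10 threshold can exceed 0.40; the pipeline then clamps the lower
    bound to 0.40 (recording the raw p10 in the manifest), which empties
    the marginal class rather than failing.
11. **Anthropogenic pressure** (`pressure_summary`). Land-cover codes are
    aggregated to anthropogenic / natural / other via a mapping table;
    per habitat class the area shares of each category are reported
    (latitude-corrected; a finer aligned land-cover grid is aggregated by
    per-cell category area fractions).
12. **Environmental characterization** (`env_characterization`). Across
    several species: per-variable one-way ANOVA with Tukey HSD (Kruskal–
    Wallis with pairwise Wilcoxon available by config) summarized as
    median/quartiles/outlier counts plus a compact letter display.

## The synthetic-data generator

Because the real inputs (decadal climate normals, soil property grids,
30 m land cover, vetted occurrences) cannot ship with a package, the
`synthetic_data` generators reproduce the statistical structure the
analysis assumes, with known truth:

* **Predictor fields** are Gaussian random fields — white noise convolved
  with an isotropic Gaussian kernel whose sd is the stated correlation
  range in cells (FFT, periodic wraparound) — rescaled to plausible
  physical units per layer name (vpd in kPa, light in MJ m⁻² day⁻¹, soil
  texture in %, and so on). `corr_range_cells = 0` gives white noise. A
  sand/silt/clay request produces three positive fields normalized per
  cell to sum to exactly 100; `collinear_spec` appends engineered linear
  combinations for screening tests.
* **The virtual species** has Gaussian responses (optimum, breadth,
  weight) per predictor; the default link passes the weighted mean
  response through a logistic centered at 0.5 (steepness 6), affinely
  rescaled so that a cell at every optimum scores exactly 1. The fixture
  species used throughout the tests is a narrow atmospheric-moisture
  specialist: a single vpd response with optimum 1.3 kPa and breadth
  0.15 kPa against a field with mean 0.8 and sd 0.25 kPa. That breadth is
  the study condition "one dominant, strong driver": the true-suitability
  oracle itself achieves a presence–background AUC near 0.93 under it,
  leaving genuine but bounded room for model error. (A broader niche,
  breadth 0.3, caps even the oracle near 0.79 — a weak-signal regime that
  the recovery benchmarks are not about.)
* **Presences** are cells drawn without replacement with probability
  proportional to suitability (optionally times a bias surface), placed at
  cell centers so grid thinning is deterministic; within-cell jitter is
  available but off by default.
* **Land cover** thresholds a smoothed field at the empirical quantile of
  the target anthropogenic fraction, giving a spatially clustered
  two-category grid whose realized share matches the target.

What the generator does **not** emulate: observation bias correlated with
accessibility, coordinate error, regional trends and anisotropy in the
predictors, realistic coastline geometry, or the fine-grained mosaic
structure of real land cover. Passing tests therefore demonstrate that the
pipeline's machinery is correct and well calibrated under its own
assumptions — not that any particular real-world prediction is accurate.

## Numerical conventions

* Percentiles and quantiles everywhere use linear interpolation between
  order statistics (R type 7).
* AUC is the rank-based (Mann–Whitney) estimator with midranks, so ties
  count one half.
* TSS scans all unique score values as thresholds with the rule
  `score >= t` and returns the smallest maximizing threshold.
* Exact collinearity is detected at R² ≥ 1 − 1e-10 and treated as
  infinite VIF.
* Great-circle distances use the haversine formula, radius 6371.0088 km.
* Occurrence thinning tie-breaks: earliest event year (missing years sort
  last), then stable input order.
* Extent membership is closed (boundary points belong to the grid);
  point extraction uses cell containment, never interpolation.
* Depth averaging of paired soil layers is unweighted by default;
  thickness weighting is available via `thickness_weights`.
* Every stochastic stage derives a 31-bit child seed from the master seed
  and stage labels (`derive_seed`), so runs are bit-reproducible and
  stages are independently replayable.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script fixtures use 25–60 cell square grids,
12–50 presences, 10:1 backgrounds, 1–10 background sets, 99 null
replicates, and 20-seed Monte-Carlo loops. These sizes were chosen as the
smallest at which the statistical properties under test (type-I control
near 0.05, niche recovery, the spatial-blocking penalty) are stable; the
same code runs unchanged at continental scale.

## Known limitations

* Rasters are exchanged as ESRI ASCII grids (plain text, WGS84,
  single-band); multi-band or tiled formats and projected CRSs are out of
  scope.
* The ensemble refits on one background set rather than averaging
  replicate-level predictions; with strongly multimodal fits the two
  conventions can differ.
* The null-model closure defaults to the linear-logistic family for
  runtime reasons; a full four-family null is configurable but slow.
* Block allocation is uniform random over occupied blocks; systematic
  (checkerboard) allocation is not implemented.
* `env_characterization` assumes independent observations; spatially
  clustered occurrences violate this and the letter display should be
  read as descriptive, not inferential, in that case.
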