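---
title: "Methods: ensemble niche transfer and range-shift decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble niche transfer and range-shift decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invrisk)
```

This vignette documents the models and procedures implemented in `invrisk`,
the assumptions behind them, the numerical choices that matter, and what
the bundled synthetic validation does and does not demonstrate.

## 1. Problem and model

The package compares the realized range of an *introduced* population with
the *potential* range that one or more *native* populations of the same
species could occupy in the introduced region. The comparison is built from
presence-background species distribution models (SDMs): for each
population, habitat suitability is estimated from occurrence records and
environmental predictor rasters, the model fitted in the population's home
region is projected onto the target region, and the projection is
binarized into a range map. The pair (introduced map, transferred native
map) is then decomposed cell-wise into expansion (introduced only),
stabilization (shared, area $RS$), and unfilling (native only), and
summarized by

$$RR = IR/NR, \qquad IRS = \frac{2\,RS}{IR + NR},$$

with $IR$ = expansion + stabilization and $NR$ = unfilling +
stabilization. $IRS$ is the area-weighted Sørensen coincidence of the two
maps: 1 for identical ranges, 0 for disjoint ones. Because published
analyses are not consistent about the direction of $RR$ (introduced over
native vs the reverse) or about the factor of two in $IRS$, the package
always computes and labels **both** directions and **both** variants
(`RR`, `RR_native_over_introduced`, `IRS`, `IRS_reported_variant`), and
never silently picks one.

Areas are spherical cell areas
$A = R^2\,\Delta\lambda\,(\sin\varphi_{top}-\sin\varphi_{bot})$ with
$R = 6371.0088$ km. The spherical (rather than ellipsoidal) approximation
errs by under 0.3%, far below the 2-decimal reporting precision of typical
range-area tables. Cells that are nodata in either map are excluded from
all three components and counted; asymmetric treatment would break the
exact swap symmetry (swapping the inputs must swap expansion and
unfilling and leave stabilization and $IRS$ unchanged), which the test
suite asserts on 1000 random map pairs.

## 2. Pipeline stages and their parameters

**Spatial thinning** (`thin_occurrences()`). Occurrence records are
rarefied so no two retained records of one population lie within
`radius_km` (default 5 km, great-circle haversine distance) of each other,
mitigating spatial sampling bias. The algorithm repeatedly deletes the
record with the most within-radius neighbours, breaking ties uniformly at
random from the seed, then reinstates any removed record that no longer
conflicts — so the output provably satisfies the distance constraint *and*
is maximal (no removed record could be re-added). Greedy deletion alone
does not guarantee maximality; the reinstatement pass closes that gap.
Populations are thinned independently because they are modelled
independently.

**Predictor selection** (`permutation_importance()`,
`select_predictors()`). Importance is prediction-permutation importance on
a preliminary model fitted to all predictors: for predictor $v$,
$1 - \max(0, r(\hat p, \hat p_{v\text{-permuted}}))$ averaged over
replicates — 0 for an ignored predictor, near 1 when predictions track $v$
alone. A refit-based leave-one-variable-out delta-AUC variant is available
(`method = "loo_auc"`); the choice is recorded in the returned table. The
selection loop then repeatedly finds the surviving predictor pair with the
largest $|r|$ above the threshold (default 0.7) and removes its
lower-importance member, recomputing until no pair exceeds the threshold.
The pair order (descending $|r|$) and the tie-break (remove the
lexicographically later name) make the loop deterministic and
column-order invariant; importance is *not* refitted between removals,
mirroring the two-stage design (preliminary model → selection → final
model).

**Pseudo-absences** (`generate_pseudo_absences()`). 1000 background
points, or one per occurrence when there are fewer than 1000, drawn
uniformly without replacement from valid cells excluding occupied cells,
placed at cell centers. One pseudo-absence set is drawn per population,
not per algorithm. Presences and pseudo-absences are weighted equally in
fitting — the simplest defensible default.

**Ensemble fitting** (`ensemble_sdm()`). Seven learner families are
registered: neural network (`nnet`), classification tree (`rpart`),
discriminant analysis on a quadratic feature basis (`MASS::lda`; this
fills the flexible-discriminant slot with a quadratic rather than
MARS-basis discriminant), maxent-style $\ell_1$-regularized logistic
regression on linear-plus-quadratic features (`glmnet`), random forest
(`ranger`), GAM with small-basis smooths (`mgcv`), and gradient boosting
(`xgboost`). Any subset of two or more families forms a valid ensemble;
the shipped defaults use `rf + maxent + gam`, a fast and diverse trio. All
learners run single-threaded with seeds derived from one master seed, so
fits are reproducible. Predictors are standardized inside each member; a
fully constant design degenerates to the observed presence rate rather
than failing.

Validation is five repeated random stratified 70/30 splits — repeated
random splits, not 5-fold partitioning, because each repetition draws an
independent 70% sample. Each (algorithm, split) candidate is evaluated on
its test fold by AUC (rank form: the probability a random presence
outscores a random absence, ties half-weighted) and by TSS at the fold's
MSS threshold. Candidates failing TSS ≥ 0.7 or AUC ≥ 0.8 are excluded.
The ensemble predicts the unweighted mean of surviving member scores
(a TSS-weighted mean is available but off by default, since gating — not
weighting — is the stated mechanism).

**MSS threshold** (`mss_threshold()`). The binarization cut-off maximizes
sensitivity + specificity over candidate thresholds: the midpoints of
consecutive sorted unique scores plus the extreme scores themselves, under
the rule score ≥ threshold ⇒ presence, with objective ties broken toward
the lowest threshold (the most inclusive range). The ensemble threshold is
calibrated on the pooled presence/pseudo-absence set from ensemble scores;
each population's map uses its own threshold — the introduced population's
calibrated on the target region, each native population's calibrated on
its source data and carried along with the transfer.

**Null models** (`build_null_models()`, `compare_real_vs_null()`). Per
replicate (default 10), virtual presence records equal to 70% of the
actual count (rounded half away from zero; the convention is explicit
because the count is printed) are drawn uniformly from valid cells, a
model is fitted to them with fresh pseudo-absences, and it is evaluated
against a freshly drawn held-out 30% of the *real* records. The held-out
sample is re-drawn per replicate; seeds are logged. Real vs null AUC and
TSS are compared with one-sided Welch t-tests (real > null), one-sided
because the scientific claim is directional. On no-signal data the null
AUC distribution centers on 0.5 and the verdict's type-I rate stays at the
nominal level — both are asserted in the acceptance tests.

## 3. Rasters and geometry

Grids are geographic WGS84 lon/lat, pixel-is-area, row 0 northmost, with
half-open cells $[\text{west}, \text{east}) \times (\text{south},
\text{north}]$ — the dominant convention of distributed climate rasters.
I/O uses the ESRI ASCII grid format: plain text, single band, explicit
`NODATA_value`, readable by any GIS; values are written with 17
significant digits so write-then-read round trips are exact. Alignment
resamples continuous layers bilinearly and land-use fraction layers by
nearest neighbour (which preserves the $[0,1]$ bounds exactly); any cell
with a nodata contributor becomes nodata. Point-to-cell lookup uses the
half-open intervals, so a point on a shared edge belongs to exactly one
cell.

## 4. The synthetic validation scenario

`synthetic_scenario()` defines the package's study conditions: two
disjoint 100 × 50-cell "continents" at 0.25°, five predictors per
continent (three climate, one land-use fraction, one topography). Each
predictor is a linear spatial gradient — orientations fanned ±60° off the
latitude axis so the layers are correlated but not collinear (pairwise
$|r|$ from ≈0 to ≈0.65) — plus moving-average-smoothed Gaussian noise
(amplitude 2, smoothing radius 2 cells), with 2% of cells masked nodata.
Moving-average smoothing was chosen over spectral methods because it is
dependency-free and bit-reproducible from the seed.

Two virtual species have logistic-linear suitability in standardized
predictors with partially shared coefficients: the native species
(bio1 = −24, bio12 = +12, elevation = −6, intercept −16) and the
introduced species (same climate slopes, cropland = +6 instead of
elevation, intercept −28). The steep slopes give near-binary suitability:
the species have sharp tolerance edges, so the true range (suitability ≥
0.5, ~21% of the target continent for the native species, ~14% for the
introduced, largely nested) is insensitive to the exact occupancy
threshold and forms a well-posed target for threshold-based range
estimation. With gentle slopes no model — not even the true suitability
used as a score — can reach TSS 0.7 against uniform background, because
presences spread over marginal habitat; sharpness is thus a property of
the emulated system, not a tuning knob. Each species contributes 500
occurrences, sampled per cell proportionally to suitability (optionally
times a fixed west-east bias gradient raised to a configurable power) and
jittered uniformly within the cell.

What passing the recovery tests shows: on data whose generating process
matches the SDM assumptions (logistic niche, unbiased sampling,
environment fully observed), the full pipeline recovers true ranges with
Jaccard ≈ 0.8 and true RR/IRS within ±25%. What it does not show:
robustness to dispersal limitation, biotic interactions, unobserved
predictors, or strong sampling bias — real-data performance depends on
those, and no synthetic pass certifies them.

## 5. Numerical choices, degenerate inputs, problem sizes

- All randomness flows from one master seed through a deterministic
  seed-spawning function; every stage's seed is recorded in the run
  report, and identical configurations reproduce reports and rasters
  bitwise.
- Correlation of constant columns is defined as 0 (with a warning) rather
  than `NA`, so selection never stalls on a degenerate layer; constant
  predictions give importance 0 for all predictors, with a warning.
- Welch's test with two zero-variance equal-mean samples returns $p = 1$
  by convention.
- `sample()`-style index pitfalls (length-one candidate vectors) are
  avoided by explicit index sampling, so degenerate grids with a single
  habitable cell behave correctly.
- Default sizes were chosen to keep a desk-scale run fast: the scenario's
  5000-cell continents, 500 occurrences per species, three ensemble
  families, five splits, and ten null replicates complete in roughly ten
  seconds; tests and the acceptance script use these sizes.

## 6. Known limitations

- Projected (non-geographic) rasters are rejected rather than reprojected;
  reproject upstream.
- The learner set approximates, but does not bit-reproduce, any existing
  SDM platform's internal algorithms; the flexible-discriminant slot uses
  a quadratic discriminant basis.
- Environmental-space analyses (niche overlap in predictor space,
  Schoener's D), spatial-block cross-validation, and future-climate
  projection are out of scope.
- The range comparison is geometric: it quantifies where ranges lie, not
  why; interpretation as "invasion risk" inherits every caveat of
  presence-background SDM transfer.
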