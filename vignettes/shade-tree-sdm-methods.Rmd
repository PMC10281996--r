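---
title: "Methods: consensus species distribution modelling for cocoa agroforestry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus species distribution modelling for cocoa agroforestry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shaderange)
```

## What this package models

`shaderange` implements an ensemble (consensus) species-distribution-modelling
pipeline for assessing how climate change may reshape the habitat of cocoa
and the shade-tree species used in cocoa-based agroforestry. The scientific
object is, per species, a habitat-suitability surface
$\hat{s}(x) \in [0,1]$ over a regular 2.5 arc-minute longitude/latitude grid,
estimated from presence records and randomly drawn pseudo-absences using
bioclimatic (BIO1–BIO19 family) and edaphic (soil) predictors, then
projected under shifted future climate while soil and land cover are held
constant.

Because the real inputs of such a study (GBIF occurrences, WorldClim and
CMIP6 climate surfaces, SoilGrids, satellite land cover) are bulky external
downloads, the package is built around a first-class synthetic-data module:
*virtual species* with known Gaussian niches living on simulated, spatially
autocorrelated environmental fields. Every downstream stage — cleaning,
background sampling, predictor selection, modelling, projection, community
mapping — is therefore testable against known truth, which is how the test
suite validates the pipeline.

## The synthetic world

**Environmental layers.** Each layer is an optional linear north–south
gradient plus a Gaussian random field, realized as kernel-smoothed white
noise (separable Gaussian kernel, sd in cells = the `smoothing` parameter),
then linearly rescaled so the realized mean and standard deviation over land
match the request exactly. A true Gaussian-process simulation would also
work; smoothed noise was chosen because it is fast, trivially seedable, and
any autocorrelated field suffices for exercising the pipeline. An optional
contiguous "ocean" (nodata) region is carved from the lowest quantile of an
independent smoothed field (`ocean_fraction`, 0.15 in the demo — enough
nodata to exercise the land filters without starving the sampler of cells).

**Virtual species.** True suitability is a product of independent Gaussian
responses, $s(x) = \prod_j \exp\{-\tfrac12 ((x_j - \mu_j)/\tau_j)^2\}$,
rescaled multiplicatively (capped at 1) so the mean over land approximates a
target prevalence. The response is kept continuous (no logistic
thresholding) so that recovery tests can correlate predictions against a
smooth truth.

**Occurrence samples.** Clean records are drawn from land cells with
probability proportional to true suitability, with a within-cell coordinate
jitter of at most 0.4 cells — this deliberately produces sub-cell duplicate
clusters, as herbarium data do, so grid thinning has something to do.
Contaminated records of known classes (ocean points, pre-baseline years,
exact duplicates, climatically marginal locations, blacklisted sources) are
injected in exact numbers and tracked in a hidden `.truth` column, so each
cleaning filter can be audited record-by-record.

What the generator does *not* emulate: spatial sampling bias correlated
with accessibility, coordinate uncertainty beyond one cell, taxonomic
misidentification, or temporal trends in collection effort. Passing tests
therefore demonstrate algorithmic correctness of the pipeline, not
robustness to every pathology of real occurrence data.

## Occurrence quality control

Filters flag rows rather than deleting them; a record is retained iff it
carries no flag, and a per-species audit report is always reconstructible.
The cascade order is: (i) invalid/missing coordinates, (ii) off-land
(ocean or outside the study grid — the grid defines the analysis universe),
(iii) collected before the 1969 climate baseline (missing years are flagged
too, conservatively; configurable), (iv) climatically marginal, (v)
blacklisted sources (default `fossil`, `unknown`), then one-record-per-cell
thinning, then the strict minimum-sample rule (a species is modelled only
with more than 60 retained records).

The marginal-climate filter needs a definition of "the last 10% of the
climatic gradient": here it is two-sided and per species — on any climatic
layer, values strictly outside the central 90% (5% per tail, type-7
empirical quantiles) of that species' distribution are flagged. The
reference distribution is defined by the upstream filters only, which makes
the whole cascade idempotent: re-running it on its own output changes
nothing. Species with fewer than 20 usable records skip this filter with a
warning, since empirical tails from a handful of points are noise.

Thinning keeps, per (species, cell), the record with the most recent year,
breaking ties by lowest input index — deterministic and audit-friendly.

## Pseudo-absences

1000 background points per species are drawn uniformly from cells that are
on land, strictly within 500 km (haversine, cell centers, Earth radius
6371 km) of at least one presence, and contain no presence. The sampling
unit is the cell, without replacement, with the point placed at the cell
center — matching the raster resolution at which the models operate. The
buffer is the union of per-presence discs, not a convex hull. Tests verify
the distance bound with an independent haversine implementation
(`geosphere`) and check sampling uniformity with a chi-squared test.

## Predictor selection

Candidate predictors are reduced in two stages on the pooled
presence + pseudo-absence extraction across species (one shared predictor
set, as is typical for multi-species ensembles): iterative VIF filtering —
drop the single worst column while any VIF = $1/(1-R^2)$ exceeds 8, one at a
time, since each removal changes every other VIF — followed by pairwise
filtering: while any $|r| > 0.7$, drop the lower-priority member of the
worst pair. "Priority" stands in for the expert ecological ranking such
studies apply; the default ranks variables by mean absolute correlation
with all others (the most redundant variable loses), and a user-supplied
ranking can replace it. Perfectly collinear columns get `Inf` VIF rather
than an error. The final set provably satisfies both thresholds at once.

## The ensemble

Four learners are fitted per species: logistic GLM with linear + quadratic
terms; GAM with thin-plate spline smoothers (basis dimension 4, REML);
gradient-boosted trees (2000 rounds, learning rate 0.01, depth 3); and a
500-tree random forest. Hyperparameters are fixed and deliberately ordinary
— the pipeline's claims are about the ensemble machinery, not about tuned
learners — and every stochastic fit is seeded.

Fourfold cross-validation is stratified by class (so no fold is ever
single-class), fold sizes within a class differing by at most one.
Performance is AUC (rank-based, ties at 1/2) and TSS evaluated at the
held-out-optimal threshold.

The consensus prediction is a weighted average of member scores. The
default weight is *skill above chance*, $w_a \propto \max(\mathrm{AUC}_a -
0.5, 0)$: raw AUC weights barely distinguish decent models (0.85 vs 0.95
differ by 12%, while their skill differs by 29%), and chance-level models
arguably deserve zero weight, not half weight. A literal mean-AUC mode
(`weight_mode = "raw"`) is available for strict equivalence with the
classical formulation. After weighting, every member is refitted on all the
data and the species' binarization threshold is set on the full-data
ensemble scores.

**Threshold rule.** "Maximizing sensitivity and specificity" is read as
maximizing their sum (equivalently TSS), the standard max-SSS criterion.
All decision-distinct thresholds are the distinct score values; the
returned threshold is the midpoint of the optimal score interval (ties
resolved toward the lowest interval, favouring sensitivity), clamped into
(0,1) for probability scores — with a fallback to the candidate value
itself in the degenerate case where clamping would leave the optimal
interval. Predictions are positive at `score >= threshold`.

**Variable importance** is permutation importance on the best (highest mean
CV AUC) algorithm: mean AUC drop over 5 permutations per predictor,
negatives truncated, rescaled to sum 100%. This is method-agnostic, unlike
boosted-tree relative influence, at the cost of not matching that metric
numerically. Climatic and edaphic sums partition the 100% exactly.

## Projection and accounting

Fitted ensembles are applied to the current stack and to scenario-shifted
stacks (affine shifts per climatic layer; edaphic layers are immutable
under scenarios by construction). Multiple GCM variants of one SSP × period
are combined by the cellwise mean of suitability *before* thresholding;
per-GCM binarization with majority voting is a defensible alternative, but
mean-then-threshold uses the continuous information and keeps the species
threshold — fit once under current conditions — meaningful for futures.

Suitable areas are sums of geodesic cell areas,
$R^2 \, \Delta\lambda \, (\sin\varphi_{top} - \sin\varphi_{bot})$ with
$R = 6371$ km, so a cell near the equator counts more than one at higher
latitude; a cell-count mode exists for comparison. Change maps partition
into gain/stable/loss, with the identities gain + stable = future and
loss + stable = current asserted in tests. The land-cover constraint
(habitat only counts on classes available for agroforestry without
deforestation: shrubs, grassland, cropland, sparse vegetation) is a raster
intersection applied to both time points; land cover is held constant
across scenarios.

## Community products

Richness maps are cellwise sums of per-species binaries; hotspots are cells
with strictly more than `min_richness` species (default 25, following the
"more than 25 species" reading; the rule is configurable to `>=`). The
overlap summary reports, per shade species, the mean focal-crop (cocoa)
suitability and the mean of a chosen environmental layer over the species'
suitable cells, current and future, yielding a shift vector per species.
The "most relevant variable" for that summary is a configuration choice
(default: first climatic layer) rather than being hard-coded to temperature
seasonality, because on synthetic worlds the dominant gradient is whatever
the generator made dominant.

## Numerical and design choices worth knowing

- **Grids** are north-up, cell-center referenced, half-open `[min, max)`;
  points on the eastern/southern edge belong to no cell and are treated as
  off-land by QC.
- **Raster I/O** is plain-text ESRI ASCII grid plus a YAML sidecar for
  layer classes and land-cover legends. The format is lossless for these
  purposes and keeps every artifact diffable and versionable.
- **Determinism.** Every generator and stochastic stage takes an explicit
  seed and restores the caller's RNG state. Pipeline stages derive their
  seeds from a master seed by a stable string hash, so a rerun of any stage
  subset is reproducible independently of execution order; reruns of the
  demo pipeline are bit-identical (asserted on MD5 manifests).
- **Degenerate inputs.** Zero-sd layers yield exact constants; a species
  whose niche misses the landscape entirely raises an error rather than
  returning zeros; single-class training data, empty eligible-cell sets and
  pseudo-absence shortfalls raise informative errors; VIF on perfectly
  collinear data returns `Inf` and the filter removes exactly one copy.
- **Recovery benchmark calibration.** The niche-recovery test (fourfold CV
  AUC ≥ 0.9, truth correlation ≥ 0.8, active layers > 80% importance) uses
  a *strong* niche, defined as Gaussian tolerance ≈ 1/3 of the regional
  layer sd. The definition comes from a ceiling analysis, not from tuning:
  ranking the training points by the *known true suitability* — the best
  any model could do — gives AUC ≈ 0.88 at tolerance 0.5 sd versus ≈ 0.93
  at 0.35 sd, because at prevalence 0.3 random background points
  necessarily overlap suitable habitat. A recovery target of 0.9 is
  meaningful only where the data-generating process permits it.
- **Problem sizes.** The bundled demo and the test suite run on 60 × 80
  grids (≈ 4000 land cells), 3 species, 300–500 presences, 1000
  pseudo-absences, one scenario × two GCMs — sizes chosen so the full suite
  and the demo complete in minutes on a single CPU while still exercising
  every code path at the study's default parameter values (1000
  pseudo-absences, 500 km, VIF 8, |r| 0.7, fourfold CV, n > 60).

## Limitations

The pipeline inherits the assumptions of correlative SDMs: presences are
treated as reflecting environmental equilibrium, pseudo-absences as
uninformative background, and projection assumes niche conservatism, no
dispersal limits, and static soil and land cover. The synthetic world makes
those assumptions true by construction; on real data they are
approximations, and results at the margins (threshold position, small-area
percentages) are sensitive to background placement. The per-species
importance figures use permutation importance and will differ numerically
from boosted-tree relative influence even when rankings agree.

## A minimal run

```{r demo, eval = FALSE}
cfg <- demo_config(master_seed = 42)
manifest <- run_pipeline(cfg, "demo_out")
head(manifest)
```

The manifest lists every artifact with its stage, path, MD5 checksum and
stage seed; `demo_out/` then contains the cleaned occurrences and QC report,
background points, predictor-selection table, cross-validation metrics,
per-species suitability rasters, area-change accounting and community
products, all as text files.
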