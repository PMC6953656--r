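---
title: "Modeling compositional turnover from occurrence records: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling compositional turnover from occurrence records: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betascape)
```

`betascape` estimates and maps beta diversity — compositional dissimilarity
between geographic sample sites — from point occurrence records and
environmental raster layers. This vignette is the package's account of the
statistical machinery, the choices made where the design was genuinely open,
and what the validation on synthetic data does and does not establish.

## From records to sites

Opportunistic occurrence records are not survey plots: they arrive as
unevenly dense point clouds. The package forms sample sites by clustering
record coordinates with the Markov Cluster (MCL) algorithm. MCL needs a
graph, not raw distances, so we build one explicitly: records closer than
`edge_radius` (default 0.5°) are joined by an edge weighted
`exp(-d² / (2·kernel_bandwidth²))` (default bandwidth 0.1°), with unit
self-loops. The radius bounds the diameter a cluster can attain, which is
what tuning MCL's inflation and pre-inflation options is usually after —
preventing continental-scale "sites" that would span multiple ecoregions.
Inflation (2), pre-inflation (1) and the pruning threshold (1e-5) default to
the mcl program's own values and are exposed in the run configuration. The
iteration is the classical one: column-normalize, one-off element-wise
pre-inflation power, then alternate expansion (matrix squaring), inflation
(element-wise power + renormalization) and pruning until the matrix stops
changing; clusters are the connected components of the limit matrix's
support, so every record is assigned. Column sums are tracked at every step;
the suite asserts they stay within 1e-9 of 1.

Dense record sets make an all-records graph needless: exact duplicate
coordinates are always collapsed, and an optional `snap` (pipeline default
0.25°) rounds coordinates to a grid before clustering, with each record
inheriting its node's cluster. Distances are Euclidean on raw decimal
degrees — the convention for distance-matrix clustering of coordinate tables
— with haversine available behind a flag for users who prefer metric
distances.

Records whose 0.1°-rounded coordinates sit on a boundary between region
classes are removed before tallying, because a "site" straddling two
ecoregions blurs exactly the contrast the class statistics test. The
boundary rule is ambiguous in the field's usual phrasing, so both readings
are implemented behind one switch: the default `"cell"` rule probes the
class grid at the rounded cell's center and four corners
(record-independent, deterministic); the `"records"` rule compares classes
under the actual records in the cell.

The community matrix is then filtered: species observed at fewer than
`min_sites_per_species` sites and sites with fewer than `min_obs_per_site`
records are removed *iteratively to a fixed point*, because a single pass
can leave sites that fall below threshold once sparse species are gone. The
defaults (30 sites/species, 300 records/site) suit continental record sets
of tens of millions of records; the packaged validation scenario scales them
to 5 and 50 for its 20,000 records. A conservation invariant is enforced
across the whole chain: records read = records dropped at parsing + dropped
at boundaries + dropped by filters + retained.

## Dissimilarity

Compositional dissimilarity uses the Horn–Morisita index, the
abundance-based Horn variant valid for non-integer data:

$$d(x, y) = 1 - \frac{2\sum_i x_i y_i}
  {\left(\sum_i x_i^2/X^2 + \sum_i y_i^2/Y^2\right) X Y},
  \qquad X = \sum_i x_i,\; Y = \sum_i y_i.$$

Morisita-family indices estimate the probability that two individuals, one
drawn from each site, are conspecific, which makes them markedly more robust
to incomplete and unequal sampling than Bray–Curtis — the decisive property
for ad hoc occurrence data. The index is symmetric and invariant to
proportional rescaling of either vector; the classical Morisita form
(integer counts, n(n−1) denominators) is available behind a flag. All
distance-matrix routines unfold lower triangles in one fixed order — pairs
(1,2), (1,3), …, (2,3), … — so Mantel, MRM and GDM vectors align
bit-identically.

Class contrasts ("dissimilarity is greater between ecoregions than within")
are Mantel correlations between the dissimilarity matrix and a 0/1
different-class indicator, with one-sided permutation p-values (labels
permuted over sites, add-one correction). One-sided tests match the
directional claim being made; the calibration suite confirms the test holds
its 5% level under the null.

## Multiple regression on distance matrices

MRM regresses the unfolded response distances on unfolded predictor
distances — geographic distance plus one |eᵢ − eⱼ| matrix per environmental
variable (the standard construction; predictors are z-standardized on the
unfolded scale by default so coefficients are comparable). Because unfolded
distances are pseudoreplicated, inference is by response permutation only:
rows and columns of the response matrix are permuted simultaneously,
predictors held fixed; the overall p comes from the permutation null of R²,
per-coefficient p-values from the nulls of |t|. The package reports the four
nested models — geographic; + climate; + vegetation; + both — as one
comparison table. Nested R² monotonicity is an OLS identity and is asserted
on every fixture run.

## Generalized dissimilarity modeling

GDM fixes the two failures of linear distance regression: compositional
dissimilarity saturates at 1, and its rate of change varies along gradients.
The model is

$$\mu_{ij} = 1 - \exp(-\eta_{ij}), \qquad
  \eta_{ij} = \beta_0 + \sum_p \sum_k \beta_{pk}
  \left| I_{pk}(x_{pi}) - I_{pk}(x_{pj}) \right|,$$

with `I_pk` monotone I-spline bases and all coefficients constrained
non-negative, so predicted dissimilarity can never decrease as sites move
apart along any gradient. Three bases per predictor with knots at that
predictor's 0/50/100 percentiles is the de-facto standard and the package
default. The bases are order-3 Ramsay I-splines, built as tail sums of
B-splines on boundary-augmented knots and normalized to rise 0 → 1 across
the knot range; a non-negative combination is therefore a monotone transform
whose plateau height equals the coefficient sum. That height is the
predictor's **importance** (the "magnitude" plotted as a spline's plateau in
partial-ecological-distance figures). Geographic position enters as two
separate spline-transformed predictors, latitude and longitude, rather than
one great-circle distance term, so anisotropic spatial turnover can be fit.

Fitting minimizes the weighted binomial-form deviance

$$D = 2 \sum_{ij} w_{ij}\left[ d\,\ln\frac{d}{\mu}
  + (1-d)\ln\frac{1-d}{1-\mu}\right]$$

with the 0·ln 0 = 0 convention; observed d = 1 values are nudged to
1 − 1e-9 to keep logs finite. Pair weights
`w_ij = (S_i + S_j) / (2 max S)` down-weight species-poor site pairs, the
standard bias reduction for ad hoc presence data. The optimizer is IRLS with
a non-negative least-squares inner solve (`pracma::lsqnonneg`) and
step-halving, which makes the deviance monotone non-increasing;
convergence is declared at a relative deviance change below 1e-8 (or a
deviance numerically zero relative to the null), capped at 500 iterations
with an error, never a silent result, on failure. The suite checks the
fitter two independent ways on small instances: it must beat 10⁴ random
feasible coefficient draws and agree to 1e-6 relative deviance with a
box-constrained quasi-Newton optimizer restarted 20 times. The null deviance
uses the closed-form optimum of the intercept-only model (μ₀ = weighted mean
dissimilarity).

Predictor significance mirrors standard GDM variable-importance practice —
the procedure is an interpretation, since no canonical test exists: each
predictor's site values are permuted across sites (response and other
predictors fixed), the model refit, and p is the add-one-corrected fraction
of permutations reaching the observed percent deviance explained. The
default of 100 permutations reflects that each permutation is a full refit;
the pipeline's packaged scenario uses 49, which already resolves the 0.05
threshold.

## Mapping

Each retained predictor's raster is transformed pixelwise to
`f_p(x) = Σ_k β_pk I_pk(x)` — biological space, bounded by
[0, importance]. A PCA over valid pixels of the transformed stack reduces
the layers to three components, min–max scaled to [0, 255] and assigned to
red, green and blue, so color difference approximates predicted
compositional dissimilarity. Two determinism details matter for
reproducibility: component signs are fixed by requiring each loading
vector's largest-magnitude entry to be positive, and fewer than three layers
are padded with zero layers (with a warning), degenerate components
rendering as 0. Rasters are read and written as ESRI ASCII grids — a
plain-text, GDAL-compatible single-band format that keeps every artifact
human-diffable; the grid convention is north-up with half-open pixels
(a point on an interior edge belongs to the pixel east/south of it).

Raster extraction at site centroids reproduces the nearest-neighbor
fallback used when fine-resolution products have gaps: if the containing
pixel is nodata, the grid is coarsened by integer factors 2, 3, … 8 and the
first valid value taken, with the factor recorded as provenance. Coarsening
picks the valid constituent pixel nearest the block center, which preserves
the nearest-neighbor contract (every coarse value is one of its
constituents) while guaranteeing a block with any data yields data. The
integer-factor ladder generalizes metric pixel-size steps (e.g. 250 m →
2,000 m) to grids in degrees. Multi-year vegetation layers are combined by
per-pixel median ignoring nodata (mean of central pair for even counts),
pixels nodata only when nodata in every year. Each environmental layer is
sampled independently at the site centroid; no attempt is made to reconcile
differing native resolutions beyond the fallback rule.

## The synthetic world: what it validates

Real inputs for this analysis are multi-gigabyte occurrence snapshots and
global rasters; published headline numbers from such data are properties of
those data, not of the algorithms. The package therefore validates against a
generator with known truth. `generate_world()` produces smooth environmental
surfaces (low-pass-filtered Gaussian noise over a monotone latitudinal
gradient, rescaled to realistic ranges: temperature −5–25, precipitation
0–2000, elevation 0–2500, cover 0–100) and spatially coherent categorical
regions (k-means on coordinates plus environment). Species follow the
simplest model realizing both recognized turnover drivers — environmental
filtering and dispersal limitation: expected abundance is a Gaussian niche
`max_intensity · exp(-Σ_v (e_v - opt_v)²/(2 b_v²))` times a hard circular
range disc. Sampling effort is a two-patch 10:1 surface emulating
geographically biased recording; records are drawn pixel-first
(effort-weighted), then species-within-pixel (expected-abundance
multinomial), with coordinates jittered uniformly within the pixel so site
clustering is nontrivial. `true_pair_dissimilarity()` evaluates
Horn–Morisita on noise-free expected abundances, giving a ground-truth
oracle for recovery tests.

The packaged scenario — a 24 × 24 grid over 12° × 12°, 5 environmental
variables, 6 ecoregion-like and 3 climate-like classes, 40 species, 20,000
records — runs end to end in well under a minute, and its size was chosen so
the full suite exercises every stage at meaningful sample sizes (about 35
sites and 30+ retained species after filtering). What passing tests show:
the indices, fits, permutation tests and maps compute what they claim, the
fitter attains its constrained optimum, planted signal is recovered and pure
noise rejected at the advertised rates. What they do not show: anything
about taxonomic error, spatial autocorrelation of effort beyond the
two-patch pattern, temporal mismatch between records and environmental
layers, or species interactions — none of which the generator emulates, all
of which real occurrence data contain.

## Numerical and design notes

- MCL graph construction (Gaussian kernel, radius cutoff, unit self-loops)
  is a package decision; any construction yielding a column-stochastic
  matrix works, and the planted-cloud tests pin the behavior.
- Site ids are contiguous integers from 0 in order of first record
  occurrence; relabeling input order permutes membership only.
- Interior I-spline knots are nudged 1e-9·range inside the boundary when
  percentile ties would collapse them; constant predictors contribute no
  basis and report zero importance rather than erroring inside a larger fit.
- `fit_gdm` clamps μ to [1e-10, 1 − 1e-10] inside the IRLS loop; the
  intercept is constrained non-negative like every other coefficient, so
  fitted dissimilarity of identical sites is `1 − exp(−β₀) ≥ 0`.
- Permutation p-values always use the add-one correction, so p ∈ (0, 1] and
  a reported p can never be 0.
- Every stochastic routine takes an explicit seed; the pipeline expands one
  top-level seed per stage by a fixed rule (`(seed mod 1e6)·1000 + stage
  index`), and reruns are bit-identical including map pixels.
- Known limitations: no reprojection between coordinate systems (all layers
  must share the geographic grid's CRS); no partial Mantel or distance-based
  RDA; no spline uncertainty bands; class grids are consumed as inputs, not
  derived from climate rules.
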