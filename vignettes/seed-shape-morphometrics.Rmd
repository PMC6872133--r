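---
title: "Quantifying seed shape and linking it to genome-wide markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying seed shape and linking it to genome-wide markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedmorph)
```

## The problem

Seed shape in cereals varies continuously across a germplasm collection, and
simple indices (length, width, thickness and their ratios) capture only a
fraction of that variation. `seedmorph` implements a complete
outline-morphometrics pipeline for seed profiles — from binary scanner masks
to shape descriptors — and couples it to quantitative genetics: genomic
prediction of whole contours and mixed-model association scans of the leading
shape components. Because every choice of contour *standardization* (how
scale, direction and trace start are fixed) changes the descriptors, the
package exposes the full grid of standardizations and descriptor types so
their downstream consequences can be compared on equal footing.

## From image to contour

A binary mask is cleaned by morphological opening then closing with a 3x3
cross structuring element (one pass each), hole filling, and removal of
components below a pixel threshold (`clean_binary()`). The kernel size is a
fixed, configurable convention; opening with the cross rounds sharp convex
corners by design. The remaining component's boundary is traced with
Moore-neighbour tracing, recorded as eight-direction Freeman chain codes and
decoded to pixel coordinates (`trace_contour()`); orientation is forced
counter-clockwise (signed area > 0) so that later reflection-sensitive steps
see consistently oriented input. The base landmark — the point where the
seed was attached to the parent plant — is supplied as a coordinate (from a
landmark table or the simulator; there is no interactive placement) and the
trace is rotated so the nearest boundary vertex comes first.

`resample()` places `P = 500` points at equal arc-length intervals along the
polygonal boundary, starting at (and including) the base landmark. Length is
the longest distance from the base landmark to the contour; width and
thickness are coordinate ranges perpendicular to that axis in the front and
side view respectively, with ties among farthest points broken by the
smallest index so the measurement is deterministic (`measure()`).

## Standardization procedures

Four procedures remove nuisance variation in direction, scale and trace
start, each with scaling on or off (reference distance `c = 1` when scaling):

* **SL** — translate the centroid to the origin and rotate the base landmark
  onto the positive x-axis; scaling divides by the landmark–centroid
  distance.
* **GPA** — generalized Procrustes superposition over the 500 matched points:
  center each contour, optionally normalize centroid size to 1, then
  iteratively rotate each onto the consensus (pointwise mean) until the
  consensus moves less than `1e-10`. Rotations are proper (determinant +1):
  reflections would silently flip seeds, so they are forbidden. The initial
  consensus is the first contour, which keeps the procedure deterministic.
  The summed squared distance to the consensus is non-increasing across
  iterations — this is asserted in the tests.
* **FESA** — rotate so the semi-major axis of the first-harmonic ellipse is
  horizontal with endpoints at `(±c, 0)`, centering on the harmonic position
  terms; the trace start moves to the resampled vertex nearest the `(+c, 0)`
  endpoint. The 180° ambiguity of the axis is resolved by placing the base
  landmark's image in the right half-plane (exact ties on the y-axis fall
  back to the smaller rotation angle). The start relocation is a cyclic
  index shift with no re-interpolation, so point correspondence stays
  countable; the residual start phase is bounded by half a sampling step
  (`pi/P`).
* **FESL** — FESA's rotation, centering and scale, but the base landmark
  remains the trace start.

All four are exactly invariant to input translation, invariant to input
rotation up to numerical tolerance, and preserve shape (pairwise distance
ratios) exactly.

## Shape descriptors

Two descriptor families are computed from the standardized point sets
(`descriptor_matrix()`):

* **SPP** — the superposed coordinates themselves, concatenated as
  `(x_1..x_P, y_1..y_P)` (2P features).
* **EFD** — elliptic Fourier coefficients `(a_n, b_n, c_n, d_n)` of the
  closed path, at 20 harmonics (a low-pass summary) or at full resolution.
  At `P = 500` the sampling supports at most `floor((P-1)/2) = 249`
  harmonics, so the "250-harmonic" full-resolution descriptor is realized
  as 249; the label `EFD250` is kept for comparability.

A numerical choice that matters: the Fourier coefficients are computed with
the `P` vertices treated as *uniform in the curve parameter*
(`param = "uniform"`, the default). For contours produced by `resample()`
this is precisely the arc-length parameterization of the original traced
outline, and it makes the transform a fixed linear map of the coordinates —
the congruence that guarantees SPP and full-resolution EFD carry the same
geometry (their pairwise distances are proportional by the Parseval constant
`sqrt(P/2)`, and their principal components match). Measuring the resampled
polygon's own chord lengths instead (`param = "arc"`, the canonical
chain-code form, available for raw unevenly sampled polygons) makes the map
weakly nonlinear per contour; on smooth resampled outlines the two agree to
high precision, but under per-point digitisation noise the chord-measured
form lets corresponding points slide along the outline and the equivalence
of the two descriptor families degrades in the low-variance components.
One consequence worth knowing: under the arc-length form the first harmonic
of a 2:1 ellipse is `(1.828, 0, 0, 1.073)`, not the `(2, 0, 0, 1)` obtained
when the ellipse's natural angle is the parameter — an ellipse traversed at
unit speed is not a pure cosine in either coordinate.

Position terms `(A0, C0)` are stored alongside but excluded from the feature
columns, matching the "4 coefficients per harmonic" feature count; position
is already standardized.

## Shape space and reconstruction

`fit_pca()` performs PCA on the sample variance–covariance matrix
(denominator `n - 1`, no column standardization — the features share units).
Eigenvector sign is intrinsically arbitrary; the package fixes it by making
the largest-magnitude loading positive (first index on ties) so scores are
reproducible across refits, including cross-validation folds.
`reconstruct_pc_extremes()` renders `mean ± 2 SD` along each component —
SPP descriptors reshape directly to coordinates, EFD descriptors invert
through the Fourier series — which is how the morphological meaning of a PC
is inspected. Accession-level traits are arithmetic means of the seed-level
descriptors or scores (`average_by_accession()`); PCA is always fitted on
seeds first and averaged second. Trait similarity is summarized by
`trait_cluster()` with the distance `d = 1 - r^2` (r the Pearson correlation
across accessions) under centroid linkage; the analysis runs at accession
level, where the traits that enter association scans live.

## Genomic prediction and GWAS

Markers are coded 0/1/2, filtered at MAF > 0.03, and summarized by the
additive relationship `A = WW' / (2 Σ p_j(1-p_j))` with `W` the
frequency-centered codes (`additive_relationship()`). Two predictors are
available per PC score (each PC is modeled separately):

* **GBLUP** — `y = μ + u + e`, `u ~ (0, σ²_u K)`. Variance components are
  estimated by REML, profiled over `λ = σ²_u/σ²_e` on the spectral
  decomposition of `K` and minimized by one-dimensional search — a
  deterministic fit with no convergence failures. Test-line values come from
  the kinship cross-block, `û_test = σ²_u K_{te,tr} V⁻¹_{tr}(y - μ)`.
* **RKHS** — multi-kernel Gaussian regression with `K_h = exp(-hD)`, `D` the
  squared-Euclidean genotype distances and bandwidths `h = X/M` for
  `X ∈ {1/5, 1, 5}`, `M` the median off-diagonal of `D` (kernel averaging).
  One variance component per kernel plus a residual, estimated by a damped
  fixed-point iteration on the REML score equations
  (`y'PK_kPy = tr(PK_k)`), with a positivity floor.

Both fits are deterministic given the data; a Monte-Carlo (MCMC) fit of the
same models would add sampling noise without changing the point predictions
appreciably, which is why the package uses REML throughout.

Contour-level accuracy is the cross-validated statistic

`Q² = 1 - Σ_l Σ_t [(x̄_lt - x̂_lt)² + (ȳ_lt - ŷ_lt)²] / Σ_l Σ_t [(x̄_lt - x̿_t)² + (ȳ_lt - ȳ̿_t)²]`

over `L` accessions and `T = 500` contour points, where predicted
descriptors are rebuilt from the first 30 predicted PC scores (components
beyond 30 are set to their mean) and rendered as contours. `Q² = 1` is
perfect, `Q² = 0` is no better than predicting the grand-mean shape, and
worse-than-mean predictions go negative. `predict_shape_cv()` runs repeated
10-fold cross-validation; one fold matrix per replicate
(`make_cv_folds()`) is shared across every method × procedure combination so
the replicate-level Q² values form a paired design, compared with
`compare_methods_anova()` (main-effect F tests for the scale and direction
factors).

The association scan (`gwas_qk()`) is the Q+K mixed model
`y = mβ + Qv + u + e` with `u ~ (0, σ²_g K)` and `Q` the first 6 genotype
PCs. Variance components are estimated once on the marker-free null model
and held fixed for every marker (the P3D/EMMAX approximation — the norm for
this model family; per-marker REML would cost three orders of magnitude more
for a near-identical ranking). Each marker then gets a GLS t-test after
whitening by the null covariance; markers collinear with the covariates are
flagged with `p = 1`. Significance is controlled at 5% FDR by the
Benjamini–Hochberg step-up rule (`bh_threshold()`).

GWAS traits are accession means of seed-level PC scores (equivalently,
projections of accession-mean descriptors, since both averaging and
projection are linear).

## The synthetic generator

`simulate_genotypes()` draws a Balding–Nichols structured panel: ancestral
frequencies uniform on (0.1, 0.9), subpopulation frequencies Beta-diverged
with `Fst = 0.15` across 3 subpopulations (so the 6-PC structure correction
is exercised meaningfully), inbred lines (codes 0/2 with 1% residual
heterozygosity), 2,000 markers on 10 chromosomes at desk scale — a reduced
image of a RAD-seq diversity panel.

`simulate_shapes()` builds each seed from a superellipse template (exponent
2.5) deformed by four heritable latent modes: overall log-size, front-view
log-aspect, side-view log-aspect, and the depth of a Gaussian indentation at
the base landmark (the landmark sits in the dent, as on a real seed). Mode
variances default to the ratio 10:5:2:1 (0.130, 0.065, 0.026, 0.013): a
diverse collection varies strongly in size, substantially in elongation and
modestly in the local base geometry. Heritabilities default to
0.8/0.7/0.6/0.5 — size the most heritable, so the benchmark reproduces the
qualitative finding that unscaled (size-carrying) descriptors predict
better than scaled ones. Each mode's genetic value is a sum of 20 planted
QTL effects rescaled to `h² x` the mode variance; per-seed environmental
mode noise carries the complement.

Two environmental layers act on the rendered outline. A *smooth radial
deformation field* (harmonics 2–8, per-component sd `0.02/k^1.5`) models
biological seed-to-seed irregularity, which is smooth at the scale of the
outline; and iid per-point jitter of sd 0.5% of the mean radius models
digitisation error. Separating the two matters: white jitter alone is not a
realistic environmental model, and the smooth field is what populates the
mid-rank principal components with reproducible, congruent structure.

What the generator does **not** emulate: linkage disequilibrium and
realistic recombination maps (markers are exchangeable given structure),
pericarp texture or color, lighting/segmentation artifacts, and any
allometry linking size to shape beyond the multiplicative template. Tests
passing on this generator therefore validate the pipeline's mechanics and
statistical calibration, not the biology of any particular crop.

`render_masks()` rasterizes contours by even-odd scanline fill and emits the
landmark table in the ingest format, closing the loop so the image-side code
path can be tested end to end (a traced, resampled mask stays within one
pixel of its source outline on average).

## Numerical choices and degenerate inputs

* Coordinates are x-right/y-up with 0-based pixel centers; image rows are
  negated at ingest so orientation math is conventional.
* GPA convergence: consensus displacement < 1e-10, at most 200 iterations,
  warning plus best iterate on non-convergence.
* Near-circular contours make the first-harmonic axis unstable; FESA/FESL
  warn when `E/e < 1.01` and the circle itself reports `psi1 = 0` by
  convention. A base landmark coinciding with the centroid is an error for
  SL; a point-mass contour is an error for the harmonic fit.
* `Q²` is undefined (error) when all accession mean contours are identical;
  predictions worse than the grand mean are reported as negative values,
  not clamped.
* BH with no qualifying p-value returns an empty significant set and an
  `NA` threshold.
* RKHS variance iteration is capped at 200 steps with a relative tolerance
  of 1e-6 and a floor of `1e-8 x var(y)` per component.

## Problem sizes used by the test suite

The standard population is 300 accessions × 10 seeds with 2,000 markers —
large enough for stable eigenstructure and calibrated tests, small enough to
run in seconds. Calibration experiments use 100 replicates of a
100-line/2,000-marker null for the type-I error of the scan, 10 replicates
of a 300-line panel for QTL power, and 10 replicates of a 600-line panel
(one seed per accession, 5-fold CV) for heritability-rank recovery — the
larger panel gives the rank test enough power to resolve heritabilities 0.8
vs 0.5 reliably. These sizes are the package's benchmark conditions, chosen
once; they are deliberately far below a real RAD-seq panel (hundreds of
accessions × tens of thousands of markers), which the same code handles by
the same O(n³)-per-fit algebra.

## Known limitations

* The base landmark is an input, not detected; no interactive tools.
* Only two views (front/side) and 2D outlines; no 3D superposition or
  sliding semi-landmarks.
* GWAS assumes a complete, imputed genotype matrix; no missing-data
  handling or imputation.
* The ANOVA on Q² treats replicates as independent; with shared CV folds
  this is the paired design intended, but p-values inherit the usual
  optimism of resampled accuracy comparisons.
* Numerical identity with other EFD/GPA implementations is not guaranteed
  where conventions are unstated in the field (start-phase handling, axis
  disambiguation, GPA scale semantics); the package's rules are documented
  above and fixed.
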