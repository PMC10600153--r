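---
title: "Methods: single-cell morphological and topological profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell morphological and topological profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scmtop)
```

This vignette is the package's own account of its methods: the models and
conventions each stage implements, the parameters that matter, the choices
made where the design was genuinely open, and what the synthetic-data tests
do and do not demonstrate.

## Input model

The unit of analysis is one whole-slide image (WSI) that has already been
segmented by a nuclear segmentation/classification network. The package
consumes a JSON map from nucleus id to `{bbox, centroid, contour, type}`
with the five-class integer coding 1 = tumor, 2 = inflammatory,
3 = stroma (connective), 4 = dead (necrotic), 5 = normal (non-neoplastic
epithelial); code 0 (unlabelled) is dropped with a warning. Coordinates are
0-based pixels, x rightward, y downward, and all distances are Euclidean in
pixels. The microns-per-pixel scale defaults to `mpp = 0.25`, so the 100-px
edge threshold below equals 25 um and a 200-um spot is 800 px. Dead nuclei
are excluded from every analysis; normal cells are retained only in
composition summaries ("non-necrotic total") and are excluded from feature
profiling and graphs, which cover tumor, inflammatory and stroma cells.
Nuclei touching slide borders are kept: the segmentation already decided
they are nuclei, and dropping them would bias spot-level counts near the
grid boundary.

## Morphological features

The contour polygon is rasterized to a binary mask with pixel-center
semantics (a pixel belongs to the mask when its integer-grid center is
inside the polygon or on its boundary). Including the boundary makes an
axis-aligned square with vertices (0,0)-(9,9) a full 10 x 10 mask, so
`Extent = Solidity = 1` for convex bbox-filling shapes, which is the
convention the feature names imply. Then:

- `Area` = mask pixel count; `AreaBbox` = bbox pixel count;
  `Extent` = Area/AreaBbox.
- `Perimeter` = polygon perimeter of the contour;
  `Circularity` = 4 pi Area / Perimeter^2.
- `Solidity` = Area over the rasterized convex hull's pixel count
  (rasterizing the hull keeps numerator and denominator in the same
  pixel-count units; mixing mask counts with continuous polygon areas can
  push Solidity above 1).
- `MajorAxisLength`/`MinorAxisLength` = 4 sqrt(eigenvalues) of the mask's
  central second-moment matrix (the ellipse with equal moments),
  `CellEccentricities` = sqrt(1 - lambda2/lambda1),
  `Elongation` = 1 - Minor/Major.
- Curvature: the contour is resampled to 128 points of uniform arc length,
  smoothed with a circular Gaussian of sigma = 2 samples, oriented so a
  circle has positive curvature, and
  kappa = (x'y'' - y'x'') / (x'^2 + y'^2)^(3/2) is evaluated by central
  differences; `CurvMean/Max/Min/Std` summarize the samples. Smoothing is
  needed because raw segmentation contours carry pixel-level staircase
  noise that would otherwise dominate the curvature extrema; sigma = 2
  samples suppresses that scale while preserving lobes of the nucleus
  outline.

Tests validate these against analytic shapes (disk of radius 20 px: Area
within 2 % of 1256.6, Circularity within 5 % of 1) and against brute-force
pixel-moment enumeration on random blob contours; translation invariance is
exact for integer shifts, and scale relations (Area ~ s^2, Perimeter ~ s)
hold to rasterization tolerance.

## Texture features

The grayscale patch cropped to the nucleus bbox is quantized to 32 gray
levels (8-bit input, fixed bin width 8). Symmetric co-occurrence matrices
are tabulated at the four unit offsets (0, 45, 90, 135 degrees), counting
only pixel pairs with **both** pixels inside the nuclear mask, normalized,
and ASM, Contrast, Correlation, Entropy (bits) and Homogeneity are averaged
over the four angles; angle-averaging removes orientation artifacts.
Correlation of a zero-variance patch is defined as 0. Intensity statistics
(mean, population SD, max, min) use masked pixels only. Texture is
optional: without an image the columns are NA and downstream stages
restrict themselves to morphology (MITH then uses N = 14 features).

## Pairwise cell graphs

For each ordered type pair (C1, C2) from {T, I, S}, every C1 cell proposes
edges to its k = 5 nearest **C2** cells; for heterotypic pairs the
symmetric direction is added; proposals with length >= 100 px are deleted
(strict `<`, so a 100.0-px pair is not connected) and the union is
deduplicated into an undirected graph. Restricting the candidate set to the
partner type is the reading that keeps heterotypic graphs meaningful: if
neighbors were searched among all cells, a tumor cell inside a tumor nest
would spend its k slots on other tumor cells and T-I/T-S graphs would be
nearly empty. Distance ties are broken by nucleus id order so the graphs
are deterministic. Graphs are undirected for all feature purposes.

Per graph and cell: `Nsubgraph` (connected-component size, >= 1),
`MinEdgeLength`/`MeanEdgeLength` over incident edges with the 100-px
sentinel for isolated cells (100 is the upper limit of a connectable
distance, so the sentinel is continuous with the feature's range),
`Degrees`, `Coreness` (k-core number in the whole graph), `Eccentricity`
within the component, `Eccentricity_normed` = Eccentricity / component
diameter (0 for singletons), `HarmonicCentrality` and `Closeness` within
the component (Closeness 0 for isolated cells), `Betweenness` and
`Betweenness_normed` = Betweenness / ((n-1)(n-2)/2) with n the component
size (0 when n < 3), and for homotypic graphs the local
`ClusteringCoefficient` (0 for degree < 2). Heterotypic graphs are
bipartite, so every local clustering coefficient is structurally zero and
the column is omitted. The component-wise normalizations are our choice
where only the feature names were given; they make the normalized values
comparable across components of different sizes.

`StromaBlocker` (inflammatory cells only) is a reconstruction whose exact
published formula was not available: for each inflammatory cell, its
k = 5 nearest tumor cells within a 300-px radius are taken and the stroma
centroids within a 15-px half-width corridor of each straight
inflammatory-to-tumor segment are counted; the feature is the mean count
(0 when no tumor cell is in range). All three parameters are exposed and
the feature is documented as a corridor-count barrier measure; analyses
that need the published definition should treat it as such.

## Cell clustering and extrapolation

Per cell type, 0.5 % of cells are sampled per slide (at least one per
nonempty slide), features are shifted per feature by their pooled minimum
where negative (curvature features can be negative; the shift is stored
with the model), log1p-transformed, z-scored, projected on up to 50
principal components, and clustered with Leiden (modularity objective) on
an unweighted k = 15 nearest-neighbor graph. Clusters are relabelled
0-based by decreasing size and prefixed TUM/INF/STR. The resolution
default is 1.0; cluster granularity is data-dependent, and the
planted-blob recovery tests use a coarse resolution (0.05) because two
compact Gaussian blobs are a much coarser structure than the many-cluster
regime the default targets.

Extrapolation holds the reference memberships fixed: the new cohort is
preprocessed over the model's feature set (by default with its own
log/scale statistics, mirroring a per-cohort preprocessing convention;
`reuse_reference_scaling = TRUE` applies the stored reference parameters
instead, which is the right choice when the new cohort's composition is
shifted, e.g. dominated by one cluster), the joint PCA space is recomputed
on the concatenated scaled matrices, and a seeded constrained local-move
pass over the joint kNN graph assigns each new cell the existing label
with maximal modularity gain, iterated to convergence, with reference
vertices frozen. New cells can only receive existing labels; reference
labels are unchanged by construction. (The R igraph Leiden interface has
no fixed-membership argument, so this constrained pass is implemented in
the package; its semantics — frozen reference, greedy modularity moves for
new cells — are what the fixed-membership option of the Python
implementation provides.)

The AIC (aggregated inflammatory cell) score of a sample is the summed
abundance of the locally aggregated inflammatory clusters, INF0, INF1,
INF6 and INF7 by default; which clusters are "aggregated" is a finding
about a particular cohort, so the set is a parameter.

## MITH

All tumor nuclei of all samples are pooled and each feature is z-scored
globally with the **population** SD (a two-point feature {0, 2} maps to
{-1, +1}). For a sample with M >= 2 tumor nuclei,
`MITH = (1/N) sum_i sqrt( sum_j (x_ij - xbar_i)^2 / M )` — the mean over
features of the per-sample population SD, exactly as the formula divides
by M and not M - 1. MITH is computed on all tumor nuclei, not the
clustering subsample: it is cheap, and subsampling would only add noise. A
robust (median/MAD) normalization variant is available by argument.
Because the normalization is global, MITH is a *relative* statistic: a
single-sample cohort always has MITH near 1, and the dispersion
monotonicity test therefore pools a low- and a high-dispersion sample
under one normalization.

## Spots, spatial correlation and MEMs

Slides are tessellated into non-overlapping square spots of 200 um
(half-open intervals; a cell exactly on a boundary belongs to the
higher-index spot; the grid origin is fixed at pixel (0, 0) with no offset
search). Spots straddling the border are kept, and empty spots remain in
the grid (they are assigned `Module0_NC` at scoring).

Colocalization of two cell clusters x and y uses the bivariate extension
of Moran's I,
`C = (Ns/W) * sum_ij w_ij (x_i - xbar)(y_j - ybar) / (sqrt(sum (x-xbar)^2) sqrt(sum (y-ybar)^2))`,
and spatial organization of a single field uses Moran's I; both share
binary rook weights (up to four orthogonal grid neighbors, w_ii = 0). The
univariate statistic specifies "four nearest neighbors"; on a square grid
the four orthogonal neighbors are exactly that, and using the same scheme
for the bivariate statistic keeps the identity C(x, x) = I(x), which the
tests verify to 1e-10. (k-nearest spot centers are available as an
alternative scheme but would introduce corner ties.) Fields with zero
variance return 0 with a `degenerate` flag.

Per-sample cluster x cluster correlation matrices are averaged element-wise
across samples ignoring degenerate entries, symmetrized as (C + t(C))/2,
and the clusters are grouped by Ward clustering (ward.D2 on Euclidean
distances between matrix rows, i.e. between correlation profiles) cut into
`n_modules` groups (default 8). The cut criterion was open; a fixed
module count mirrors a `maxclust`-style cut and keeps module identity
stable across reruns. Spot module scores are the fraction of the spot's
cells in the module's clusters (scores sum to 1 for nonempty spots);
assignment is the maximum score with ties to the first module in model
order. Intra-/inter-MEM variation of cell-type proportions uses population
SDs, excludes `Module0_NC` spots, and counts modules with fewer than 2
spots as SD 0 with a warning.

## Ecotypes

Per-sample MEM composition is the fraction of classified spots per module;
`Module0_NC` spots are excluded from the denominator by default (they
carry no cellular signal, and their share depends on how much empty glass
the scan includes, which is a property of the scan rather than the tumor).
Ward clustering of the composition vectors yields ecotypes; k is chosen
over 2..10 by maximal mean Silhouette with ties broken by
Calinski-Harabasz — two indices were named without a combination rule, and
Silhouette-first is scale-free while CH provides a deterministic
tie-break. The classifier is an RBF-kernel SVM (kernel unstated in the
source method; RBF is the e1071 default and handles the compositional
simplex geometry) trained on a stratified 80/20 split and reported as
held-out weighted F1.

## Synthetic data

The generator plants every structure the pipeline is supposed to recover:

- **Point patterns.** Homogeneous Poisson, Thomas cluster (Poisson
  parents, Poisson offspring counts, Gaussian displacement; offspring
  falling outside the slide are discarded) and region-restricted uniform
  processes, at intensities in cells/mm^2. Default intensities
  (250-500 cells/mm^2 per type or cluster) give tens of cells per 200-um
  spot, the regime where spot statistics are informative.
- **Contours.** Ellipses (log-normal axis ratio) with radial Fourier
  perturbation at harmonics 2-4; the perturbation amplitude controls
  morphological dispersion, and MITH responds monotonically to it (tested).
- **Patches.** 8-bit Gaussian noise around a per-type mean gray level,
  with optional stripe patterns for controllable GLCM contrast.
- **Cohorts.** Slides tiled into blocks of 2 x 2 spots; each block hosts
  one of four planted modules (two co-placed cell clusters each), drawn
  from an archetype-specific mixture (dominant weight 0.7, log-normal
  noise 0.1); 40 samples over 4 archetypes. This plants the full
  hierarchy: cluster colocalization within blocks, module composition per
  sample, and ecotype structure across samples.

What passing these tests shows: the statistics, graph constructions and
recovery procedures are implemented correctly and recover structure they
are designed to see, at desk scale (fields of up to 500 cells for graph
oracles, 1600-um slides with 64 spots, 40-sample cohorts; the whole suite
runs in minutes on one CPU — sizes chosen so the oracles, which are
O(n^2) or worse, stay exact and fast). What it does not show: performance
on real H&E, where segmentation errors, staining variability, tissue
artifacts and much larger n dominate; the synthetic nuclei are smooth
perturbed ellipses, the texture model is stationary noise rather than
chromatin, and the planted modules are far better separated than real
micro-anatomy. Cohort-level findings (which clusters are "aggregated
inflammatory", the number of modules or ecotypes in a cancer type) are
properties of data, not of this implementation.

## Numerical conventions collected

- Population SD everywhere a formula divides by M (MITH, intensity SD,
  MEM variation); sample SD only inside the clustering z-scoring, where
  it is a preprocessing convention, not a reported statistic.
- Degenerate inputs: zero-variance features are dropped with a warning;
  zero-variance spot fields return 0 with a flag; empty spots are
  `Module0_NC`; samples with M < 2 tumor nuclei have MITH = NA; samples
  with no cells of a type have NA abundance rows.
- Determinism: every stochastic step (sampling, Leiden, extrapolation
  initialization, splits, simulation) takes an integer seed; kNN ties are
  broken by id order; identical seeds give identical outputs, which the
  suite checks byte-for-byte on pipeline CSVs.
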