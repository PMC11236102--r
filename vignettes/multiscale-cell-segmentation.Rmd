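---
title: "Multi-scale manifold cell segmentation: model, parameters and design notes"
author: "spotseg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale manifold cell segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spotseg)
```

## The problem

Imaging-based spatial transcriptomics assays resolve individual RNA
molecules in situ. The raw data is a cloud of *spots*: each has 2D or 3D
physical coordinates and a categorical gene tag, and nothing else — no cell
boundaries, no nucleus stain required. Cell *instance* segmentation means
assigning every spot to an individual cell (not merely a cell type), with
unassignable spots marked as noise. `spotseg` approaches this as manifold
learning on a fused spatial–transcriptomic dissimilarity, followed by
density clustering in the learned low-dimensional space.

## The model, stage by stage

### Outlier filtering

Before any feature computation, spots whose Euclidean nearest-neighbor
distance exceeds a threshold are removed. No universal threshold exists
across assays and magnifications, so the default is scale-free: the 99th
percentile of the nearest-neighbor-distance distribution, with an absolute
override. A single pass is made; removing a spot can raise its former
neighbors' nearest-neighbor distances, so the operation is deliberately not
iterated (iterating can eat into sparse cell boundaries).

### Multi-scale neighborhood gene composition (MSNGC)

Every spot's local transcriptomic context is summarized as a `c × L` count
matrix: row β counts, per gene tag, the surrounding spots within the
scale-β neighborhood. Defaults: scale factors (1, 3, 5) over a base radius
of 10 coordinate units in x/y and 7 in z (anisotropic axial resolution is
the norm in these assays; the 3D neighborhood is the axis-scaled ellipsoid
`(Δx²+Δy²)/(βR_xy)² + Δz²/(βR_z)² ≤ 1`, boundary inclusive). The close
scale sees subcellular composition, the mid scale roughly one cell, the
long scale a cell plus its surroundings. The spot's own tag is excluded —
it is constant with respect to the spot and would only dilute contrast.
Counts are exact: the spatial query is chunked but equivalent to an
all-pairs scan (and is tested against one).

### Fused ST distance

Two spots are compared by `D(i,j) = d_Manhattan(i,j) · (1 − ρ(Mᵢ, Mⱼ))`.
ρ is computed **per scale** as the Pearson correlation between the two
spots' scale-β rows and then averaged over scales. Averaging (rather than
summing) keeps ρ in [−1, 1] and hence D non-negative with a factor in
[0, 2]; a scale where either row is constant (isolated spots, empty
neighborhoods) contributes 0 — no evidence, no effect. A raw sum over
scales would leave the range of the correlation term at [−c, c] and could
make the distance negative, which the downstream graph construction cannot
accept. D is symmetric and non-negative but *not* a metric: a high
correlation shrinks a large physical separation, so the triangle inequality
can fail. The pipeline only requires symmetry and non-negativity, but the
violation has one practical consequence for approximate neighbor search
(see NN-descent below).

### Fuzzy k-NN graph

For each spot the k (default 50, sensible range 2–100) nearest others under
D are found — exactly, via the full distance matrix, up to N = 20,000;
above that by a seeded NN-descent. Each row is then calibrated: with δᵢ the
distance to the nearest neighbor, σᵢ solves

    Σⱼ exp(−max{0, Dᵢⱼ − δᵢ}/σᵢ) = log₂(k)

by vectorized bisection (tolerance 1e-5, at most 64 bracket doublings and
64 bisection steps; the lower search bound is 1e-3 × the row's mean
distance). The weight sum is monotone in σ, so bisection is reliable; when
every distance in a row ties with δᵢ the sum is identically k, the target
is unattainable, σ is pinned at the lower bound and the row is flagged.
The nearest neighbor always receives weight exactly 1, which guarantees
every spot at least one strong edge. Directed weights are symmetrized by
the probabilistic union `A = w + wᵀ − w∘wᵀ`, which is symmetric, bounded by
[0, 1], monotone in each direction, and reduces to the single weight for
one-sided edges.

### Spectral initialization

Initial coordinates come from the symmetric normalized Laplacian
`L = I − D^{-1/2} A D^{-1/2}`: eigenvectors 2..d+1 by ascending eigenvalue
(the first is trivial), scaled so the largest absolute coordinate is 10,
with signs fixed by making each column's largest-magnitude entry positive.
Up to N = 2048 a dense eigendecomposition is used; above that, a
deterministic seeded subspace (orthogonal) iteration on the normalized
adjacency with sparse matrix–vector products and a final Rayleigh–Ritz
step — precision requirements are modest because this is only an
initializer. Zero-degree vertices get small seeded random coordinates.

### Embedding optimization

The layout minimizes the cross-entropy between graph weights `p = A` and
low-dimensional similarities `q = (1 + a‖yᵢ−yⱼ‖^{2b})⁻¹`, summed over
ordered pairs (p and q are symmetric, so every unordered pair is counted
twice; the reported exact CE follows that convention). `a` and `b` are fit
once from `min_dist = 0.1` and `spread = 1.0` by least squares against the
piecewise target curve (1 up to `min_dist`, exponential decay beyond),
giving a ≈ 1.58, b ≈ 0.90.

The optimizer is stochastic gradient descent with the standard
manifold-layout conventions: edges sampled proportionally to their weight,
attractive updates moving both endpoints, five uniform non-neighbor
negative samples per positive (repulsive updates on the head only,
weighted by `repulsion_strength`, default 1), per-component gradient
clipping at ±4, and a learning rate decaying linearly from 1.0 to 0 over
the epochs (500 for N ≤ 5000, 200 above — larger data sets visit more
edges per epoch). Sampling uses a self-contained xorshift RNG, so a given
integer seed reproduces the layout bit-for-bit.

Negative sampling optimizes a *subsampled* surrogate of the exact
cross-entropy, and on weakly structured graphs the exact objective can
drift upward even as the surrogate falls. Where the exact objective is
computable (N ≤ 500) the result is therefore checked against the
initialization, and if the stochastic phase ended higher, a deterministic
full-batch repair runs instead: gradient descent on the exact CE from the
initial coordinates with a backtracking line search that never accepts an
uphill step. The returned exact CE consequently never exceeds its value at
the initialization. The repair is intentionally *not* run when the
stochastic phase already improved the exact objective: full minimization of
the exact CE applies unsubsampled repulsion to every non-neighbor pair —
including same-cell pairs beyond the k-NN horizon — and inflates clusters,
which is precisely the pathology negative sampling exists to avoid.

### Density clustering and eps

DBSCAN is implemented from scratch on Euclidean distance in the embedding:
a core point has at least `min_samples` points (itself included — the
self-inclusive reading matches the usual "at least minPts points within ε"
phrasing) in its inclusive eps-ball; clusters are connected components of
cores plus density-reachable border points; the rest is noise (−1). Points
are scanned in ascending index order and a border point reachable from
several clusters joins the earliest-formed one, making labels
deterministic and order-equivariant up to renaming.

`min_samples` defaults to 4. A default of 1 is sometimes quoted for this
method, but it makes every point a core point and silently disables noise
detection; the CLI warns when it is selected. `eps` has no universal value
either; the default is a k-dist heuristic computed on the embedding: 3 ×
the 99th percentile of the distance to the `min_samples`-th nearest
neighbor. The embedding compresses cells into blobs whose internal point
spacing is an order of magnitude below the blob separation, so any radius
in that window works; the 3× multiplier additionally bridges low-density
necks inside elongated cells. Both the percentile and multiplier are
exposed.

### Center refinement

After the first clustering, the representative spot of each cluster (the
member nearest the cluster's coordinate mean; ties to the lowest index) is
found, pairwise ST distances among these centers are converted to fuzzy
weights with the same calibration machinery (k capped at one less than the
number of centers), and the center–center edges are folded into A by fuzzy
union — existing edges can only strengthen. The spectral initialization and
the optimization are then rerun and the embedding re-clustered. One round
by default; with fewer than three clusters the round is skipped with a
warning. The refinement couples clusters that share transcriptomic context,
nudging related cells toward consistent neighborhoods in the re-embedding.

## Evaluation metrics

ARI is computed from the contingency table in its adjusted form; NMI as
`2·MI/(H(Y)+H(C))` with natural-log entropies (the base cancels), with the
conventions MI ≤ 0 → 0 and H(Y)+H(C) = 0 → 1; the silhouette coefficient
as the mean of `(bᵢ−aᵢ)/max(aᵢ,bᵢ)` with singletons scoring 0, computed by
default in the clustering space (the space DBSCAN actually operated in —
the choice is exposed, and physical-space silhouettes are also supported).
Spots predicted as noise, and spots whose ground truth is background, are
excluded from scoring by default; a flag instead treats predicted noise as
its own cluster. All three implementations are tested to 1e-12 against
independent oracles (pair counting, joint-histogram entropies, double
loops) and against `mclust`/`cluster` where those offer an equivalent.

## The simulator

The generator emulates the statistical skeleton of imaging-based data:
cells are compact isotropic clusters (truncated Gaussian, sd = radius/2) of
gene-tagged points; each cell type draws a gene-frequency profile once from
a symmetric Dirichlet (concentration 0.3 by default — spiky, distinctive
profiles); per-cell read counts are Poisson; background spots are uniform
in space and gene. Optional mechanisms create regimes where composition at
specific scales is (un)informative: `core_profile_mix` blends a shared
baseline into cell reads, and `context_fraction` places type-informative
spots in an annulus around each cell (ground-truth background). What it
does **not** emulate: irregular cell shapes, optical crowding and transcript
misidentification, subcellular RNA localization, tissue-scale morphology.
Passing tests on this simulator demonstrate that the pipeline recovers
compact cells with distinct composition profiles; they do not certify
performance on convoluted real-tissue morphologies.

Presets (chosen once as the package's reference conditions):

* **easy** — 30 cells, 3 types, 10 genes, ~150 reads/cell, centers 4 radii
  apart, no background. Every stage should succeed nearly perfectly.
* **medium** — same cells packed at 3 radii plus uniform background noise.
* **hard** — 20 large sparse cells (radius 25, ~100 reads) packed at 1.6
  radii so they physically overlap, 24 genes, light background. The close
  scale (R = 10) contains too few reads for a stable composition estimate,
  while the mid/long scales (2–5 base radii) aggregate a cell's own reads
  into a reliable type signature; geometry alone cannot split abutting
  cells. This construction realizes, in simulation, the regime where
  multi-scale features are expected to beat a single close scale — the
  direction the package's ablation test checks. Earlier candidate designs
  (shared-baseline cores with a type-specific context annulus) failed to
  isolate that regime: annulus context makes the close scale informative
  too, and non-overlapping truncated-Gaussian cells remain separable from
  geometry alone.

## Problem sizes and numerical choices

The test suite runs the full pipeline on fields of roughly 2,000–4,600
spots (the presets above) and exercises unit properties on fields of
100–500 spots; brute-force oracles (all-pairs counts, dense unions,
double-loop objectives, reference DBSCAN) back every derived value. Sizes
were chosen so the suite doubles as executable documentation of the
reference conditions. Other numerical choices collected in one place:
q is clamped to [1e-12, 1−1e-12] inside the cross-entropy; squared
distances are floored at 1e-12 in the full-batch gradient; the inclusive
neighborhood boundary carries a 1+1e-12 relative guard against rounding;
k-NN ties break to the lower spot index; eigen-sign is fixed per column;
DBSCAN scan order is ascending index.

## Known limitations

* **Sub-cluster fragmentation at very few components.** With only a handful
  of graph components, the spectral initializer's extra dimensions are
  *internal* cell modes; a cell initialized as two lobes can settle into
  two nearby blobs, because weak cross-lobe edges are sampled too rarely to
  overcome accumulated repulsion. In fields with many cells every component
  initializes near a point and the effect disappears. Raising `eps` or
  `repulsion_strength`-aware re-runs are practical workarounds.
* **NN-descent under a non-metric.** Because the ST distance violates the
  triangle inequality, local-join NN-descent can miss occasional
  far-in-space/close-in-feature neighbors (measured recall ≈ 99.5% on test
  fields). The exact path is used up to N = 20,000.
* **Memory.** The exact k-NN path materializes the N × N distance matrix
  (O(N²) doubles).
* **`min_samples = 1`** disables noise detection by construction.
* The refinement's center edges are few relative to N; it polishes
  borderline cases but cannot rescue a badly fragmented first clustering.
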