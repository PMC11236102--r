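# spotseg

Cell segmentation for imaging-based spatial transcriptomics by multi-scale
manifold learning.

Imaging-based assays (STARmap, MERFISH and relatives) detect individual RNA
molecules — *spots* — each with physical coordinates and a gene tag, but no
cell boundaries. `spotseg` assigns every spot to an individual cell by
clustering a learned low-dimensional representation of the spot cloud:

1. **Multi-scale neighborhood gene composition (MSNGC).** Every spot *i* gets
   a `c × L` matrix **M**ᵢ counting the gene tags of surrounding spots within
   concentric neighborhoods of radius *R*, 3*R* and 5*R* (axis-scaled
   ellipsoids in 3D).
2. **Fused spatial-transcriptomic (ST) distance.**
   `D(i, j) = d_Manhattan(i, j) · (1 − ρ(Mᵢ, Mⱼ))`, where ρ is the mean
   per-scale Pearson correlation of the MSNGC rows. Physically close spots
   with matching local transcriptomic context become near neighbors.
3. **Fuzzy k-NN manifold graph.** For each spot, the k nearest spots under
   `D`; per-spot bandwidths σᵢ solve
   `Σⱼ exp(−max{0, Dᵢⱼ − δᵢ}/σᵢ) = log₂(k)` with δᵢ the nearest-neighbor
   distance; directed weights are symmetrized by the fuzzy union
   `A = w + wᵀ − w ∘ wᵀ`.
4. **Embedding.** Spectral initialization from the normalized graph
   Laplacian, then stochastic gradient descent on the cross-entropy between
   graph weights `p = A` and low-dimensional similarities
   `q = (1 + a‖yᵢ−yⱼ‖^{2b})⁻¹`.
5. **Segmentation.** DBSCAN in the embedding (noise = `-1`), followed by a
   refinement round that injects cluster-center–to–center edges back into
   the graph and re-embeds.

The package also ships the three standard evaluation metrics (adjusted Rand
index, normalized mutual information, silhouette coefficient) implemented
from their defining formulas, and a synthetic spot-cloud simulator with
per-spot ground truth so the entire pipeline can be validated without any
external data.

## Worked example

```r
library(spotseg)

# 30 simulated cells, 3 cell types, ~150 reads each, no background noise
sim <- simulate_spots(make_separable_preset("easy", seed = 1))
sim$spots
#> spot_table: 4527 spots, 2D, 10 gene tags

res <- segment(sim$spots, segmentation_config(seed = 1))
res
#> segmentation_result: 4527 spots, 30 clusters, 46 noise/filtered (eps 0.4239)

evaluate_segmentation(sim$truth$spot_cell, res$labels)
#> $ari
#> [1] 1
#> $nmi
#> [1] 1
```

All 30 simulated cells are recovered as distinct clusters; ARI and NMI of 1
mean every scored spot (spots the outlier filter removed are labeled `-1`
and excluded) is assigned to the right cell instance. `res$eps_used` is the
DBSCAN radius chosen by the k-dist heuristic on the embedding.

The same pipeline is available from the shell via the bundled CLI
(`inst/cli/spotseg`): `simulate`, `segment`, `evaluate`, `msngc-export` and
`graph-export` subcommands; all tabular I/O is headered CSV and run metadata
is JSON.

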