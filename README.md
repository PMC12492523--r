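# angionet

Graph-theoretic quantification of endothelial tube-formation (angiogenesis)
assays.

Tube-formation assays — endothelial cells (typically HUVECs) self-organizing
into capillary-like meshes on basement-membrane matrix — are a standard in
vitro readout of angiogenic potential, but they are usually quantified with
object-level morphometrics (total tubule length, junction counts) that treat
the network as a bag of disconnected features. `angionet` instead converts
each brightfield micrograph into a weighted mathematical graph and measures
the network as an integrated system, for researchers running angiogenesis
assays, screening pro- or anti-angiogenic treatments, or studying vascular
remodeling dynamics.

## The method

Each image is processed as follows:

1. **Preprocessing** — grayscale conversion, Gaussian smoothing (σ = 1 px),
   Otsu thresholding, and removal of 8-connected components smaller than
   64 px, yielding a binary tubule mask.
2. **Skeletonization** — iterative morphological thinning to a 1-px-wide,
   topology-preserving centerline.
3. **Pixel graph** — every skeleton pixel `p_i = (x_i, y_i)` becomes a node;
   an undirected edge `e_ij` exists whenever
   `sqrt((x_i − x_j)² + (y_i − y_j)²) ≤ √2` (8-connectivity), weighted by
   that Euclidean distance (1 axial, √2 diagonal).
4. **Eleven network metrics** — |V|, |E|, average degree ⟨k⟩, average
   clustering coefficient `C_v = 2T_v / (k_v(k_v−1))`, global efficiency
   `E_global = (1/(|V|(|V|−1))) Σ_{i≠j} 1/d_ij` (disconnected pairs
   contribute 0), normalized average betweenness centrality
   `BC(v) = Σ σ_st(v)/σ_st`, average tortuosity `T_ij = L_ij / D_ij` over
   seeded random same-component node pairs, number of connected components,
   largest component size, the **connectivity index**
   `N_largest / N_total` (1 = fully integrated network), and network
   density `ND = 2E/(N(N−1))`.
5. **Radial zone analysis** — nodes are assigned to six concentric annuli of
   width Δr = 50 px around the image center (`k = ⌊d_i/Δr⌋ + 1`), counts are
   normalized by annular area `π(r_out² − r_in²)`, and five heterogeneity
   metrics summarize the density profile: SD, Shannon entropy (nats),
   coefficient of variation, center-to-edge gradient, and linear slope.
6. **Statistics** — per-metric two-group comparison with the Mann–Whitney U
   test, Cliff's delta effect size (negligible ≤ 0.147 < small ≤ 0.33 <
   medium ≤ 0.474 < large), ROC-AUC discriminability (positive class =
   dense), and Spearman correlation matrices across metrics.

A synthetic vascular-mesh generator (`generate_mesh_image()`) produces
dark-tubes-on-bright-background images with exact ground truth, emulating
sparse vs. dense seeding morphologies and early-timepoint fragmentation, so
the whole pipeline is testable without microscopy data.

## Worked example

```r
library(angionet)

syn <- generate_mesh_image(synthetic_preset("dense", rng_seed = 2))
rec <- analyze_image(syn$image, image_id = "dense_demo",
                     metrics = metric_config(rng_seed = 1))
print(rec)
#> Analysis record: dense_demo
#> Skeleton-graph metrics
#>   n_nodes                  3466
#>   n_edges                  4110
#>   avg_degree               2.37161
#>   avg_clustering           0.158502
#>   global_efficiency        0.00765355
#>   avg_betweenness          0.0719087
#>   avg_tortuosity           1.49142
#>   n_components             1
#>   largest_component_size   3466
#>   connectivity_index       1
#>   network_density          0.000684447
#> Radial heterogeneity metrics
#>   std_dev          0.0125166
#>   entropy          1.46058
#>   cv               0.705936
#>   radial_gradient  0.0331042
#>   linear_slope     -0.00562838
```

Reading the record: the dense synthetic mesh skeletonizes to 3466 node
pixels forming a single connected component (`n_components = 1`,
`connectivity_index = 1` — a fully integrated network). Average degree
≈ 2.37 reflects a skeleton of paths (degree 2) punctuated by junctions;
tortuosity ≈ 1.49 means network paths are about 49% longer than
straight-line distances. Entropy 1.46 (out of a ln 6 ≈ 1.79 maximum) with a
near-zero slope indicates a fairly even, isotropic radial spread of nodes.

Batch analysis and group comparison:

```r
tab <- analyze_images("path/to/images/", csv = "metrics.csv")
tab$group <- c("sparse", "dense")[...]   # your labels
compare_groups(tab, "group", "sparse", "dense")
#> one row per metric: U, p, stars, cliffs_delta, magnitude, auc, auc_flipped
```

The same pipeline is available from a shell via the thin CLI:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "angionet.R", package = "angionet"))') \
    analyze --images imgs/ --out results/ --figures
# also: compare --csv metrics.csv ... ; simulate --preset dense --seed 1
```

`--figures` writes the standardized four-panel output per image: original,
skeleton, graph overlay, node scatter.

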