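---
title: "Quantifying angiogenic networks as weighted pixel graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying angiogenic networks as weighted pixel graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angionet)
```

## The problem and the model

In vitro tube-formation assays measure the capacity of endothelial cells to
self-organize into capillary-like networks on a basement-membrane matrix.
`angionet` treats the imaged tubule network as what it functionally is — a
transport network — by reducing each brightfield micrograph to a weighted,
undirected graph whose nodes are skeleton pixels and whose edges join
8-adjacent pixels with Euclidean weights (1 for axial, √2 for diagonal
neighbors). Global transport properties (efficiency, betweenness), local
organization (degree, clustering), geometry (tortuosity), integration
(components, largest component, connectivity index `N_largest / N_total`),
and spatial patterning (radial zone analysis) are then measured on that
graph.

The modeling assumptions worth keeping in mind:

* **Binary vasculature.** Everything downstream of Otsu thresholding sees
  tube/not-tube; lumen diameter and intensity information are discarded
  (edge weights encode geometry of the centerline, not caliber).
* **Pixel-level nodes.** Nodes are *all* skeleton pixels, not only
  junctions. Counts and densities therefore scale with skeleton length, and
  degree ≈ 2 is the baseline of any smooth path. This makes the graph
  faithful to geometry at the cost of size-dependent metrics — hence the
  optional per-node normalization in the statistics layer
  (`normalize_per_node()`).
* **2D networks.** Z-structure, overlaps and crossings are projected; two
  tubes crossing in projection fuse into one junction.

## Pipeline parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `gaussian_sigma` | 1 | px | suppress high-frequency noise without erasing thin tubules |
| `min_object_size` | 64 | px | strict "< 64 removed": 64-px components are kept |
| `invert_foreground` | auto | — | minority side of the Otsu split is foreground |
| `delta_r` | 50 | px | annulus width; 6 zones cover radii up to 300 px |
| `n_zones` | 6 | — | six concentric annuli |
| `tortuosity_sample_pairs` | 100 | pairs | bounds the all-pairs cost on 10³–10⁴-node skeletons |
| `weighted_paths` | TRUE | — | Euclidean path lengths; hop counts available |

**Foreground polarity.** Otsu yields a threshold, not a polarity, and
brightfield tubules are usually darker than background but can invert with
illumination. The default takes whichever side of the threshold occupies
the *smaller* pixel fraction, on the grounds that tubules cover a minority
of the field in these assays; `invert_foreground` overrides this when a
field is mostly vessel.

**Weighted vs. hop-count paths.** Tortuosity is a geometric quantity and
*requires* Euclidean path lengths; for consistency, efficiency and
betweenness use the same weighted paths by default. `weighted_paths =
FALSE` switches those two to hop counts for users who want the purely
combinatorial variants — the ranking of images is typically unchanged,
because on a pixel graph edge weights live in the narrow set {1, √2}.

## Numerical and convention choices

* **Clustering coefficient** uses the standard Watts–Strogatz form
  `C_v = 2T_v / (k_v(k_v − 1))` with `C_v = 0` for `k_v < 2`, unweighted
  triangle counting, averaged over all nodes.
* **Disconnected pairs** contribute 0 to global efficiency (the `1/∞`
  convention), so efficiency is well defined on fragmented early-timepoint
  networks without special-casing.
* **Betweenness normalization** divides by `(|V|−1)(|V|−2)/2`, making
  average betweenness comparable across images of very different skeleton
  size; graphs with fewer than 3 nodes have no interior positions and
  return 0.
* **Tortuosity sampling** draws distinct unordered pairs uniformly from
  *same-component* pairs only (cross-component tortuosity is undefined),
  seeded via `metric_config(rng_seed = ...)`; when the requested sample
  covers all valid pairs the estimate is the exact all-pairs mean. A
  subtlety of pixel graphs: an L-shaped bend has a diagonal shortcut
  between the two pixels flanking the corner, so path lengths around bends
  are shorter than naive arc length — tortuosity values reflect the graph
  metric, not the drawn curve.
* **Degenerate graphs** produce `NA` sentinels with warnings (efficiency
  and density need ≥ 2 nodes, tortuosity needs a connected pair), never a
  fabricated 0. A batch run stays alive: a constant image yields an
  all-background mask with a warning rather than an error.
* **Gaussian boundary handling** uses symmetric (half-sample) reflection
  padding, so a constant image is reproduced exactly at the borders; the
  kernel is truncated at radius `⌈4σ⌉` and renormalized
  (`gaussian_kernel()` exposes it for verification).
* **Adjacency** is decided on integer Chebyshev distance 1, which is exact;
  the √2 threshold of the pairwise formulation is float-compared with a
  1e-9 guard only in the test oracle. The implementation scans the fixed
  half-neighborhood {E, S, SE, SW} so each edge is generated exactly once;
  the test suite proves set-identity against the O(n²) pairwise-distance
  construction.
* **Skeletonization** is iterative two-subpass parallel thinning
  (Zhang–Suen). Parallel deletion erases isolated compact 2×2 blobs
  entirely — a classic defect of the scheme — so a guard restores one
  representative pixel (nearest the component centroid) for any source
  component that would vanish, keeping the component count of skeleton and
  mask identical. One-pixel-wide lines are fixed points.
* **Zone boundaries** follow floor semantics: a node at distance exactly
  `k·Δr` belongs to zone `k + 1`. The geometric center is
  `((width−1)/2, (height−1)/2)` in 0-based pixel coordinates — symmetric
  for odd and even dimensions. Nodes beyond the outermost zone are excluded
  from densities but reported (`n_excluded`), so counts always conserve.
* **Entropy** is natural-log Shannon entropy of the area-normalized density
  shares (not raw counts, which would be dominated by the larger outer
  annuli); its maximum is `ln(n_zones)` exactly at uniformity. **SD** is
  the population SD over the six zone densities (a description of the
  fixed six-zone profile, not an estimate from a sample;
  `sd_type = "sample"` switches).
* **Mann–Whitney p-values** are exact when `min(n, m) ≤ 8` with no ties
  (the realistic n = 6–9 regime), otherwise the tie-corrected normal
  approximation with continuity correction; two samples that are entirely
  one tied value return p = 1. **Cliff's delta** boundary values (0.147,
  0.33, 0.474) fall in the lower magnitude class. **ROC-AUC** counts ties
  as ½ and equals `U/(nm)`; because discriminability is direction-free,
  `auc_flipped = max(auc, 1 − auc)` is always reported alongside the raw
  sparse = 0 / dense = 1 orientation. No multiple-testing correction is
  applied by default (raw per-metric p-values are reported); a
  Benjamini–Hochberg option exists.
* **Per-node normalization** applies to a caller-chosen column list and
  defaults to none: the averaged metrics (degree, clustering, betweenness,
  tortuosity) are already per-node quantities, so blanket normalization
  would double-correct.

## The synthetic generator

`generate_mesh_image()` emulates what tube-formation fields look like to
this pipeline: a proximity mesh (3-nearest-neighbor graph over scattered
points, augmented to a single component) rasterized as dark tubes of fixed
caliber on a bright background. The presets encode the two canonical
morphologies — `"sparse"` (10 points, 25% of edges deleted: few, fragmented
tubules) and `"dense"` (40 points, intact mesh: a rich, fully
interconnected network) — on a 384×384 px field, chosen so that the
default six 50-px zones cover the whole field (the half-diagonal is
≈ 271 px) and skeletons land in the 10³–10⁴-node range typical of real
images while keeping a full batch analysis in seconds per image. The
`fragmentation` parameter deletes a fraction of mesh edges, reproducing the
disconnected early-timepoint phenotype; noise specks are 2–7-px dark
squares (always below the 64-px cleanup limit).

What the generator deliberately does **not** emulate: intensity gradients
and vignetting, out-of-focus blur, cell bodies and debris larger than
64 px, tube-caliber variation, and curved tubules (mesh edges are straight
segments). Passing tests on synthetic data therefore demonstrate the
correctness of the *computation* — segmentation recovery (pixel F1 ≥ 0.9 on
clean images), exact graph construction, metric values, directional
sensitivity to density and fragmentation — not robustness of Otsu
segmentation to difficult real-world illumination, which is a known
limitation of threshold-based pipelines.

## Validation strategy and problem sizes

The test suite validates every metric against independent brute-force
oracles: Floyd–Warshall all-pairs distances for efficiency, exhaustive
triangle enumeration for clustering, and exhaustive shortest-path
enumeration for betweenness, on 100+ random graphs of up to 12 nodes
(integer edge weights keep shortest-path ties exact in floating point for
both routes; {1, √2} pixel weights are covered by the tie-free quantities
and by exact hand-derived fixtures). Graph construction is checked for
set-identity against the pairwise-distance formulation on all fixtures and
50 random skeletons. Toy skeletons (lines, an L-triangle, a diamond ring, a
cross, fragmented sets) pin down exact closed-form values, e.g. the
3-pixel line: efficiency 5/6, average betweenness 1/3, density 2/3.
End-to-end runs use 160–384 px synthetic images with 5–6 replicates per
condition — enough for the nonparametric statistics to reach their extreme
values (AUC = 1, exact p = 0.0022 at n = 6) when groups separate fully.

## Known limitations

* Otsu thresholding can fail on low-contrast or unevenly illuminated
  images; errors propagate to the skeleton. Adaptive or learning-based
  segmentation is out of scope.
* Pixel-level graphs are large (one node per skeleton pixel); exact
  all-pairs quantities are O(|V|·|E|), so very large fields (≫ 10⁵ skeleton
  pixels) will be slow. Tortuosity is already sampled; efficiency and
  betweenness are not.
* Metrics are topological descriptors, not measurements of perfusion or
  barrier function; linking structure to function requires complementary
  experiments.
* 3D stacks, lumen/intensity-weighted graphs, and junction-level
  (as opposed to pixel-level) graph reductions are not implemented.
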