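---
title: "Detecting spatial cellular communities in multiplexed imaging data"
author: "SpatialCommunities package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting spatial cellular communities in multiplexed imaging data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpatialCommunities)
```

## The model

Segmented multiplexed imaging data (e.g. imaging mass cytometry, IMC) give
one record per cell: a centroid in µm (1 pixel = 1 µm for IMC), a cell-type
label from a fixed palette, and marker mean intensities. A **spatial
community** is a cluster of cells grouped by the cell-type composition of
their *local neighborhoods*, not by their own phenotype: two cells belong
to the same community when they sit in the same kind of microenvironment.

The unit of locality is the fixed-radius neighborhood: cells of the same
image whose centroids lie within `radius_px = 15` µm. Fifteen µm is about
one cell diameter, so neighbors are cells "up to one cell away" and
neighborhood size varies with local packing — that variation is intentional
and carries density information. The feature of cell *i* is its
neighborhood profile, the proportion of each palette type among its
neighbors (range 0–1, entries summing to 1). The assumptions are
consequential and worth stating:

* **Centroid approximation.** The original neighbor rule operates on
  segmentation-mask boundaries; without masks we threshold centroid
  distances at the same 15 µm. For roughly convex ~10 µm cells the two
  rules agree closely; for elongated cells the centroid rule undercounts.
  `radius_px` is configurable to compensate.
* **The center cell is excluded from its own profile** (a neighbor relation
  holds between distinct objects). The kNN-window variant used for tissue
  microarrays *includes* the center, per `include_center`/`knnWindows()`.
* **Isolated cells** (no neighbor within the radius) keep an all-zero
  profile, are flagged, and stay in the clustering; they collect in
  low-diversity communities rather than being silently dropped.

## Community detection and agglomeration

`clusterProfiles()` is a PhenoGraph-style procedure: a kNN graph on the
profile vectors (euclidean; `knn_k`), edge weights from the Jaccard overlap
of the endpoints' kNN sets (sets include the point itself, so the weight is
`|shared| / (2(k+1) − |shared|)`), then seeded Louvain modularity
optimization. Community ids are canonicalized by decreasing size.

Modularity optimization over-segments large homogeneous regions (the
resolution limit); this is expected and absorbed by the next stage rather
than fought: `agglomerateCommunities()` merges communities by
average-linkage hierarchical clustering (euclidean) of their **cell-type
compositions** — the distribution of member cells' own types — down to a
target count, recording the merge forest. Near-duplicate tumor-dominated
communities merge first; diverse immune communities survive. The linkage
and metric are package choices (the upstream method's are unspecified);
both composition summaries (member types, mean neighbor profile) are stored
on every `CommunityLabeling` so either can drive merging or matching.

Two clusterings of the same data (e.g. different `knn_k`) are compared with
`matchCommunities()`: Pearson correlation between all pairs of community
compositions, then greedy best-match assignment (ties broken by community
size). This replaces the visual tSNE-overlap argument for parameter
robustness with a quantity a test can check.

**Scale of `knn_k`.** The reference analyses use k = 250 on cohorts of
10^5–10^6 cells. On the ~5,000-cell simulated tissues used throughout this
package's validation we use `knn_k = 50` (and 80 for the stability
contrast): k must sit well below the smallest community of interest, and
the smallest planted communities here hold 100–300 cells. This is a
property of the method's granularity, not a tuning knob; the package warns
when `knn_k` approaches the cell count.

The tissue-microarray variant (`knnWindows()` + `windowKmeans()`) follows
the windowed-k-means school: each cell's window is itself plus its
`window_k − 1 = 9` nearest cells (the cited description "10 nearest
neighboring cells including the center cell" is ambiguous between 10 and 11
total; we implement 10 total, configurable), summarized by raw type counts
and clustered with seeded mini-batch k-means (k-means++ initialization,
per-center learning rates; `stats::kmeans` available as the `"lloyd"`
backend). No installed R package provides mini-batch k-means, so it is
implemented here and cross-checked against `stats::kmeans` in the tests.

## Permutation enrichment and the conditional analysis

`permutationEnrichment()` quantifies cell–cell association around a focal
type. Per image (and by default per community), the statistic for neighbor
type *t* is the mean count of *t* among the graph neighbors of focal cells.
The null permutes cell-type labels over the same positions and graph —
within the community by default (`permute_within = "community"`, matching
the community-separated variant of the analysis), or across the whole image
(`"image"`, the original whole-image null). Reported per
(image, stratum, neighbor type):

* observed and null-mean statistics;
* `log2fc = log2((obs + ε)/(null + ε))` with ε = 1, so zero counts are
  finite and shrunk toward 0;
* one-sided `p_enrich`/`p_deplete` with the add-one correction
  `p = (1 + #{perm ≥ obs}) / (n_perm + 1)` — never exactly 0, floor
  `1/(n_perm+1)`;
* `significant` at `min(p) ≤ alpha` with `alpha = 0.01` and
  `n_perm = 1000` defaults.

The conditional analysis asks whether an association differs when a
conditioning type (regulatory T cells) is present. A focal cell is in the
`"with"` stratum when ≥ 1 conditioning cell lies in its radius neighborhood
(the same neighborhood unit as everything else). Under the null,
conditioning-type cells keep their labels and positions and only the
remaining labels permute — otherwise the strata would dissolve under
relabeling and the conditional question would be unanswerable. Whether the
original analysis permuted all or only non-focal labels is not documented;
both nulls are implemented and the conditioning-preserving one is the
default for stratified runs.

## Distance, correlation, and density statistics

* `minDistance()`: per source cell, the euclidean nearest target in the
  same image, dropped (and flagged) above `max_dist_px = 800`; log2-scaled
  distances are reported alongside raw ones; a Wilcoxon rank-sum test
  compares two source classes (the upstream work reports significance tiers
  without naming the test; rank-sum is the conventional choice for skewed
  distances). A cell in both the source and target sets never matches
  itself.
* Marker high/low splits (`selectCells()`) use strict `> expr_threshold`
  on the stored, unscaled intensity with threshold 0.5; the scale on which
  the original threshold was applied is not documented, so the threshold is
  a parameter, not a constant.
* `crossSectionProfile()`: positions projected on an axis through the
  tumor center (centroid of tumor-type cells; first principal axis of
  those cells when `axis = "auto"` — the projection axis is not defined
  upstream, so it is explicit here), counts per community per signed bin;
  out-of-range cells land in the edge bins; `slab_halfwidth` restricts to
  a band around the axis to emulate a true section.
* `pairwiseCorrelation()`: Pearson r and two-sided p for every cell-type
  pair across units (ROIs or communities), tiers \*, \*\*, \*\*\* at
  0.05/0.01/0.001, zero-variance types masked. Running it at community
  resolution rather than ROI resolution is what exposes co-occurrence
  confined to small niches.
* `communityDensity()`: cells per mm², area from the convex hull of the
  image's cells by default (the upstream "total tissue area" source is
  unstated; fixed areas can be supplied); presence at ≥ 25 cells/mm²,
  boundary inclusive. `coOccurrence()` is the fraction of images where two
  community sets are both present; `covariateCorrelation()` is Spearman
  rank correlation of density against a per-image covariate such as tumor
  mutational burden (the mixed-effects association with patient random
  effects used for multi-region cohorts is out of scope; the rank
  correlation is the in-scope substitute).

## The synthetic tissue generator

`tissueSpec()` defines the study conditions the package is validated under;
`generateTissue()` draws one image and its ground truth. Defaults:

* **Geometry**: 0.8 × 0.8 mm field, circular tumor core (r = 240 µm) with
  a 70 µm interface annulus — the single-tumor ring architecture in which
  interface communities appear as a ring around the tumor bulk.
* **Densities** (cells/µm²): tumor 0.010, interface 0.008, normal 0.006 —
  near-confluent IMC packing, i.e. 6,000–10,000 cells/mm² and 15-µm
  neighborhoods of ~4–8 cells. Much sparser tissue makes single-cell
  profiles mostly noise; much denser is physically implausible for ~10 µm
  cells.
* **Composition**: 14 cell types; each region is anchored by types rare
  elsewhere (tumor core 88% tumor cells; interface a myeloid/stroma band;
  normal 62% epithelium), and diffuse T/DC content outside hubs is low —
  mirroring tumors where most T cells concentrate in a few communities.
  Regions must be *clearly distinct* in composition for planted-community
  recovery to be a well-posed check; cells within ~15 µm of a region
  boundary have genuinely mixed neighborhoods and bound the achievable
  agreement regardless of method.
* **Hubs**: three T/DC aggregates (DC/CD103⁺DC/CD4/CD8/Treg, 70 cells,
  r = 30 µm, Gaussian sd = r/2 truncated at r) on the interface annulus and
  two B-cell follicles in the normal region — five planted communities in
  total (three regions + two hub kinds).
* **Markers**: log-normal per (marker, cell type) with sdlog 0.7 and
  additive meanlog shifts per (marker, type, community, group); hub T cells
  get PD-1/Ki67 shifts and hub DCs a CXCL9 shift, so threshold-based
  high/low splits have signal. Log2 display scaling uses a +1 pseudocount
  (the upstream description says only "log2 scaled"; the pseudocount is a
  package choice and configurable).
* **Conditional structure**: a hub spec may declare a conditioning type
  (Treg) present in a fixed fraction of instances (the count per image is
  fixed at `round(n_instances × prob)` so both strata exist by
  construction); in conditioned instances, nominated types (DCs) are
  displaced ~75 µm from the hub core, suppressing their adjacency to the
  hub's CD8 cells. This plants the "CD8–DC contact is lower where Tregs
  are present" signature that the conditional enrichment must recover.
* `generateCohort()` derives per-image seeds as `seed + image_index` and
  applies arm effects (marker shifts, hub-frequency and density scaling).

What the generator does **not** emulate: segmentation errors and cell-type
misclassification; irregular tumor shapes, necrotic cores, vasculature and
tissue folds; spatial gradients within a region; marker spillover and
batch effects; multi-tumor fields (configurable geometry, but the default
is one core). Passing tests therefore show the pipeline recovers planted
structure under idealized but realistically sized and parameterized
conditions — not that it is robust to upstream segmentation artifacts.

## Numerical choices

* Radius thresholding is inclusive (distance ≤ 15 counts); the kd-tree
  range query runs with a hair of slack and is then filtered exactly, so
  boundary pairs at exactly the radius are kept.
* kNN windows break ties by (distance, cell index) via a blocked exhaustive
  search — exact and deterministic at tissue-microarray sizes. The profile
  kNN search uses BiocNeighbors; its tie resolution draws from R's RNG, so
  it runs under the same seed as Louvain, making clustering reproducible
  end to end.
* Profile rows are integer counts divided by the neighborhood size: row
  sums are 1 up to IEEE rounding (~1e-16), and tests assert at 1e-12.
* Permutation p-values use the add-one correction; permuted statistics are
  compared with a 1e-12 slack so exact ties count as ≥.
* Degenerate inputs: empty images give empty graphs; images without focal
  cells are skipped with a warning; zero-variance types are masked in
  correlations and zeroed (with a warning) in z-scores; zero qualifying
  prevalence flags the relative interaction count undefined; a zero tissue
  area is an error.
* Community ids are canonicalized by decreasing size everywhere, so labels
  are comparable across runs and reruns are byte-identical.

## Problem sizes used in validation

The test suite and the acceptance script run on simulated tissues of
roughly 2,000–10,000 cells (single images or small cohorts), 10,000
permutations for the exactness check against full enumeration (2,970
distinct relabelings of a 12-cell toy image), 499–1,000 permutations
elsewhere, and 40-image cohorts for the type-I-error check — sizes chosen
so the whole suite completes in a few minutes on one core while keeping
every check statistically meaningful.

## Limitations

* Centroid-based neighborhoods ignore cell shape; contact-rich elongated
  cells are undercounted.
* Louvain's resolution limit means the fine community count is not
  interpretable on its own; choose the agglomeration target by the
  diversity of communities you need to distinguish (the reference analyses
  settle on 18 for cross-dataset comparability).
* Permutation nulls condition on positions and the graph; they test label
  exchangeability, not point-process models of cell placement.
* Per-image significance is reported without multiple-testing correction
  across neighbor types, matching the upstream convention; a
  Benjamini–Hochberg pass over the returned p-values is one line of
  `p.adjust` if needed.
* The convex-hull tissue area overestimates density for sparse, ragged
  ROIs; supply measured areas where available.
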