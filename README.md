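# SpatialCommunities

Spatial cellular-community analysis for segmented single-cell tables from
multiplexed tissue imaging (imaging mass cytometry and similar platforms).

Multiplexed imaging yields, after segmentation and cell typing, one row per
cell: a centroid (x, y in µm; for IMC 1 pixel = 1 µm), a cell-type label,
and per-marker mean intensities. The question this package addresses is not
*what* cells are present but *how they organize*: which recurring local
microenvironments ("spatial communities") exist in a tissue, which cell
types they bring into contact — e.g. T cell/dendritic cell aggregates at
the tumor–normal interface — and how those contacts change with treatment
or with the presence of suppressive cells such as regulatory T cells.

## Method

For every cell *i*, neighbors are the cells of the same image within a
fixed radius *r* = 15 µm (about one cell diameter, so neighborhoods reflect
local density). The neighborhood profile of *i* is the vector of neighbor
cell-type proportions over the palette *X*:

    p_i(X) = (# neighbors of i with type X) / (# neighbors of i)   ∈ [0, 1]

The analysis stages, each an exported function:

* **Communities** — `clusterProfiles()` runs a PhenoGraph-style procedure
  on the profile vectors: kNN graph (euclidean), edges reweighted by the
  Jaccard overlap of the endpoints' kNN sets, Louvain modularity
  optimization (seeded). `agglomerateCommunities()` merges the fine
  communities by average-linkage clustering of their cell-type
  compositions down to a target count — low-diversity (tumor-dominated)
  variants merge first. `windowKmeans()` is the tissue-microarray variant:
  10-cell kNN windows clustered by mini-batch k-means;
  `zscoreProfile()` standardizes the resulting community phenotypes.
* **Enrichment** — `permutationEnrichment()` tests, per image and
  community, whether each cell type is enriched or depleted among the
  neighbors of a focal type (mean neighbor count per focal cell) against
  1000 random relabelings of the community's cells; one-sided p-values
  with the add-one correction, significant at p ≤ 0.01.
  `conditionalSplit()` stratifies focal cells by the presence of a
  conditioning type (e.g. Treg) in their neighborhood; conditioning cells
  stay fixed under permutation so the strata survive the null.
* **Spatial statistics** — capped nearest-target distances with a rank-sum
  comparison (`minDistance()`), cross-section community profiles through
  the tumor center (`crossSectionProfile()`), per-community vs per-ROI
  cell-type correlations (`pairwiseCorrelation()`), ROI clustering
  (`clusterROIs()`), and community density / presence / co-occurrence at
  25 cells/mm² (`communityDensity()`, `coOccurrence()`,
  `covariateCorrelation()`).
* **Synthetic tissue** — `tissueSpec()` / `generateTissue()` /
  `generateCohort()` simulate IMC-like tissue (Poisson cell placement in
  tumor core / interface / normal regions, planted hub communities,
  log-normal markers with community- and arm-specific shifts) with
  per-cell ground truth, so every stage is testable without imaging data.
* **Pipeline** — `runPipeline()` chains simulate → neighbors →
  communities → enrich → stats with one seed, CSV artifacts, and a JSON
  manifest of digests; identical config + seed reproduce byte-identical
  outputs.

## Worked example

```r
library(SpatialCommunities)

tt  <- generateTissue(tissueSpec(seed = 7))   # synthetic 0.8 x 0.8 mm ROI
tt$cells
#> CellTable: 5167 cells, 1 image(s), 14 cell types, 7 markers
#>   top types: Tumor (1685), Epithelium (1326), Fibroblast (485), Endothelium (329)

g    <- buildNeighborGraph(tt$cells, 15)
g
#> NeighborGraph: 5167 cells, 17641 edges, radius 15 um, 1 image(s)

prof <- neighborhoodProfiles(tt$cells, g)
lab  <- clusterProfiles(prof, knn_k = 50, seed = 1,
                        cell_types = cellTypes(tt$cells))
agg  <- agglomerateCommunities(lab, 5)$labeling
agg
#> CommunityLabeling: 5167 cells in 5 communities; sizes 2046, 1789, 826, 342, 164

ariScore(communityLabels(agg), tt$truth$community)
#> 0.846      # agreement with the five planted communities

rankByCellType(agg, tt$cells, "CD8_T", top_n = 2)$coverage
#> 0.847      # two communities hold 85% of all CD8+ T cells

hub <- which.max(typeComposition(agg)[, "CD8_T"])
enr <- permutationEnrichment(tt$cells, g, "CD8_T",
                             labeling = agg, community = hub,
                             n_perm = 1000, seed = 1)
head(as.data.frame(enr)[order(enr$p_enrich),
     c("neighbor_type", "observed", "null_mean", "log2fc", "p_enrich")], 5)
#>    neighbor_type observed null_mean log2fc p_enrich
#> 10         CD4_T     5.05     3.142  0.547 0.000999
#> 11         CD8_T     7.23     4.100  0.690 0.000999
#> 12          Treg     2.31     1.481  0.415 0.000999
#> 13            DC     3.17     1.964  0.491 0.000999
#> 14      CD103_DC     1.26     0.745  0.371 0.002997
```

The enrichment table reads: within the CD8-rich interface community, a CD8+
T cell has on average 3.17 DCs among its 15-µm neighbors, versus 1.96
expected under random relabeling — a log2 fold change of 0.49, significant
at p ≤ 0.01. That is the planted T/DC hub structure, recovered end to end.

## Vignette

`vignettes/spatial-communities.Rmd` documents the model, the tunable
parameters and their defaults, what the synthetic tissue does and does not
emulate, and the numerical design choices.
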