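#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
NULL

.RESERVED_COLUMNS <- c("cell_id", "image_id", "x", "y", "cell_type",
                       "domain", "group")

#' CellTable: segmented single-cell data from multiplexed imaging
#'
#' A \linkS4class{SingleCellExperiment} holding one column per segmented
#' cell. Marker mean intensities live in the \code{"intensities"} assay
#' (markers x cells); per-cell spatial and phenotype metadata live in
#' \code{colData}: \code{cell_id}, \code{image_id} (ROI identifier),
#' \code{x}/\code{y} centroid coordinates in micrometres (for IMC,
#' 1 pixel = 1 um), \code{cell_type} (factor whose levels are the cell-type
#' palette), and optional \code{domain} (normal/interface/tumor) and
#' \code{group} (treatment arm) labels.
#'
#' Validity requires finite coordinates, non-negative intensities, cell
#' types drawn from the palette, and uniqueness of (cell_id, image_id).
#'
#' @seealso [CellTable()] for construction from a data.frame,
#'   [readCellTable()] for CSV input.
#' @export
setClass("CellTable", contains = "SingleCellExperiment")

setValidity("CellTable", function(object) {
  cd <- SummarizedExperiment::colData(object)
  required <- c("cell_id", "image_id", "x", "y", "cell_type")
  miss <- setdiff(required, colnames(cd))
  if (length(miss) > 0)
    return(sprintf("missing colData column(s): %s",
                   paste(miss, collapse = ", ")))
  if (!is.numeric(cd$x) || !is.numeric(cd$y))
    return("x and y must be numeric")
  if (any(!is.finite(cd$x)) || any(!is.finite(cd$y)))
    return("x and y must be finite")
  if (!is.factor(cd$cell_type))
    return("cell_type must be a factor (levels = palette)")
  if (anyNA(cd$cell_type))
    return("cell_type contains values outside the palette")
  if (length(levels(cd$cell_type)) < 2)
    return("palette must contain at least 2 cell types")
  if (anyDuplicated(paste(cd$image_id, cd$cell_id, sep = "\r")))
    return("(cell_id, image_id) pairs must be unique")
  if ("intensities" %in% SummarizedExperiment::assayNames(object)) {
    a <- SummarizedExperiment::assay(object, "intensities")
    if (nrow(a) > 0 && any(a < 0, na.rm = TRUE))
      return("marker intensities must be non-negative")
  }
  TRUE
})

#' NeighborGraph: per-image spatial adjacency
#'
#' Undirected adjacency between cells of the same image whose centroid
#' distance is at most \code{radius} micrometres (the fixed-radius
#' approximation of the boundary-expansion neighbor rule). Edges are stored
#' once with \code{from < to}; no self loops; edges never cross images.
#'
#' @slot edges two-column integer matrix of cell indices (from < to).
#' @slot nCells number of cells the graph was built on.
#' @slot radius neighbor radius in micrometres/pixels.
#' @slot imageOf factor giving each cell's image.
#' @seealso [buildNeighborGraph()]
#' @export
setClass("NeighborGraph",
         representation(edges = "matrix", nCells = "integer",
                        radius = "numeric", imageOf = "factor"))

setValidity("NeighborGraph", function(object) {
  e <- object@edges
  if (ncol(e) != 2) return("edges must have two columns")
  if (nrow(e) > 0) {
    if (any(e[, 1] >= e[, 2])) return("edges must satisfy from < to")
    if (any(e < 1) || any(e > object@nCells)) return("edge index out of range")
    if (any(object@imageOf[e[, 1]] != object@imageOf[e[, 2]]))
      return("edges must not cross images")
  }
  if (length(object@imageOf) != object@nCells)
    return("imageOf length must equal nCells")
  if (object@radius <= 0) return("radius must be positive")
  TRUE
})

#' CommunityLabeling: per-cell spatial community assignment
#'
#' Stores one community id per cell (integers 1..K, canonicalized by
#' decreasing community size) together with two composition summaries per
#' community: \code{typeComposition}, the distribution of member cells' own
#' cell types (used for agglomeration and cross-run matching), and
#' \code{profileComposition}, the mean neighborhood profile of member cells.
#'
#' @slot labels integer vector, one community id per cell.
#' @slot typeComposition K x T matrix, rows sum to 1 (may be all-NA when
#'   cell types were not supplied at clustering time).
#' @slot profileComposition K x T matrix of mean neighbor profiles.
#' @slot sizes integer vector of community sizes.
#' @slot params list of parameters used (e.g. knn_k, seed, method).
#' @seealso [clusterProfiles()], [windowKmeans()], [agglomerateCommunities()]
#' @export
setClass("CommunityLabeling",
         representation(labels = "integer", typeComposition = "matrix",
                        profileComposition = "matrix", sizes = "integer",
                        params = "list"))

setValidity("CommunityLabeling", function(object) {
  k <- length(object@sizes)
  if (k == 0) return("at least one community required")
  if (max(object@labels) != k || min(object@labels) < 1)
    return("labels must cover 1..K")
  if (sum(object@sizes) != length(object@labels))
    return("community sizes must sum to the number of cells")
  if (!all(tabulate(object@labels, nbins = k) == object@sizes))
    return("sizes inconsistent with labels")
  if (nrow(object@typeComposition) != k ||
      nrow(object@profileComposition) != k)
    return("composition must have one row per community")
  rs <- rowSums(object@typeComposition)
  if (!all(is.na(rs) | abs(rs - 1) < 1e-6))
    return("typeComposition rows must sum to 1")
  # profileComposition is the mean member feature vector (neighbor profile
  # or window composition); no sum constraint: isolated members pull row
  # sums below 1 and raw feature matrices need not be proportions
  TRUE
})

#' MergeTree: record of community agglomeration
#'
#' The sequence of pairwise merges applied when agglomerating K communities
#' down to a target count; exactly (initial - target) merges, forming a
#' forest over the initial communities. Merged nodes are numbered
#' \code{initial_n + step}.
#'
#' @slot merges data.frame with columns step, a, b, merged.
#' @slot initial_n,target_n community counts before/after.
#' @seealso [agglomerateCommunities()]
#' @export
setClass("MergeTree",
         representation(merges = "data.frame", initial_n = "integer",
                        target_n = "integer"))

setValidity("MergeTree", function(object) {
  if (nrow(object@merges) != object@initial_n - object@target_n)
    return("must record exactly initial_n - target_n merges")
  if (!all(c("step", "a", "b", "merged") %in% colnames(object@merges)))
    return("merges must have columns step, a, b, merged")
  TRUE
})

#' AnalysisConfig: run configuration
#'
#' Holds the tunable constants of the pipeline with the defaults used
#' throughout: 15 px neighbor radius, graph-building k of 250,
#' 1000 permutations at significance level 0.01, an 800 px distance cap,
#' a 0.5 marker high/low threshold, a 25 cells/mm^2 community presence
#' threshold, and 10-cell kNN windows.
#'
#' @slot radius_px neighbor radius (um = px for IMC).
#' @slot knn_k k for PhenoGraph-style graph building.
#' @slot n_perm number of label permutations.
#' @slot alpha significance level for permutation p-values.
#' @slot max_dist_px cap on nearest-target distances.
#' @slot expr_threshold marker high/low cut on stored intensities.
#' @slot density_threshold community presence threshold, cells/mm^2.
#' @slot window_k kNN window size (center cell included).
#' @slot seed master random seed.
#' @seealso [analysisConfig()], [readAnalysisConfig()]
#' @export
setClass("AnalysisConfig",
         representation(radius_px = "numeric", knn_k = "integer",
                        n_perm = "integer", alpha = "numeric",
                        max_dist_px = "numeric", expr_threshold = "numeric",
                        density_threshold = "numeric", window_k = "integer",
                        seed = "integer"))

setValidity("AnalysisConfig", function(object) {
  pos <- c(radius_px = object@radius_px, knn_k = object@knn_k,
           n_perm = object@n_perm, max_dist_px = object@max_dist_px,
           expr_threshold = object@expr_threshold,
           density_threshold = object@density_threshold,
           window_k = object@window_k)
  if (any(pos <= 0))
    return(sprintf("must be > 0: %s",
                   paste(names(pos)[pos <= 0], collapse = ", ")))
  if (object@alpha <= 0 || object@alpha >= 1)
    return("alpha must lie in (0, 1)")
  TRUE
})

#' HubSpec: a planted multi-cell-type aggregate
#'
#' Describes one kind of planted "hub" community: compact aggregates of a
#' fixed cell-type mixture (e.g. a T cell + dendritic cell + Treg hub on
#' the tumor interface). Each generated image receives \code{n_instances}
#' instances. When \code{conditioning_type} is set, a fixed fraction
#' (\code{conditioning_prob}) of instances contain that type; in those
#' instances, cells of \code{segregate_types} are displaced radially by
#' \code{segregate_offset} um, suppressing their adjacency to the rest of
#' the hub. Unconditioned instances drop the conditioning type and
#' renormalize the composition.
#'
#' @slot name planted community id.
#' @slot n_instances instances per image.
#' @slot radius hub radius, um.
#' @slot n_cells cells per instance.
#' @slot composition named probability vector over cell types (sums to 1).
#' @slot placement "interface" (centers on the interface annulus) or
#'   "normal" (uniform in the normal region).
#' @slot conditioning_type optional cell type conditioning the hub
#'   micro-structure (e.g. "Treg"); character(0) for none.
#' @slot conditioning_prob fraction of instances containing the type.
#' @slot segregate_types types displaced in conditioned instances.
#' @slot segregate_offset displacement distance, um.
#' @seealso [hubSpec()], [generateTissue()]
#' @export
setClass("HubSpec",
         representation(name = "character", n_instances = "integer",
                        radius = "numeric", n_cells = "integer",
                        composition = "numeric", placement = "character",
                        conditioning_type = "character",
                        conditioning_prob = "numeric",
                        segregate_types = "character",
                        segregate_offset = "numeric"))

setValidity("HubSpec", function(object) {
  if (abs(sum(object@composition) - 1) > 1e-9)
    return("hub composition must sum to 1")
  if (is.null(names(object@composition)))
    return("hub composition must be named by cell type")
  if (object@n_cells < 1) return("n_cells must be >= 1")
  if (object@radius <= 0) return("radius must be positive")
  if (!object@placement %in% c("interface", "normal"))
    return("placement must be 'interface' or 'normal'")
  if (object@conditioning_prob < 0 || object@conditioning_prob > 1)
    return("conditioning_prob must lie in [0, 1]")
  TRUE
})

#' TissueSpec: parameters of the synthetic tissue generator
#'
#' Defines a rectangular 2D field with a circular tumor core, an annular
#' tumor-normal interface, and surrounding normal tissue; cells are placed
#' by homogeneous Poisson processes with region-specific densities and
#' cell-type mixtures, planted hubs are added per [hubSpec()], and marker
#' intensities are drawn log-normally per (marker, cell type) with
#' community/group-dependent shifts.
#'
#' @slot field_width,field_height field dimensions, um.
#' @slot tumor_center (x, y) of the tumor core.
#' @slot tumor_radius,interface_width geometry of core and annulus, um.
#' @slot densities named vector (normal, interface, tumor), cells per um^2.
#' @slot composition 3 x T matrix of cell-type probabilities per region
#'   (rows normal/interface/tumor, each summing to 1).
#' @slot hubs list of \linkS4class{HubSpec}.
#' @slot marker_means markers x cell types matrix of baseline log-normal
#'   meanlog parameters.
#' @slot marker_sdlog common log-normal sdlog.
#' @slot marker_shifts data.frame (marker, cell_type, community, group,
#'   dmu); NA fields are wildcards; matching rows add dmu to meanlog.
#' @slot group treatment/arm label stamped on generated cells.
#' @slot seed integer random seed.
#' @seealso [tissueSpec()], [generateTissue()], [generateCohort()]
#' @export
setClass("TissueSpec",
         representation(field_width = "numeric", field_height = "numeric",
                        tumor_center = "numeric", tumor_radius = "numeric",
                        interface_width = "numeric", densities = "numeric",
                        composition = "matrix", hubs = "list",
                        marker_means = "matrix", marker_sdlog = "numeric",
                        marker_shifts = "data.frame", group = "character",
                        seed = "integer"))

setValidity("TissueSpec", function(object) {
  if (any(object@densities <= 0)) return("densities must be positive")
  if (!identical(sort(names(object@densities)),
                 sort(c("normal", "interface", "tumor"))))
    return("densities must be named normal, interface, tumor")
  if (!identical(sort(rownames(object@composition)),
                 sort(c("normal", "interface", "tumor"))))
    return("composition rows must be normal, interface, tumor")
  rs <- rowSums(object@composition)
  if (any(abs(rs - 1) > 1e-9))
    return("composition rows must sum to 1")
  outer_r <- object@tumor_radius + object@interface_width
  cx <- object@tumor_center[1]; cy <- object@tumor_center[2]
  if (cx - outer_r < 0 || cy - outer_r < 0 ||
      cx + outer_r > object@field_width || cy + outer_r > object@field_height)
    return("tumor core plus interface must fit inside the field")
  for (h in object@hubs) {
    if (!is(h, "HubSpec")) return("hubs must be HubSpec objects")
    bad <- setdiff(names(h@composition), colnames(object@composition))
    if (length(bad) > 0)
      return(sprintf("hub '%s' uses unknown cell type(s): %s", h@name,
                     paste(bad, collapse = ", ")))
  }
  TRUE
})
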