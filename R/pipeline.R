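.needFile <- function(path, stage) {
  if (!file.exists(path))
    stop(sprintf("stage '%s' requires missing file: %s", stage, path),
         call. = FALSE)
  path
}

#' Run the full spatial-community pipeline on synthetic or supplied data
#'
#' Chains the pipeline stages — simulate (synthetic cohort), neighbors
#' (radius graph + neighborhood profiles), communities (profile clustering,
#' optional agglomeration), enrich (permutation enrichment around a focal
#' type in its top community), stats (community densities, per-ROI
#' composition correlations) — reading and writing CSV artifacts under
#' \code{out_dir}, and records a JSON manifest with the configuration,
#' seeds, per-stage timings and an md5 digest of every output file.
#' Identical configuration and seed reproduce byte-identical stage outputs.
#'
#' @param out_dir output directory (created if needed).
#' @param config an \linkS4class{AnalysisConfig}; its seed drives every
#'   stage.
#' @param spec optional \linkS4class{TissueSpec} for the simulate stage
#'   (default [tissueSpec()] with the config seed).
#' @param n_images images to simulate; default 2.
#' @param knn_k graph-building k for the communities stage; defaults to
#'   \code{config@knn_k} (capped below the cell count with a warning).
#' @param target_n optional agglomeration target.
#' @param focal_type focal cell type for the enrich stage; default
#'   "CD8_T".
#' @param conditioning_type optional conditioning type for stratified
#'   enrichment.
#' @param stages subset of
#'   \code{c("simulate","neighbors","communities","enrich","stats")}, in
#'   order; later stages read the files earlier ones wrote (an informative
#'   error names any missing input).
#' @param quiet suppress progress messages.
#' @return the manifest, invisibly (also written to
#'   \code{run_manifest.json}).
#' @export
runPipeline <- function(out_dir, config = analysisConfig(), spec = NULL,
                        n_images = 2, knn_k = NULL, target_n = NULL,
                        focal_type = "CD8_T", conditioning_type = NULL,
                        stages = c("simulate", "neighbors", "communities",
                                   "enrich", "stats"),
                        quiet = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(out_dir, f)
  say <- function(...) if (!quiet) message("[", format(Sys.time(), "%T"),
                                           "] ", ...)
  manifest <- list(version = as.character(utils::packageVersion(
                     "SpatialCommunities")),
                   config = as.list(config), stages = list())
  t_stage <- function(stage, code) {
    el <- system.time(code)[["elapsed"]]
    manifest$stages[[stage]] <<- list(elapsed_s = round(el, 3))
    say("stage ", stage, " done (", round(el, 2), " s)")
  }
  if ("simulate" %in% stages) t_stage("simulate", {
    if (is.null(spec)) spec <- tissueSpec(seed = config@seed)
    cohort <- generateCohort(spec, n_images)
    cells <- combineCellTables(lapply(cohort, `[[`, "cells"))
    writeCellTable(cells, pth("cells.csv"))
    truth <- do.call(rbind, lapply(cohort, function(x) {
      cbind(x$truth, image_id = imageIds(x$cells)[1])
    }))
    utils::write.csv(truth, pth("truth.csv"), row.names = FALSE)
  })
  if ("neighbors" %in% stages) t_stage("neighbors", {
    cells <- readCellTable(.needFile(pth("cells.csv"), "neighbors"))
    graph <- buildNeighborGraph(cells, config@radius_px)
    e <- edgeMatrix(graph)
    utils::write.csv(data.frame(from = e[, 1], to = e[, 2]),
                     pth("edges.csv"), row.names = FALSE)
    prof <- neighborhoodProfiles(cells, graph)
    out <- data.frame(cell_id = cellIds(cells),
                      image_id = imageIds(cells),
                      isolated = attr(prof, "isolated"))
    utils::write.csv(cbind(out, as.data.frame(prof)),
                     pth("profiles.csv"), row.names = FALSE)
  })
  if ("communities" %in% stages) t_stage("communities", {
    cells <- readCellTable(.needFile(pth("cells.csv"), "communities"))
    pr <- utils::read.csv(.needFile(pth("profiles.csv"), "communities"))
    prof <- as.matrix(pr[, !(colnames(pr) %in%
                               c("cell_id", "image_id", "isolated")),
                         drop = FALSE])
    k <- if (is.null(knn_k)) config@knn_k else knn_k
    if (k >= nrow(prof)) {
      warning("knn_k >= cell count; capped")
      k <- nrow(prof) - 1
    }
    lab <- clusterProfiles(prof, knn_k = k, seed = config@seed,
                           cell_types = cellTypes(cells))
    if (!is.null(target_n) && target_n < nCommunities(lab)) {
      agg <- agglomerateCommunities(lab, target_n)
      lab <- agg$labeling
      jsonlite::write_json(mergeSteps(agg$tree), pth("merge_tree.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    utils::write.csv(data.frame(cell_id = cellIds(cells),
                                image_id = imageIds(cells),
                                community = communityLabels(lab)),
                     pth("labels.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(community = seq_len(nCommunities(lab)),
                 size = communitySizes(lab), typeComposition(lab)),
      pth("composition.csv"), row.names = FALSE)
  })
  if ("enrich" %in% stages) t_stage("enrich", {
    cells <- readCellTable(.needFile(pth("cells.csv"), "enrich"))
    lab <- .readLabeling(.needFile(pth("labels.csv"), "enrich"), cells)
    graph <- buildNeighborGraph(cells, config@radius_px)
    top <- rankByCellType(lab, cells, focal_type, top_n = 1)$top
    enr <- permutationEnrichment(cells, graph, focal_type,
                                 labeling = lab, community = top,
                                 n_perm = config@n_perm,
                                 seed = config@seed, alpha = config@alpha,
                                 conditioning_type = conditioning_type)
    utils::write.csv(as.data.frame(enr), pth("enrichment.csv"),
                     row.names = FALSE)
  })
  if ("stats" %in% stages) t_stage("stats", {
    cells <- readCellTable(.needFile(pth("cells.csv"), "stats"))
    lab <- .readLabeling(.needFile(pth("labels.csv"), "stats"), cells)
    dens <- communityDensity(cells, lab,
                             density_threshold = config@density_threshold)
    utils::write.csv(as.data.frame(dens), pth("density.csv"),
                     row.names = FALSE)
    comp <- .roiComposition(cells)
    if (nrow(comp) >= 3) {
      pc <- pairwiseCorrelation(comp)
      utils::write.csv(data.frame(cell_type = rownames(pc$r), pc$r),
                       pth("roi_correlation.csv"), row.names = FALSE)
    }
  })
  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   pth("run_manifest.json"))
  manifest$seed <- config@seed
  manifest$files <- lapply(stats::setNames(files, basename(files)),
                           function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest, pth("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

.readLabeling <- function(path, cells) {
  lab <- utils::read.csv(path)
  .makeLabeling(lab$community, NULL, cellTypes(cells),
                cellTypePalette(cells), params = list(source = path))
}

# per-ROI cell-type composition (rows = images, columns = palette)
.roiComposition <- function(cells) {
  tab <- table(imageIds(cells), cellTypes(cells))
  sweep(unclass(tab), 1, pmax(rowSums(tab), 1), "/")
}
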