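#' Select cells by type and marker expression
#'
#' Convenience predicate used by the distance statistics: cells of given
#' type(s), optionally further split into marker-high (\code{intensity >
#' threshold}, strict) or marker-low cells on the stored (unscaled)
#' intensity.
#'
#' @param cells a \linkS4class{CellTable}.
#' @param types character vector of cell types (NULL = any).
#' @param marker optional marker name.
#' @param threshold positivity cut; default 0.5.
#' @param side \code{"high"} (> threshold) or \code{"low"} (<= threshold).
#' @return logical vector over cells.
#' @export
selectCells <- function(cells, types = NULL, marker = NULL, threshold = 0.5,
                        side = c("high", "low")) {
  side <- match.arg(side)
  sel <- rep(TRUE, ncol(cells))
  if (!is.null(types))
    sel <- sel & as.character(cellTypes(cells)) %in% types
  if (!is.null(marker)) {
    if (!marker %in% markerNames(cells))
      stop("marker not in table: ", marker, call. = FALSE)
    v <- intensities(cells)[marker, ]
    sel <- sel & (if (side == "high") v > threshold else v <= threshold)
  }
  sel
}

#' Nearest-target distances with a cap, and a rank-sum class comparison
#'
#' For every source cell, the euclidean distance to its nearest target cell
#' in the same image; distances above \code{max_dist_px} are dropped
#' (flagged, not recorded as distances). When \code{source_class} assigns
#' sources to two classes (e.g. marker-high vs marker-low), a Wilcoxon
#' rank-sum test compares their distance distributions. Distances are also
#' reported log2-scaled, the scale used for display.
#'
#' @param cells a \linkS4class{CellTable}.
#' @param source,target logical selectors over cells (see [selectCells()]).
#'   A cell that is both source and target is never its own nearest target.
#' @param source_class optional character/factor over cells giving the
#'   class of each source (two classes tested).
#' @param max_dist_px distance cap; default 800.
#' @param alternative passed to [stats::wilcox.test()]; default
#'   "two.sided".
#' @return list with \code{records} (\link[S4Vectors]{DataFrame}: cell_id,
#'   image_id, class, distance, log2_distance, target_found) and
#'   \code{test} (htest or NULL). Sources in images without any target are
#'   flagged and excluded from the test.
#' @export
minDistance <- function(cells, source, target, source_class = NULL,
                        max_dist_px = 800,
                        alternative = "two.sided") {
  if (!any(source) || !any(target))
    stop("source and target must each select at least one cell",
         call. = FALSE)
  xy <- spatialCoords(cells)
  img <- imageIds(cells)
  src_idx <- which(source)
  dist_out <- rep(NA_real_, length(src_idx))
  for (im in unique(img[src_idx])) {
    s <- which(img[src_idx] == im)
    tgt <- which(target & img == im)
    if (length(tgt) == 0) next
    q <- xy[src_idx[s], , drop = FALSE]
    tx <- xy[tgt, , drop = FALSE]
    k <- min(2L, length(tgt))
    res <- .quietTies(BiocNeighbors::queryKNN(tx, q, k = k))
    d1 <- res$distance[, 1]
    # a source that is itself a target sits at distance 0 of itself
    self_hit <- tgt[res$index[, 1]] == src_idx[s]
    if (k == 2) d1[self_hit] <- res$distance[self_hit, 2]
    else d1[self_hit] <- NA_real_
    dist_out[s] <- d1
  }
  found <- !is.na(dist_out) & dist_out <= max_dist_px
  cls <- if (is.null(source_class)) NA_character_ else
    as.character(source_class)[src_idx]
  records <- S4Vectors::DataFrame(
    cell_id = cellIds(cells)[src_idx], image_id = img[src_idx],
    class = cls,
    distance = ifelse(found, dist_out, NA_real_),
    log2_distance = ifelse(found & dist_out > 0, log2(dist_out), NA_real_),
    target_found = found)
  test <- NULL
  if (!is.null(source_class)) {
    ok <- records$target_found & !is.na(records$class)
    lv <- unique(records$class[ok])
    if (length(lv) == 2) {
      test <- stats::wilcox.test(
        records$distance[ok & records$class == lv[1]],
        records$distance[ok & records$class == lv[2]],
        alternative = alternative, exact = FALSE)
      test$data.name <- paste(lv, collapse = " vs ")
    }
  }
  list(records = records, test = test)
}

#' Community counts along a cross-section through the tumor
#'
#' Projects cell positions onto an axis through the tumor center (centroid
#' of tumor-type cells; the first principal axis of their coordinates when
#' \code{axis = "auto"}) and histograms each community's cell count per
#' signed-position bin, with 0 at the tumor center. Cells beyond the bin
#' range are counted in the edge bins, so bin counts sum to community
#' sizes.
#'
#' @param cells a \linkS4class{CellTable}.
#' @param labeling a \linkS4class{CommunityLabeling}.
#' @param axis \code{"auto"}, \code{"x"} or \code{"y"}.
#' @param n_bins number of position bins; default 40.
#' @param tumor_type label of tumor cells; default "Tumor". When absent the
#'   center falls back to the all-cell centroid with a warning.
#' @param range half-width of the binned interval; defaults to the largest
#'   absolute projected position.
#' @param slab_halfwidth half-thickness of the cross-section slab: only
#'   cells within this perpendicular distance of the section axis are
#'   counted (default Inf = project every cell).
#' @return list with \code{counts} (communities x bins matrix),
#'   \code{centers} (bin centers), \code{breaks}, \code{axis} (unit
#'   vector).
#' @export
crossSectionProfile <- function(cells, labeling, axis = c("auto", "x", "y"),
                                n_bins = 40, tumor_type = "Tumor",
                                range = NULL, slab_halfwidth = Inf) {
  axis <- match.arg(axis)
  xy <- spatialCoords(cells)
  is_tumor <- as.character(cellTypes(cells)) == tumor_type
  if (!any(is_tumor)) {
    warning("no '", tumor_type, "' cells; centering on all cells")
    is_tumor <- rep(TRUE, nrow(xy))
  }
  center <- colMeans(xy[is_tumor, , drop = FALSE])
  v <- switch(axis,
              x = c(1, 0), y = c(0, 1),
              auto = {
                pc <- stats::prcomp(xy[is_tumor, , drop = FALSE])
                pc$rotation[, 1]
              })
  v <- v / sqrt(sum(v^2))
  centered <- sweep(xy, 2, center)
  pos <- as.vector(centered %*% v)
  perp <- as.vector(centered %*% c(-v[2], v[1]))
  in_slab <- abs(perp) <= slab_halfwidth
  if (is.null(range)) range <- max(abs(pos[in_slab]))
  if (range <= 0) range <- 1
  breaks <- seq(-range, range, length.out = n_bins + 1)
  bin <- findInterval(pos, breaks, rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1L), n_bins)  # clamp out-of-range into edge bins
  k <- nCommunities(labeling)
  counts <- unclass(table(factor(communityLabels(labeling)[in_slab],
                                 levels = seq_len(k)),
                          factor(bin[in_slab], levels = seq_len(n_bins))))
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  dimnames(counts) <- list(community = seq_len(k),
                           position = signif(centers, 4))
  list(counts = counts, centers = centers, breaks = breaks, axis = v)
}

#' Pairwise Pearson correlation of cell-type abundances across units
#'
#' Correlates every pair of cell types across analysis units (communities
#' or ROIs) from a units x types composition matrix, with two-sided
#' p-values tiered at 0.05 / 0.01 / 0.001 and rows/columns ordered by
#' hierarchical clustering of the correlation pattern. Per-community
#' correlation localizes co-occurrence that whole-ROI correlation averages
#' away.
#'
#' @param composition units x cell types numeric matrix (>= 3 units).
#' @return list with \code{r}, \code{p} (types x types matrices; pairs
#'   involving a zero-variance type are NA with a warning), \code{tiers}
#'   (character matrix "", *, **, ***), \code{order} (clustering order of
#'   types).
#' @export
pairwiseCorrelation <- function(composition) {
  if (nrow(composition) < 3)
    stop("need at least 3 units", call. = FALSE)
  types <- colnames(composition)
  nt <- length(types)
  sds <- apply(composition, 2, stats::sd)
  if (any(sds == 0))
    warning("zero-variance cell type(s) masked: ",
            paste(types[sds == 0], collapse = ", "))
  r <- matrix(NA_real_, nt, nt, dimnames = list(types, types))
  p <- r
  for (i in seq_len(nt)) for (j in i:nt) {
    if (sds[i] == 0 || sds[j] == 0) next
    ct <- stats::cor.test(composition[, i], composition[, j],
                          method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  tiers <- matrix("", nt, nt, dimnames = dimnames(p))
  tiers[!is.na(p) & p < 0.05] <- "*"
  tiers[!is.na(p) & p < 0.01] <- "**"
  tiers[!is.na(p) & p < 0.001] <- "***"
  r0 <- r; r0[is.na(r0)] <- 0; diag(r0) <- 1
  ord <- stats::hclust(stats::dist(r0), method = "average")$order
  list(r = r, p = p, tiers = tiers, order = ord)
}

#' Hierarchically cluster ROIs by community composition
#'
#' Average-linkage hierarchical clustering (euclidean) of a ROIs x
#' communities proportion matrix, on both axes; the ROI dendrogram is what
#' separates, e.g., treated from untreated tissues.
#'
#' @param mat ROIs x communities numeric matrix (>= 2 ROIs).
#' @return list with \code{row_hclust}, \code{col_hclust} (hclust objects;
#'   col_hclust NULL when fewer than 2 columns) and \code{row_order},
#'   \code{col_order} (leaf orders).
#' @export
clusterROIs <- function(mat) {
  if (nrow(mat) < 2) stop("need at least 2 ROIs", call. = FALSE)
  rh <- stats::hclust(stats::dist(mat), method = "average")
  ch <- if (ncol(mat) >= 2)
    stats::hclust(stats::dist(t(mat)), method = "average") else NULL
  list(row_hclust = rh, col_hclust = ch,
       row_order = rh$order,
       col_order = if (is.null(ch)) seq_len(ncol(mat)) else ch$order)
}

#' Per-image community densities and presence calls
#'
#' Density of each community in each image: member count divided by tissue
#' area in mm^2. By default the area is the convex hull of all cells of the
#' image (um^2 / 1e6); fixed areas can be supplied. A community is present
#' in an image when its density is at least \code{density_threshold}
#' (inclusive boundary).
#'
#' @param cells a \linkS4class{CellTable}.
#' @param labeling a \linkS4class{CommunityLabeling}.
#' @param areas optional named numeric vector of per-image areas in mm^2;
#'   zero or negative areas are an error.
#' @param density_threshold presence threshold in cells/mm^2; default 25.
#' @return \link[S4Vectors]{DataFrame}: image_id, community, count,
#'   area_mm2, density, present.
#' @export
communityDensity <- function(cells, labeling, areas = NULL,
                             density_threshold = 25) {
  img <- imageIds(cells)
  imgs <- unique(img)
  xy <- spatialCoords(cells)
  if (is.null(areas)) {
    areas <- vapply(imgs, function(im) {
      pts <- xy[img == im, , drop = FALSE]
      if (nrow(pts) < 3) return(0)
      h <- grDevices::chull(pts)
      hx <- pts[h, 1]; hy <- pts[h, 2]
      abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2 / 1e6
    }, 0)
    names(areas) <- imgs
  }
  if (any(areas <= 0)) stop("tissue areas must be positive", call. = FALSE)
  k <- nCommunities(labeling)
  lab <- communityLabels(labeling)
  rows <- lapply(imgs, function(im) {
    cnt <- tabulate(lab[img == im], nbins = k)
    data.frame(image_id = im, community = seq_len(k), count = cnt,
               area_mm2 = unname(areas[im]),
               density = cnt / unname(areas[im]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$present <- out$density >= density_threshold
  S4Vectors::DataFrame(out)
}

#' Co-occurrence of two community sets across images
#'
#' Fraction of images in which at least one community of set A and at least
#' one community of set B are both present (per the density-threshold
#' presence calls of [communityDensity()]).
#'
#' @param records output of [communityDensity()].
#' @param communities_a,communities_b community id vectors.
#' @return list with \code{fraction}, \code{n_images}, \code{n_both}.
#' @export
coOccurrence <- function(records, communities_a, communities_b) {
  rec <- as.data.frame(records)
  per_img <- split(rec, rec$image_id)
  both <- vapply(per_img, function(d) {
    any(d$present[d$community %in% communities_a]) &&
      any(d$present[d$community %in% communities_b])
  }, TRUE)
  list(fraction = mean(both), n_images = length(both),
       n_both = sum(both))
}

#' Spearman correlation of community density with a per-image covariate
#'
#' Rank correlation between, e.g., the density of a community and tumor
#' mutational burden across images/samples.
#'
#' @param density numeric vector of per-image community densities.
#' @param covariate numeric vector of the same length (>= 4 pairs).
#' @param method correlation method; default "spearman".
#' @return list with \code{rho}, \code{p}, \code{n}, \code{method};
#'   \code{rho} is NA (flagged by a warning) for constant input.
#' @export
covariateCorrelation <- function(density, covariate, method = "spearman") {
  ok <- is.finite(density) & is.finite(covariate)
  if (sum(ok) < 4)
    stop("need at least 4 paired observations", call. = FALSE)
  if (stats::sd(density[ok]) == 0 || stats::sd(covariate[ok]) == 0) {
    warning("constant input; correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = sum(ok),
                method = method))
  }
  ct <- suppressWarnings(stats::cor.test(density[ok], covariate[ok],
                                         method = method))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok),
       method = method)
}
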