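#' Build the per-image fixed-radius neighbor graph
#'
#' Two cells of the same image are neighbors when the euclidean distance
#' between their centroids is at most \code{radius_px} (inclusive). This is
#' the centroid approximation of the segmentation-mask boundary-expansion
#' rule; the default radius of 15 um is about one cell diameter, so
#' neighbors are cells "up to one cell away" and neighborhood sizes reflect
#' local density.
#'
#' @param cells a \linkS4class{CellTable}.
#' @param radius_px neighbor radius in um (> 0); default 15.
#' @return A \linkS4class{NeighborGraph}.
#' @examples
#' ct <- CellTable(data.frame(cell_id = c("a", "b", "c"), image_id = "i",
#'                            x = c(0, 10, 40), y = 0,
#'                            cell_type = c("T", "T", "Tumor")))
#' g <- buildNeighborGraph(ct, 15)
#' neighborCounts(g)  # 1 1 0
#' @export
buildNeighborGraph <- function(cells, radius_px = 15) {
  if (radius_px <= 0) stop("radius_px must be > 0", call. = FALSE)
  xy <- spatialCoords(cells)
  img <- factor(imageIds(cells))
  from <- integer(0); to <- integer(0)
  for (lev in levels(img)) {
    idx <- which(img == lev)
    if (length(idx) < 2) next
    # kd-tree range query with a slightly inflated threshold, then exact
    # inclusive filtering so boundary pairs at exactly radius_px count
    hits <- .quietTies(BiocNeighbors::findNeighbors(
      xy[idx, , drop = FALSE],
      threshold = radius_px * (1 + 1e-9) + 1e-9))
    f <- rep.int(seq_along(idx), lengths(hits$index))
    t_ <- unlist(hits$index, use.names = FALSE)
    d <- unlist(hits$distance, use.names = FALSE)
    keep <- f < t_ & d <= radius_px
    from <- c(from, idx[f[keep]])
    to <- c(to, idx[t_[keep]])
  }
  e <- cbind(from, to)
  if (nrow(e) > 1) e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  methods::new("NeighborGraph", edges = e, nCells = ncol(cells),
               radius = as.numeric(radius_px), imageOf = img)
}

#' Accessors for NeighborGraph
#'
#' @param x a \linkS4class{NeighborGraph}.
#' @return \code{edgeMatrix}: two-column integer matrix (from < to);
#'   \code{adjacencyList}: list of integer neighbor-index vectors, one per
#'   cell; \code{neighborCounts}: integer vector of neighborhood sizes.
#' @name NeighborGraph-accessors
NULL

#' @rdname NeighborGraph-accessors
#' @export
setMethod("edgeMatrix", "NeighborGraph", function(x) x@edges)

#' @rdname NeighborGraph-accessors
#' @export
setMethod("adjacencyList", "NeighborGraph", function(x) {
  adj <- vector("list", x@nCells)
  e <- x@edges
  both_from <- c(e[, 1], e[, 2])
  both_to <- c(e[, 2], e[, 1])
  o <- order(both_from)
  split_idx <- split(both_to[o], factor(both_from[o], levels = seq_len(x@nCells)))
  for (i in seq_len(x@nCells)) adj[[i]] <- sort(split_idx[[i]])
  adj
})

#' @rdname NeighborGraph-accessors
#' @export
setMethod("neighborCounts", "NeighborGraph", function(x)
  tabulate(c(x@edges[, 1], x@edges[, 2]), nbins = x@nCells))

setMethod("show", "NeighborGraph", function(object) {
  cat("NeighborGraph:", object@nCells, "cells,", nrow(object@edges),
      "edges, radius", object@radius, "um,",
      nlevels(object@imageOf), "image(s)\n")
})

#' Per-cell neighborhood composition profiles
#'
#' For every cell, the proportion of each cell type among its graph
#' neighbors: count of type X in the neighborhood divided by total
#' neighborhood size (range 0 to 1). The center cell is excluded from its
#' own denominator by default. Isolated cells receive an all-zero profile
#' and are flagged in the \code{"isolated"} attribute.
#'
#' @param cells a \linkS4class{CellTable}.
#' @param graph a \linkS4class{NeighborGraph} built on the same cells.
#' @param palette cell-type universe; defaults to the table's palette. An
#'   error names any cell type present but missing from the palette.
#' @param include_center also count the cell itself in its neighborhood
#'   (the kNN-window convention); default FALSE.
#' @return numeric matrix (cells x types) with attributes \code{"size"}
#'   (neighborhood sizes) and \code{"isolated"} (logical).
#' @export
neighborhoodProfiles <- function(cells, graph, palette = cellTypePalette(cells),
                                 include_center = FALSE) {
  if (graph@nCells != ncol(cells))
    stop("graph was not built on these cells", call. = FALSE)
  types <- cellTypes(cells)
  missing_types <- setdiff(levels(droplevels(types)), palette)
  if (length(missing_types) > 0)
    stop("palette is missing cell type(s): ",
         paste(missing_types, collapse = ", "), call. = FALSE)
  n <- ncol(cells)
  tcode <- match(as.character(types), palette)
  e <- edgeMatrix(graph)
  from <- c(e[, 1], e[, 2]); to <- c(e[, 2], e[, 1])
  if (include_center) {
    from <- c(from, seq_len(n)); to <- c(to, seq_len(n))
  }
  counts <- matrix(0, n, length(palette), dimnames = list(NULL, palette))
  if (length(from) > 0) {
    m <- Matrix::sparseMatrix(i = from, j = tcode[to], x = 1,
                              dims = c(n, length(palette)))
    counts <- as.matrix(m)
    colnames(counts) <- palette
  }
  size <- rowSums(counts)
  prof <- counts / pmax(size, 1)
  attr(prof, "size") <- as.integer(size)
  attr(prof, "isolated") <- size == 0
  prof
}

#' k-nearest-neighbor windows around every cell
#'
#' The window of a cell is the cell itself plus its \code{window_k - 1}
#' nearest cells in the same image (euclidean distance, ties broken by
#' (distance, cell index)); in images smaller than \code{window_k} the
#' window is the whole image. Window compositions (cell-type counts, which
#' sum to the window size) are the features of the k-means community
#' variant.
#'
#' @param cells a \linkS4class{CellTable}.
#' @param window_k window size including the center cell (>= 1); default 10.
#' @return list with \code{counts} (cells x types integer matrix),
#'   \code{size} (window sizes), \code{indices} (list of member indices per
#'   window), \code{center_type} (factor), \code{image_id} (character).
#' @seealso [windowKmeans()]
#' @export
knnWindows <- function(cells, window_k = 10) {
  if (window_k < 1) stop("window_k must be >= 1", call. = FALSE)
  xy <- spatialCoords(cells)
  img <- factor(imageIds(cells))
  types <- cellTypes(cells)
  palette <- levels(types)
  n <- ncol(cells)
  tcode <- as.integer(types)
  counts <- matrix(0L, n, length(palette), dimnames = list(NULL, palette))
  indices <- vector("list", n)
  for (lev in levels(img)) {
    idx <- which(img == lev)
    k <- min(window_k, length(idx))
    sub <- xy[idx, , drop = FALSE]
    # blocked brute force keeps the (distance, index) tie-break exact
    block <- 512L
    for (s in seq(1, length(idx), by = block)) {
      rows <- s:min(s + block - 1L, length(idx))
      d2 <- outer(rowSums(sub[rows, , drop = FALSE]^2),
                  rowSums(sub^2), "+") -
        2 * sub[rows, , drop = FALSE] %*% t(sub)
      for (ri in seq_along(rows)) {
        d2[ri, rows[ri]] <- -1  # the center cell is always in its window
        o <- order(d2[ri, ], seq_along(idx))[seq_len(k)]
        members <- idx[o]
        indices[[idx[rows[ri]]]] <- members
        counts[idx[rows[ri]], ] <-
          tabulate(tcode[members], nbins = length(palette))
      }
    }
  }
  list(counts = counts, size = as.integer(rowSums(counts)),
       indices = indices, center_type = types,
       image_id = as.character(img))
}
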