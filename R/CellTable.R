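#' Construct a CellTable from a per-cell data.frame
#'
#' Builds a validated \linkS4class{CellTable} from a table with one row per
#' segmented cell. Required columns: \code{cell_id}, \code{image_id},
#' \code{x}, \code{y}, \code{cell_type}; optional \code{domain} and
#' \code{group}. Every other numeric column is treated as a marker mean
#' intensity unless \code{markers} names them explicitly.
#'
#' @param df data.frame of per-cell records.
#' @param palette ordered character vector of allowed cell-type labels;
#'   defaults to the sorted unique labels present. Labels in \code{df} that
#'   are absent from the palette raise an error naming them.
#' @param markers optional character vector of marker column names.
#' @return A \linkS4class{CellTable}.
#' @examples
#' df <- data.frame(cell_id = c("c1", "c2", "c3"), image_id = "img1",
#'                  x = c(0, 10, 40), y = 0,
#'                  cell_type = c("CD8_T", "DC", "Tumor"),
#'                  PD1 = c(1.2, 0.1, 0), Ki67 = c(0, 0.4, 2.2))
#' ct <- CellTable(df)
#' cellTypePalette(ct)
#' @export
CellTable <- function(df, palette = NULL, markers = NULL) {
  required <- c("cell_id", "image_id", "x", "y", "cell_type")
  miss <- setdiff(required, colnames(df))
  if (length(miss) > 0)
    stop("schema error: missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(palette)) palette <- sort(unique(as.character(df$cell_type)))
  unknown <- setdiff(unique(as.character(df$cell_type)), palette)
  if (length(unknown) > 0)
    stop("unknown cell-type label(s) not in palette: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (is.null(markers)) {
    candidates <- setdiff(colnames(df), .RESERVED_COLUMNS)
    markers <- candidates[vapply(df[candidates], is.numeric, logical(1))]
  }
  cd <- S4Vectors::DataFrame(
    cell_id = as.character(df$cell_id),
    image_id = as.character(df$image_id),
    x = as.numeric(df$x), y = as.numeric(df$y),
    cell_type = factor(as.character(df$cell_type), levels = palette))
  cd$domain <- if ("domain" %in% colnames(df))
    as.character(df$domain) else NA_character_
  cd$group <- if ("group" %in% colnames(df))
    as.character(df$group) else NA_character_
  assays <- list(intensities = t(as.matrix(df[, markers, drop = FALSE])))
  rownames(assays$intensities) <- markers
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = assays, colData = cd)
  colnames(sce) <- cd$cell_id
  metadata(sce)$palette <- palette
  methods::new("CellTable", sce)
}

#' Accessors for CellTable
#'
#' @param x a \linkS4class{CellTable}.
#' @return \code{cellIds}, \code{imageIds}: character vectors;
#'   \code{spatialCoords}: n x 2 numeric matrix (columns x, y);
#'   \code{cellTypes}: factor; \code{cellTypePalette}: ordered character
#'   vector of allowed types; \code{markerNames}: character;
#'   \code{intensities}: markers x cells matrix; \code{cellGroups},
#'   \code{cellDomains}: character vectors.
#' @name CellTable-accessors
NULL

#' @rdname CellTable-accessors
#' @export
setMethod("cellIds", "CellTable", function(x)
  SummarizedExperiment::colData(x)$cell_id)

#' @rdname CellTable-accessors
#' @export
setMethod("imageIds", "CellTable", function(x)
  SummarizedExperiment::colData(x)$image_id)

#' @rdname CellTable-accessors
#' @export
setMethod("spatialCoords", "CellTable", function(x) {
  cd <- SummarizedExperiment::colData(x)
  cbind(x = cd$x, y = cd$y)
})

#' @rdname CellTable-accessors
#' @export
setMethod("cellTypes", "CellTable", function(x)
  SummarizedExperiment::colData(x)$cell_type)

#' @rdname CellTable-accessors
#' @export
setMethod("cellTypePalette", "CellTable", function(x)
  levels(SummarizedExperiment::colData(x)$cell_type))

#' @rdname CellTable-accessors
#' @export
setMethod("markerNames", "CellTable", function(x)
  rownames(SummarizedExperiment::assay(x, "intensities")))

#' @rdname CellTable-accessors
#' @export
setMethod("intensities", "CellTable", function(x)
  SummarizedExperiment::assay(x, "intensities"))

#' @rdname CellTable-accessors
#' @export
setMethod("cellGroups", "CellTable", function(x)
  SummarizedExperiment::colData(x)$group)

#' @rdname CellTable-accessors
#' @export
setMethod("cellDomains", "CellTable", function(x)
  SummarizedExperiment::colData(x)$domain)

setMethod("show", "CellTable", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("CellTable:", ncol(object), "cells,",
      length(unique(cd$image_id)), "image(s),",
      length(levels(cd$cell_type)), "cell types,",
      nrow(object), "markers\n")
  tt <- sort(table(cd$cell_type), decreasing = TRUE)
  cat("  top types:",
      paste(sprintf("%s (%d)", names(head(tt, 4)), head(tt, 4)),
            collapse = ", "), "\n")
})

#' Convert a CellTable back to a per-cell data.frame
#'
#' Inverse of [CellTable()]: one row per cell with the reserved metadata
#' columns followed by one numeric column per marker.
#'
#' @param x a \linkS4class{CellTable}.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return data.frame with columns cell_id, image_id, x, y, cell_type,
#'   domain, group, then markers.
#' @export
as.data.frame.CellTable <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  cd <- SummarizedExperiment::colData(x)
  out <- data.frame(cell_id = cd$cell_id, image_id = cd$image_id,
                    x = cd$x, y = cd$y,
                    cell_type = as.character(cd$cell_type),
                    domain = cd$domain, group = cd$group,
                    stringsAsFactors = FALSE)
  im <- intensities(x)
  if (nrow(im) > 0) out <- cbind(out, as.data.frame(t(im)))
  rownames(out) <- NULL
  out
}
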