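#' Read a cell table from CSV
#'
#' Reads a UTF-8 CSV with one row per segmented cell. The header must
#' contain \code{cell_id}, \code{image_id}, \code{x}, \code{y},
#' \code{cell_type}; \code{domain} and \code{group} are optional; all other
#' numeric columns are auto-detected as marker intensities.
#'
#' @param path path to a CSV file.
#' @param palette optional ordered cell-type palette; unknown labels in the
#'   file raise an error naming them.
#' @return A \linkS4class{CellTable}.
#' @seealso [writeCellTable()], [CellTable()]
#' @export
readCellTable <- function(path, palette = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, encoding = "UTF-8")
  required <- c("cell_id", "image_id", "x", "y", "cell_type")
  miss <- setdiff(required, colnames(df))
  if (length(miss) > 0)
    stop("schema error: missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (col in c("x", "y")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) > 0)
      stop(sprintf("parse error: non-numeric '%s' at row %d", col, bad[1]),
           call. = FALSE)
    df[[col]] <- v
  }
  CellTable(df, palette = palette)
}

#' Write a cell table to CSV
#'
#' Writes the reserved metadata columns followed by one column per marker;
#' [readCellTable()] of the result reproduces the object (text fields
#' exactly, numerics to full double precision).
#'
#' @param x a \linkS4class{CellTable}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCellTable <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Log2 scaling with pseudocount
#'
#' \code{log2(value + pseudocount)} elementwise, the transform applied to
#' marker intensities before display or comparison. With the default
#' pseudocount of 1, zero maps to zero.
#'
#' @param values non-negative numeric vector.
#' @param pseudocount offset added before taking logs (default 1).
#' @return numeric vector of the same length.
#' @examples
#' log2Scale(c(0, 1, 7))  # 0 1 3
#' @export
log2Scale <- function(values, pseudocount = 1) {
  if (any(values < 0, na.rm = TRUE))
    stop("log2Scale requires non-negative values", call. = FALSE)
  log2(values + pseudocount)
}

#' Create an analysis configuration
#'
#' @param radius_px neighbor radius in um (= px for IMC); default 15.
#' @param knn_k graph-building k for profile clustering; default 250.
#' @param n_perm permutation rounds; default 1000.
#' @param alpha significance level; default 0.01.
#' @param max_dist_px nearest-distance cap; default 800.
#' @param expr_threshold marker high/low cut; default 0.5.
#' @param density_threshold community presence threshold in cells/mm^2;
#'   default 25 (inclusive).
#' @param window_k kNN window size including the center cell; default 10.
#' @param seed master random seed.
#' @return An \linkS4class{AnalysisConfig}.
#' @export
analysisConfig <- function(radius_px = 15, knn_k = 250L, n_perm = 1000L,
                           alpha = 0.01, max_dist_px = 800,
                           expr_threshold = 0.5, density_threshold = 25,
                           window_k = 10L, seed = 1L) {
  methods::new("AnalysisConfig", radius_px = as.numeric(radius_px),
               knn_k = as.integer(knn_k), n_perm = as.integer(n_perm),
               alpha = as.numeric(alpha),
               max_dist_px = as.numeric(max_dist_px),
               expr_threshold = as.numeric(expr_threshold),
               density_threshold = as.numeric(density_threshold),
               window_k = as.integer(window_k), seed = as.integer(seed))
}

#' Read an analysis configuration from a YAML file
#'
#' The file is a flat mapping of [analysisConfig()] argument names to
#' values; unknown keys raise an error.
#'
#' @param path YAML file path.
#' @return An \linkS4class{AnalysisConfig}.
#' @export
readAnalysisConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(analysisConfig))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(analysisConfig, vals)
}

#' Coerce an AnalysisConfig to a named list
#' @param x an \linkS4class{AnalysisConfig}.
#' @param ... ignored.
#' @return named list of configuration values.
#' @export
as.list.AnalysisConfig <- function(x, ...) {
  nm <- methods::slotNames("AnalysisConfig")
  stats::setNames(lapply(nm, function(s) methods::slot(x, s)), nm)
}

setMethod("show", "AnalysisConfig", function(object) {
  v <- as.list.AnalysisConfig(object)
  cat("AnalysisConfig:",
      paste(names(v), unlist(v), sep = "=", collapse = ", "), "\n")
})
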