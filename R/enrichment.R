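#' Permutation-based neighborhood enrichment around a focal cell type
#'
#' Tests, per image, whether each cell type is over- or under-represented
#' in the radius neighborhood of focal cells (e.g. CD8+ T cells), compared
#' with a null in which cell-type labels are randomly permuted over the
#' same positions and graph. The statistic is the mean count of the
#' neighbor type per focal cell. By default the analysis is restricted to
#' one spatial community and labels are permuted within that community
#' (\code{permute_within = "community"}); \code{"image"} permutes across
#' the whole image instead. One-sided p-values use the add-one correction
#' \code{p = (1 + #[perm >= obs]) / (n_perm + 1)} and are therefore never
#' exactly zero; log2 fold changes are
#' \code{log2((obs + eps) / (null_mean + eps))} with \code{eps = 1}.
#'
#' When \code{conditioning_type} is given (e.g. "Treg"), focal statistics
#' are computed separately for focal cells with and without a
#' conditioning-type cell in their neighborhood, and conditioning-type
#' cells keep their labels fixed under permutation so the two strata remain
#' defined under the null.
#'
#' @param cells a \linkS4class{CellTable}.
#' @param graph the \linkS4class{NeighborGraph} on the same cells.
#' @param focal_type cell type whose neighborhood is analyzed.
#' @param labeling optional \linkS4class{CommunityLabeling}.
#' @param community community id to restrict to (requires
#'   \code{labeling}).
#' @param n_perm number of permutations; default 1000 (a warning is issued
#'   below 100).
#' @param seed random seed.
#' @param alpha significance level; default 0.01.
#' @param permute_within \code{"community"} (default) or \code{"image"}.
#' @param conditioning_type optional cell type for conditional
#'   stratification.
#' @param epsilon pseudocount inside the log2 ratio; default 1.
#' @return \link[S4Vectors]{DataFrame} with one row per
#'   (image, stratum, neighbor type): observed and null-mean statistics,
#'   log2fc, p_enrich, p_deplete, and a significance flag at
#'   \code{min(p) <= alpha}. Images without focal cells are skipped with a
#'   warning.
#' @export
permutationEnrichment <- function(cells, graph, focal_type, labeling = NULL,
                                  community = NULL, n_perm = 1000, seed = 1,
                                  alpha = 0.01,
                                  permute_within = c("community", "image"),
                                  conditioning_type = NULL, epsilon = 1) {
  permute_within <- match.arg(permute_within)
  if (n_perm < 100)
    warning("n_perm < 100 gives very coarse p-values")
  palette <- cellTypePalette(cells)
  if (!focal_type %in% palette)
    stop("focal_type not in palette: ", focal_type, call. = FALSE)
  types <- as.character(cellTypes(cells))
  tcode <- match(types, palette)
  img <- imageIds(cells)
  n <- ncol(cells)
  in_comm <- rep(TRUE, n)
  if (!is.null(community)) {
    if (is.null(labeling))
      stop("community restriction requires a labeling", call. = FALSE)
    in_comm <- communityLabels(labeling) == community
  }
  strat_all <- factor(rep("all", n))
  if (!is.null(conditioning_type)) {
    strat_all <- conditionalSplit(cells, graph, conditioning_type)
  }
  e <- edgeMatrix(graph)
  focal_code <- match(focal_type, palette)
  cond_code <- if (is.null(conditioning_type)) 0L else
    match(conditioning_type, palette)
  nT <- length(palette)
  rows <- list()
  withr::with_seed(seed, {
    for (im in unique(img)) {
      sel <- which(img == im &
                     (if (permute_within == "community") in_comm else TRUE))
      analyzed <- in_comm[sel]
      if (!any(tcode[sel] == focal_code & analyzed)) {
        warning("image ", im, ": no focal cells; skipped")
        next
      }
      local_of <- integer(n); local_of[sel] <- seq_along(sel)
      in_sel <- logical(n); in_sel[sel] <- TRUE
      keep <- in_sel[e[, 1]] & in_sel[e[, 2]]
      df <- local_of[c(e[keep, 1], e[keep, 2])]
      dt <- local_of[c(e[keep, 2], e[keep, 1])]
      lab0 <- tcode[sel]
      strat <- strat_all[sel]
      anz <- analyzed
      movable <- if (cond_code > 0) which(lab0 != cond_code) else
        seq_along(sel)
      stat_fun <- function(lab) {
        out <- matrix(0, nlevels(strat), nT)
        nf <- numeric(nlevels(strat))
        for (si in seq_len(nlevels(strat))) {
          f <- lab == focal_code & as.integer(strat) == si & anz
          nf[si] <- sum(f)
          if (nf[si] > 0 && length(df) > 0) {
            sel_e <- f[df]
            out[si, ] <- tabulate(lab[dt[sel_e]], nbins = nT) / nf[si]
          }
        }
        list(stat = out, n_focal = nf)
      }
      obs <- stat_fun(lab0)
      ge <- matrix(0, nlevels(strat), nT)
      le <- matrix(0, nlevels(strat), nT)
      sum_null <- matrix(0, nlevels(strat), nT)
      for (r in seq_len(n_perm)) {
        lab <- lab0
        lab[movable] <- lab0[sample(movable)]
        st <- stat_fun(lab)$stat
        ge <- ge + (st >= obs$stat - 1e-12)
        le <- le + (st <= obs$stat + 1e-12)
        sum_null <- sum_null + st
      }
      null_mean <- sum_null / n_perm
      p_enrich <- (1 + ge) / (n_perm + 1)
      p_deplete <- (1 + le) / (n_perm + 1)
      for (si in seq_len(nlevels(strat))) {
        if (obs$n_focal[si] == 0) next
        rows[[length(rows) + 1]] <- data.frame(
          image_id = im, stratum = levels(strat)[si],
          focal_type = focal_type, neighbor_type = palette,
          n_focal = obs$n_focal[si], observed = obs$stat[si, ],
          null_mean = null_mean[si, ],
          log2fc = log2((obs$stat[si, ] + epsilon) /
                          (null_mean[si, ] + epsilon)),
          p_enrich = p_enrich[si, ], p_deplete = p_deplete[si, ],
          stringsAsFactors = FALSE)
      }
    }
  })
  if (length(rows) == 0)
    stop("no image contained focal cells", call. = FALSE)
  out <- do.call(rbind, rows)
  out$significant <- pmin(out$p_enrich, out$p_deplete) <= alpha
  S4Vectors::DataFrame(out)
}

#' Stratify focal cells by presence of a conditioning cell type
#'
#' A cell is in the \code{"with"} stratum when at least one cell of
#' \code{conditioning_type} lies in its radius neighborhood, else
#' \code{"without"}. Used to split a community's focal cells by, e.g.,
#' regulatory T cell presence before running [permutationEnrichment()].
#'
#' @param cells a \linkS4class{CellTable}.
#' @param graph the \linkS4class{NeighborGraph} on the same cells.
#' @param conditioning_type cell type from the palette.
#' @return factor of length \code{ncol(cells)} with levels
#'   \code{c("with", "without")}.
#' @export
conditionalSplit <- function(cells, graph, conditioning_type) {
  palette <- cellTypePalette(cells)
  if (!conditioning_type %in% palette)
    stop("conditioning_type not in palette: ", conditioning_type,
         call. = FALSE)
  is_cond <- as.character(cellTypes(cells)) == conditioning_type
  e <- edgeMatrix(graph)
  from <- c(e[, 1], e[, 2]); to <- c(e[, 2], e[, 1])
  has_cond <- rep(FALSE, ncol(cells))
  hit <- from[is_cond[to]]
  has_cond[hit] <- TRUE
  factor(ifelse(has_cond, "with", "without"),
         levels = c("with", "without"))
}

#' Normalized count of marker-positive neighbors
#'
#' Counts, per image, how often a marker-positive cell of
#' \code{target_type} (intensity strictly above \code{expr_threshold})
#' appears in the neighborhood of a \code{focal_type} cell, averaged over
#' focal cells, and normalizes by the prevalence of marker positivity among
#' \code{target_type} cells in the image's treatment group (so arms with
#' different positivity rates are comparable). The relative count is
#' flagged undefined where the prevalence is zero.
#'
#' @param cells a \linkS4class{CellTable}.
#' @param graph the \linkS4class{NeighborGraph} on the same cells.
#' @param focal_type,target_type cell types from the palette.
#' @param target_marker marker name.
#' @param expr_threshold positivity cut on the stored intensity;
#'   default 0.5.
#' @return \link[S4Vectors]{DataFrame} with one row per image: mean_count,
#'   normalizer (group prevalence), relative_count, undefined flag.
#' @export
interactionCount <- function(cells, graph, focal_type, target_type,
                             target_marker, expr_threshold = 0.5) {
  if (!target_marker %in% markerNames(cells))
    stop("marker not in table: ", target_marker, call. = FALSE)
  types <- as.character(cellTypes(cells))
  marker <- intensities(cells)[target_marker, ]
  img <- imageIds(cells)
  grp <- cellGroups(cells)
  grp[is.na(grp)] <- "(all)"
  qualifying <- types == target_type & marker > expr_threshold
  e <- edgeMatrix(graph)
  from <- c(e[, 1], e[, 2]); to <- c(e[, 2], e[, 1])
  qual_nbrs <- tabulate(from[qualifying[to]], nbins = ncol(cells))
  prevalence <- vapply(unique(grp), function(g) {
    tt <- types == target_type & grp == g
    if (!any(tt)) return(NA_real_)
    mean(marker[tt] > expr_threshold)
  }, 0)
  names(prevalence) <- unique(grp)
  rows <- lapply(unique(img), function(im) {
    focal <- which(img == im & types == focal_type)
    if (length(focal) == 0) return(NULL)
    g <- grp[img == im][1]
    norm <- unname(prevalence[as.character(g)])
    mc <- mean(qual_nbrs[focal])
    data.frame(image_id = im, group = g, n_focal = length(focal),
               mean_count = mc, normalizer = norm,
               relative_count = if (!is.na(norm) && norm > 0) mc / norm
               else NA_real_,
               undefined = is.na(norm) || norm == 0,
               stringsAsFactors = FALSE)
  })
  S4Vectors::DataFrame(do.call(rbind, rows))
}
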