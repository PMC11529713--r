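.canonicalOrder <- function(labels, k) {
  sizes <- tabulate(labels, nbins = k)
  order(-sizes, seq_len(k))
}

# Build a CommunityLabeling from raw labels; ids are relabeled 1..K by
# decreasing community size so repeated runs are comparable.
.makeLabeling <- function(labels, profiles, cell_types, palette, params) {
  labels <- as.integer(factor(labels))
  k <- max(labels)
  ord <- .canonicalOrder(labels, k)
  remap <- integer(k); remap[ord] <- seq_len(k)
  labels <- remap[labels]
  sizes <- tabulate(labels, nbins = k)
  typeComp <- matrix(NA_real_, k, length(palette),
                     dimnames = list(seq_len(k), palette))
  if (!is.null(cell_types)) {
    tc <- table(factor(labels, levels = seq_len(k)),
                factor(as.character(cell_types), levels = palette))
    typeComp <- sweep(unclass(tc), 1, pmax(rowSums(tc), 1), "/")
    dimnames(typeComp) <- list(seq_len(k), palette)
  }
  profComp <- matrix(NA_real_, k, length(palette),
                     dimnames = list(seq_len(k), palette))
  if (!is.null(profiles)) {
    profComp <- do.call(rbind, lapply(seq_len(k), function(i)
      colMeans(profiles[labels == i, , drop = FALSE])))
    dimnames(profComp) <- list(seq_len(k), colnames(profiles))
  }
  methods::new("CommunityLabeling", labels = labels,
               typeComposition = typeComp, profileComposition = profComp,
               sizes = as.integer(sizes), params = params)
}

#' Accessors for CommunityLabeling
#'
#' @param x a \linkS4class{CommunityLabeling}.
#' @return \code{communityLabels}: integer community id per cell;
#'   \code{communitySizes}: integer vector; \code{typeComposition},
#'   \code{profileComposition}: K x T matrices; \code{nCommunities}:
#'   integer.
#' @name CommunityLabeling-accessors
NULL

#' @rdname CommunityLabeling-accessors
#' @export
setMethod("communityLabels", "CommunityLabeling", function(x) x@labels)

#' @rdname CommunityLabeling-accessors
#' @export
setMethod("communitySizes", "CommunityLabeling", function(x) x@sizes)

#' @rdname CommunityLabeling-accessors
#' @export
setMethod("typeComposition", "CommunityLabeling", function(x)
  x@typeComposition)

#' @rdname CommunityLabeling-accessors
#' @export
setMethod("profileComposition", "CommunityLabeling", function(x)
  x@profileComposition)

#' @rdname CommunityLabeling-accessors
#' @export
setMethod("nCommunities", "CommunityLabeling", function(x) length(x@sizes))

setMethod("show", "CommunityLabeling", function(object) {
  cat("CommunityLabeling:", length(object@labels), "cells in",
      length(object@sizes), "communities; sizes",
      paste(utils::head(object@sizes, 8), collapse = ", "),
      if (length(object@sizes) > 8) "..." else "", "\n")
})

#' @rdname MergeTree-accessors
#' @export
setMethod("mergeSteps", "MergeTree", function(x) x@merges)

setMethod("show", "MergeTree", function(object) {
  cat("MergeTree:", object@initial_n, "->", object@target_n,
      "communities in", nrow(object@merges), "merges\n")
})

#' Cluster neighborhood profiles into spatial communities
#'
#' PhenoGraph-style community detection on per-cell neighborhood
#' composition profiles: a k-nearest-neighbor graph is built on the profile
#' vectors (euclidean), edges are reweighted by the Jaccard overlap of the
#' two endpoints' kNN sets, and Louvain modularity optimization partitions
#' the graph. Cells in the same community therefore share a recurring local
#' microenvironment, regardless of their own phenotype.
#'
#' @param profiles cells x types matrix from [neighborhoodProfiles()].
#' @param knn_k number of nearest neighbors for graph building (must be
#'   smaller than the number of cells). The reference scale is k = 250 on
#'   cohorts of 1e5+ cells; scale k below the smallest community of
#'   interest on smaller data.
#' @param seed random seed (Louvain is seeded and reproducible).
#' @param cell_types optional factor/character of member cells' own types;
#'   when supplied the labeling carries the type composition used by
#'   agglomeration and cross-run matching.
#' @return A \linkS4class{CommunityLabeling}.
#' @export
clusterProfiles <- function(profiles, knn_k = 250, seed = 1,
                            cell_types = NULL) {
  n <- nrow(profiles)
  if (knn_k >= n)
    stop("knn_k must be smaller than the number of cells", call. = FALSE)
  # the kNN search shares the seed: its tie resolution draws from R's RNG
  knn <- withr::with_seed(seed,
    .quietTies(BiocNeighbors::findKNN(profiles, k = knn_k)))
  idx <- knn$index
  # kNN sets including self; shared-neighbor counts via sparse crossproduct
  A <- Matrix::sparseMatrix(i = rep.int(seq_len(n), knn_k + 1L),
                            j = c(as.vector(idx), seq_len(n)),
                            x = 1, dims = c(n, n))
  S <- Matrix::tcrossprod(A)
  P <- Matrix::sparseMatrix(i = rep.int(seq_len(n), knn_k),
                            j = as.vector(idx), x = 1, dims = c(n, n))
  P <- P + Matrix::t(P)  # union of directed kNN edges
  W <- methods::as(S * (P > 0), "TsparseMatrix")
  keep <- W@i < W@j  # 0-based triplet indices; upper triangle once
  ei <- W@i[keep] + 1L; ej <- W@j[keep] + 1L
  shared <- W@x[keep]
  jac <- shared / (2 * (knn_k + 1) - shared)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(ei, ej))
  igraph::E(g)$weight <- jac
  cl <- withr::with_seed(seed, igraph::cluster_louvain(g))
  palette <- colnames(profiles)
  if (!is.null(cell_types) && is.factor(cell_types))
    palette <- union(palette, levels(cell_types))
  .makeLabeling(igraph::membership(cl), profiles, cell_types, palette,
                params = list(method = "phenograph_louvain", knn_k = knn_k,
                              seed = seed))
}

#' Agglomerate communities to a target count
#'
#' Hierarchical agglomeration (average linkage on euclidean distance
#' between community type-composition profiles) merges the most similar
#' communities first — in tumor tissue these are the low-diversity,
#' tumor-dominated variants — until \code{target_n} communities remain.
#'
#' @param labeling a \linkS4class{CommunityLabeling}.
#' @param target_n desired number of communities (>= 1, below the current
#'   count).
#' @return list with \code{labeling} (new \linkS4class{CommunityLabeling},
#'   ids 1..target_n by decreasing size) and \code{tree}
#'   (\linkS4class{MergeTree} of the merges applied).
#' @export
agglomerateCommunities <- function(labeling, target_n) {
  k <- nCommunities(labeling)
  if (target_n < 1) stop("target_n must be >= 1", call. = FALSE)
  if (target_n >= k)
    stop("target_n must be below the current community count", call. = FALSE)
  comp <- typeComposition(labeling)
  if (anyNA(comp)) comp <- profileComposition(labeling)
  h <- stats::hclust(stats::dist(comp), method = "average")
  cut <- stats::cutree(h, k = target_n)
  n_merge <- k - target_n
  node_id <- function(j) if (j < 0) -j else k + j
  merges <- data.frame(step = seq_len(n_merge),
                       a = vapply(seq_len(n_merge),
                                  function(s) node_id(h$merge[s, 1]), 0),
                       b = vapply(seq_len(n_merge),
                                  function(s) node_id(h$merge[s, 2]), 0),
                       merged = k + seq_len(n_merge))
  tree <- methods::new("MergeTree", merges = merges,
                       initial_n = as.integer(k),
                       target_n = as.integer(target_n))
  sizes <- communitySizes(labeling)
  new_k <- target_n
  ord <- order(-vapply(seq_len(new_k),
                       function(g) sum(sizes[cut == g]), 0),
               seq_len(new_k))
  remap <- integer(new_k); remap[ord] <- seq_len(new_k)
  cut2 <- remap[cut]
  agg <- function(m) {
    out <- matrix(0, new_k, ncol(m), dimnames = list(seq_len(new_k),
                                                     colnames(m)))
    for (g in seq_len(new_k)) {
      sel <- which(cut2 == g)
      w <- sizes[sel] / sum(sizes[sel])
      out[g, ] <- colSums(m[sel, , drop = FALSE] * w)
    }
    out
  }
  new_lab <- methods::new("CommunityLabeling",
                          labels = cut2[communityLabels(labeling)],
                          typeComposition = agg(typeComposition(labeling)),
                          profileComposition =
                            agg(profileComposition(labeling)),
                          sizes = as.integer(vapply(seq_len(new_k),
                            function(g) sum(sizes[cut2 == g]), 0)),
                          params = c(labeling@params,
                                     list(agglomerated_from = k,
                                          target_n = target_n)))
  list(labeling = new_lab, tree = tree)
}

#' Match communities between two labelings
#'
#' Pearson correlation between every pair of community type-composition
#' profiles from two labelings (e.g. clusterings of the same data at
#' different kNN parameters), followed by a greedy best-match assignment in
#' decreasing correlation (ties broken by community size). Used to show
#' that community phenotypes are stable across clustering parameters.
#'
#' @param a,b \linkS4class{CommunityLabeling} objects over the same
#'   cell-type palette.
#' @return list of class \code{"CommunityMatch"} with \code{similarity}
#'   (Ka x Kb correlation matrix) and \code{matches} (data.frame a, b,
#'   correlation).
#' @export
matchCommunities <- function(a, b) {
  ca <- typeComposition(a); cb <- typeComposition(b)
  if (!identical(colnames(ca), colnames(cb)))
    stop("labelings use different palettes", call. = FALSE)
  sim <- suppressWarnings(stats::cor(t(ca), t(cb)))
  dimnames(sim) <- list(seq_len(nrow(ca)), seq_len(nrow(cb)))
  avail_a <- rep(TRUE, nrow(sim)); avail_b <- rep(TRUE, ncol(sim))
  out <- list()
  for (step in seq_len(min(nrow(sim), ncol(sim)))) {
    s <- sim
    s[!avail_a, ] <- -Inf; s[, !avail_b] <- -Inf
    s[is.na(s)] <- -Inf
    best <- max(s)
    if (!is.finite(best)) break
    cand <- which(s == best, arr.ind = TRUE)
    if (nrow(cand) > 1) {
      pri <- order(-communitySizes(a)[cand[, 1]],
                   -communitySizes(b)[cand[, 2]],
                   cand[, 1], cand[, 2])
      cand <- cand[pri[1], , drop = FALSE]
    }
    out[[step]] <- data.frame(a = cand[1, 1], b = cand[1, 2],
                              correlation = best)
    avail_a[cand[1, 1]] <- FALSE; avail_b[cand[1, 2]] <- FALSE
  }
  structure(list(similarity = sim, matches = do.call(rbind, out)),
            class = "CommunityMatch")
}

#' @export
print.CommunityMatch <- function(x, ...) {
  cat("CommunityMatch:", nrow(x$similarity), "x", ncol(x$similarity),
      "communities;", nrow(x$matches), "matches, median correlation",
      round(stats::median(x$matches$correlation), 3), "\n")
  invisible(x)
}

#' Rank communities by their count of a given cell type
#'
#' Sorts communities by how many cells of \code{cell_type} they contain and
#' reports the fraction of all such cells captured by the top
#' \code{top_n} communities (e.g. which communities hold the bulk of the
#' CD8+ T cell population).
#'
#' @param labeling a \linkS4class{CommunityLabeling}.
#' @param cells the \linkS4class{CellTable} the labeling refers to.
#' @param cell_type cell-type label from the palette.
#' @param top_n number of communities reported; default 5.
#' @return list with \code{ranking} (data.frame community, count, ordered),
#'   \code{top} (top_n community ids) and \code{coverage} (fraction of all
#'   cells of the type inside the top communities).
#' @export
rankByCellType <- function(labeling, cells, cell_type, top_n = 5) {
  if (!cell_type %in% cellTypePalette(cells)) {
    warning("cell type '", cell_type, "' not in palette; empty ranking")
    return(list(ranking = data.frame(community = integer(0),
                                     count = integer(0)),
                top = integer(0), coverage = NA_real_))
  }
  is_type <- as.character(cellTypes(cells)) == cell_type
  k <- nCommunities(labeling)
  counts <- tabulate(communityLabels(labeling)[is_type], nbins = k)
  ord <- order(-counts, seq_len(k))
  ranking <- data.frame(community = ord, count = counts[ord])
  top <- utils::head(ord, top_n)
  total <- sum(counts)
  coverage <- if (total > 0) sum(counts[top]) / total else NA_real_
  if (total == 0) warning("no cells of type '", cell_type, "' present")
  list(ranking = ranking, top = top, coverage = coverage)
}

#' Mini-batch k-means
#'
#' Seeded mini-batch k-means (k-means++ initialization, per-center
#' learning-rate updates) for clustering large window-composition matrices.
#'
#' @param x numeric matrix (observations x features).
#' @param k number of clusters.
#' @param seed random seed.
#' @param batch_size mini-batch size; default 256.
#' @param max_iter number of mini-batch updates; default 200.
#' @return list with \code{cluster} (integer assignments from a final full
#'   pass) and \code{centers} (k x features matrix).
#' @export
miniBatchKMeans <- function(x, k, seed = 1, batch_size = 256,
                            max_iter = 200) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k > n) stop("k must not exceed the number of observations",
                  call. = FALSE)
  assign_full <- function(centers) {
    d <- outer(rowSums(x^2), rowSums(centers^2), "+") -
      2 * x %*% t(centers)
    max.col(-d, ties.method = "first")
  }
  withr::with_seed(seed, {
    # k-means++ seeding
    centers <- matrix(0, k, ncol(x))
    centers[1, ] <- x[sample.int(n, 1), ]
    if (k > 1) {
      d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
      for (j in 2:k) {
        p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
        centers[j, ] <- x[sample.int(n, 1, prob = p), ]
        d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
      }
    }
    v <- rep(0, k)
    for (it in seq_len(max_iter)) {
      b <- x[sample.int(n, min(batch_size, n)), , drop = FALSE]
      d <- outer(rowSums(b^2), rowSums(centers^2), "+") -
        2 * b %*% t(centers)
      a <- max.col(-d, ties.method = "first")
      for (c_ in unique(a)) {
        rows <- which(a == c_)
        nb <- length(rows)
        v[c_] <- v[c_] + nb
        centers[c_, ] <- centers[c_, ] +
          (colSums(b[rows, , drop = FALSE]) - nb * centers[c_, ]) / v[c_]
      }
    }
  })
  cl <- assign_full(centers)
  list(cluster = cl, centers = centers)
}

#' Cluster kNN windows into spatial communities (k-means variant)
#'
#' The window-based community detection used for tissue-microarray panels:
#' every cell's window (itself plus its nearest neighbors) is summarized by
#' its cell-type count vector, the windows are clustered with seeded
#' mini-batch k-means, and each cell inherits the cluster of its window.
#'
#' @param windows output of [knnWindows()].
#' @param n_clusters number of communities (>= 1, at most the cell count).
#' @param seed random seed.
#' @param method \code{"minibatch"} (default) or \code{"lloyd"}
#'   (\code{stats::kmeans} on the full data).
#' @param ... passed to [miniBatchKMeans()].
#' @return A \linkS4class{CommunityLabeling}.
#' @export
windowKmeans <- function(windows, n_clusters, seed = 1,
                         method = c("minibatch", "lloyd"), ...) {
  method <- match.arg(method)
  x <- windows$counts
  if (n_clusters < 1) stop("n_clusters must be >= 1", call. = FALSE)
  if (n_clusters > nrow(x))
    stop("n_clusters must not exceed the number of cells", call. = FALSE)
  labels <- if (method == "minibatch") {
    miniBatchKMeans(x, n_clusters, seed = seed, ...)$cluster
  } else {
    withr::with_seed(seed,
      stats::kmeans(x, centers = n_clusters, nstart = 10,
                    iter.max = 100)$cluster)
  }
  prof <- x / pmax(rowSums(x), 1)
  .makeLabeling(labels, prof, windows$center_type, colnames(x),
                params = list(method = paste0("window_kmeans_", method),
                              n_clusters = n_clusters, seed = seed))
}

#' Z-score community composition profiles
#'
#' Standardizes each cell type's proportion across communities (column mean
#' 0, sd 1), the representation used to display which cell types
#' characterize each community. Zero-variance columns are set to 0 with a
#' warning.
#'
#' @param labeling a \linkS4class{CommunityLabeling} with >= 2 communities.
#' @return communities x cell types matrix of z-scores.
#' @export
zscoreProfile <- function(labeling) {
  if (nCommunities(labeling) < 2)
    stop("zscoreProfile needs at least 2 communities", call. = FALSE)
  m <- typeComposition(labeling)
  if (anyNA(m)) m <- profileComposition(labeling)
  z <- scale(m)
  bad <- which(attr(z, "scaled:scale") == 0 |
                 !is.finite(attr(z, "scaled:scale")))
  if (length(bad) > 0) {
    warning("zero-variance cell type(s) set to 0: ",
            paste(colnames(m)[bad], collapse = ", "))
    z[, bad] <- 0
  }
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  z
}
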