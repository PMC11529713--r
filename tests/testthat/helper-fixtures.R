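# fixtures are built in code; no data files

toyCells <- function(x, y, type, image_id = "img1", palette = NULL, ...) {
  df <- data.frame(cell_id = sprintf("c%03d", seq_along(x)),
                   image_id = image_id, x = x, y = y, cell_type = type,
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  if (is.null(palette)) {
    palette <- sort(unique(type))
    if (length(palette) < 2) palette <- c(palette, "Other")
  }
  CellTable(df, palette = palette)
}

randomCells <- function(n, seed, types = c("A", "B", "C"),
                        field = 500, n_images = 1, markers = NULL) {
  withr::with_seed(seed, {
    df <- data.frame(
      cell_id = sprintf("c%04d", seq_len(n)),
      image_id = sprintf("img%d", sample.int(n_images, n, replace = TRUE)),
      x = runif(n, 0, field), y = runif(n, 0, field),
      cell_type = sample(types, n, replace = TRUE),
      stringsAsFactors = FALSE)
    for (m in markers) df[[m]] <- rlnorm(n)
    df
  })
}

# O(n^2) oracle for the fixed-radius neighbor rule (inclusive boundary)
bruteForceEdges <- function(cells, radius) {
  xy <- spatialCoords(cells)
  img <- imageIds(cells)
  d <- as.matrix(stats::dist(xy))
  hit <- which(d <= radius & upper.tri(d), arr.ind = TRUE)
  hit <- hit[img[hit[, 1]] == img[hit[, 2]], , drop = FALSE]
  hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
}

# brute-force average-linkage (UPGMA on euclidean) merge sequence:
# returns list of partitions (one per merge step) over the original items
bruteAverageLinkage <- function(m) {
  d <- as.matrix(stats::dist(m))
  groups <- as.list(seq_len(nrow(m)))
  partitions <- list()
  step <- 0
  while (length(groups) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (i >= j) next
      dd <- mean(d[groups[[i]], groups[[j]]])
      if (dd < best_d) { best_d <- dd; best <- c(i, j) }
    }
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
    step <- step + 1
    part <- integer(nrow(m))
    for (g in seq_along(groups)) part[groups[[g]]] <- g
    partitions[[step]] <- part
  }
  partitions
}

# rebuild the partition of original communities after the first n_steps
# merges recorded in a MergeTree
partitionFromTree <- function(tree, n_steps) {
  k <- tree@initial_n
  ms <- mergeSteps(tree)
  parent <- seq_len(k + nrow(ms))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (s in seq_len(n_steps)) {
    node <- ms$merged[s]
    parent[find(ms$a[s])] <- node
    parent[find(ms$b[s])] <- node
  }
  roots <- vapply(seq_len(k), find, 1L)
  as.integer(factor(roots))
}

# a labeling with prescribed per-community type compositions, built from
# synthetic member cells (sizes cells per community)
labelingFromComposition <- function(comp, sizes) {
  labels <- rep(seq_len(nrow(comp)), sizes)
  types <- unlist(lapply(seq_len(nrow(comp)), function(i) {
    counts <- round(comp[i, ] * sizes[i])
    counts[1] <- sizes[i] - sum(counts[-1])
    rep(colnames(comp), counts)
  }))
  lf <- factor(types, levels = colnames(comp))
  tc <- table(factor(labels), lf)
  tc <- sweep(unclass(tc), 1, rowSums(tc), "/")
  methods::new("CommunityLabeling", labels = as.integer(labels),
               typeComposition = unclass(tc),
               profileComposition = unclass(tc),
               sizes = as.integer(sizes), params = list())
}
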