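test_that("well-separated profile clouds are recovered exactly", {
  withr::with_seed(99, {
    centers <- rbind(c(0.8, 0.1, 0.1), c(0.1, 0.8, 0.1), c(0.1, 0.1, 0.8))
    truth <- rep(1:3, each = 1000)
    prof <- centers[truth, ] + matrix(rnorm(3000 * 3, sd = 0.01), 3000, 3)
  })
  colnames(prof) <- c("A", "B", "C")
  lab <- clusterProfiles(prof, knn_k = 50, seed = 1)
  # modularity optimization may split large homogeneous clouds into
  # sub-communities, but never mixes clouds: every community is pure ...
  expect_gte(nCommunities(lab), 3)
  purity <- vapply(seq_len(nCommunities(lab)), function(k) {
    max(table(truth[communityLabels(lab) == k])) /
      sum(communityLabels(lab) == k)
  }, 0)
  expect_true(all(purity == 1))
  # ... and agglomeration to the planted count recovers them exactly
  agg <- agglomerateCommunities(lab, 3)$labeling
  expect_equal(ariScore(communityLabels(agg), truth), 1.0)

  # determinism: same input + seed -> identical labeling
  lab2 <- clusterProfiles(prof, knn_k = 50, seed = 1)
  expect_identical(communityLabels(lab), communityLabels(lab2))

  # no structure: identical profiles collapse to one community
  flat <- matrix(0.5, 200, 2, dimnames = list(NULL, c("A", "B")))
  expect_equal(nCommunities(clusterProfiles(flat, knn_k = 10, seed = 1)), 1)

  expect_error(clusterProfiles(prof, knn_k = 3000, seed = 1), "smaller")
})

test_that("agglomeration merges nearest compositions and matches the UPGMA oracle", {
  withr::with_seed(4, {
    comp <- matrix(runif(8 * 4), 8, 4)
    comp <- sweep(comp, 1, rowSums(comp), "/")
    colnames(comp) <- c("A", "B", "C", "D")
    comp[2, ] <- comp[5, ]  # identical pair must merge first
    lab <- labelingFromComposition(comp, sizes = rep(100, 8))
  })
  res <- agglomerateCommunities(lab, 4)
  ms <- mergeSteps(res$tree)
  expect_equal(nrow(ms), 4)
  expect_setequal(c(ms$a[1], ms$b[1]), c(2, 5))
  # the recorded merge path reproduces brute-force average linkage
  oracle <- bruteAverageLinkage(typeComposition(lab))
  for (s in seq_len(nrow(ms)))
    expect_equal(ariScore(partitionFromTree(res$tree, s), oracle[[s]]), 1.0)

  # merged labeling bookkeeping: sizes, composition weighting, label cover
  expect_equal(nCommunities(res$labeling), 4)
  expect_equal(sum(communitySizes(res$labeling)), 800)
  expect_equal(unname(rowSums(typeComposition(res$labeling))),
               rep(1, 4), tolerance = 1e-9)

  one <- agglomerateCommunities(lab, 7)
  expect_equal(nrow(mergeSteps(one$tree)), 1)
  expect_error(agglomerateCommunities(lab, 0), ">= 1")
  expect_error(agglomerateCommunities(lab, 8), "below")
})

test_that("community matching recovers identity and permutations", {
  withr::with_seed(8, {
    comp <- matrix(runif(5 * 6), 5, 6)
    comp <- sweep(comp, 1, rowSums(comp), "/")
    colnames(comp) <- paste0("t", 1:6)
    lab <- labelingFromComposition(comp, sizes = c(50, 40, 30, 20, 10))
  })
  m <- matchCommunities(lab, lab)
  expect_equal(m$matches$a, m$matches$b)
  expect_equal(m$matches$correlation, rep(1, 5), tolerance = 1e-12)

  # permuted community ids are recovered by the greedy assignment
  perm <- c(3, 1, 5, 2, 4)
  lab_p <- labelingFromComposition(comp[perm, ],
                                   sizes = c(50, 40, 30, 20, 10)[perm])
  m2 <- matchCommunities(lab, lab_p)
  expect_equal(m2$matches$b[order(m2$matches$a)], order(perm))
  expect_true(all(m2$matches$correlation > 0.999))
})

test_that("ranking by cell type matches the counting oracle", {
  ct <- CellTable(randomCells(400, 21, types = c("CD8_T", "Tumor", "DC")))
  withr::with_seed(22, labels <- sample.int(10, 400, replace = TRUE))
  lab <- labelingFromGroundTruth(data.frame(community = labels), ct)
  r <- rankByCellType(lab, ct, "CD8_T", top_n = 5)
  counts <- tabulate(communityLabels(lab)[cellTypes(ct) == "CD8_T"], 10)
  expect_equal(r$ranking$count, sort(counts, decreasing = TRUE))
  expect_equal(r$coverage,
               sum(sort(counts, decreasing = TRUE)[1:5]) / sum(counts))

  # all focal cells in one community -> rank 1, full coverage
  one <- labelingFromGroundTruth(
    data.frame(community = ifelse(cellTypes(ct) == "CD8_T", "a", "b")), ct)
  r1 <- rankByCellType(one, ct, "CD8_T", top_n = 1)
  expect_equal(r1$coverage, 1.0)
  expect_warning(rankByCellType(lab, ct, "NK"), "not in palette")
})

test_that("window k-means recovers spatially segregated blocks", {
  # four distant blocks of a single cell type each
  withr::with_seed(31, {
    block <- rep(1:4, each = 100)
    x <- runif(400, 0, 60) + c(0, 1000, 0, 1000)[block]
    y <- runif(400, 0, 60) + c(0, 0, 1000, 1000)[block]
  })
  ct <- toyCells(x, y, c("A", "B", "C", "D")[block])
  w <- knnWindows(ct, window_k = 10)
  lab <- windowKmeans(w, 4, seed = 2)
  expect_equal(ariScore(communityLabels(lab), block), 1.0)
  expect_identical(communityLabels(windowKmeans(w, 4, seed = 2)),
                   communityLabels(lab))
  expect_equal(nCommunities(windowKmeans(w, 1, seed = 2)), 1)
  # the lloyd backend agrees on clearly separated data
  expect_equal(ariScore(
    communityLabels(windowKmeans(w, 4, seed = 2, method = "lloyd")),
    block), 1.0)
  expect_error(windowKmeans(w, 0), ">= 1")
  expect_error(windowKmeans(w, 500), "exceed")
})

test_that("mini-batch k-means agrees with stats::kmeans on separated data", {
  withr::with_seed(5, {
    x <- rbind(matrix(rnorm(200, 0, 0.1), 100, 2),
               matrix(rnorm(200, 5, 0.1), 100, 2),
               matrix(rnorm(200, 10, 0.1), 100, 2))
  })
  mb <- miniBatchKMeans(x, 3, seed = 9)
  km <- withr::with_seed(9, stats::kmeans(x, 3, nstart = 10))
  expect_equal(ariScore(mb$cluster, km$cluster), 1.0)
  # centers converge to the true means up to ordering
  got <- mb$centers[order(mb$centers[, 1]), ]
  expect_equal(got[, 1], c(0, 5, 10), tolerance = 0.15)
})

test_that("z-score profiles standardize each cell type across communities", {
  comp <- cbind(A = c(0.2, 0.4), B = c(0.8, 0.6))
  lab <- labelingFromComposition(comp, sizes = c(10, 10))
  z <- zscoreProfile(lab)
  expect_equal(unname(z[, "A"]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(unname(colMeans(z)), c(0, 0))
  expect_equal(unname(apply(z, 2, sd)), c(1, 1))

  # random fixture equals direct recomputation
  withr::with_seed(12, {
    comp2 <- matrix(runif(6 * 3), 6, 3)
    comp2 <- sweep(comp2, 1, rowSums(comp2), "/")
    colnames(comp2) <- c("A", "B", "C")
  })
  lab2 <- labelingFromComposition(comp2, sizes = rep(20, 6))
  z2 <- zscoreProfile(lab2)
  manual <- apply(typeComposition(lab2), 2,
                  function(v) (v - mean(v)) / sd(v))
  expect_equal(unname(z2), unname(manual), tolerance = 1e-9)

  # zero-variance column -> zeros with a warning
  comp3 <- cbind(A = c(0.5, 0.5), B = c(0.5, 0.5))
  lab3 <- labelingFromComposition(comp3, sizes = c(10, 10))
  expect_warning(z3 <- zscoreProfile(lab3), "zero-variance")
  expect_true(all(z3 == 0))
  expect_error(zscoreProfile(lab), NA)
})
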