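test_that("nearest-target distances honor the 3-4-5 example, the cap and brute force", {
  ct <- toyCells(x = c(0, 3, 30), y = c(0, 4, 40),
                 type = c("DC", "CD8_T", "CD8_T"),
                 palette = c("DC", "CD8_T"))
  res <- minDistance(ct, selectCells(ct, "DC"), selectCells(ct, "CD8_T"),
                     max_dist_px = 800)
  expect_equal(res$records$distance, 5)
  expect_equal(res$records$log2_distance, log2(5))

  # a target just beyond the cap is dropped and flagged
  ct2 <- toyCells(x = c(0, 801), y = 0, type = c("DC", "CD8_T"),
                  palette = c("DC", "CD8_T"))
  r2 <- minDistance(ct2, selectCells(ct2, "DC"),
                    selectCells(ct2, "CD8_T"), max_dist_px = 800)
  expect_false(r2$records$target_found)
  expect_true(is.na(r2$records$distance))
  # ... and at exactly the cap it is kept
  ct3 <- toyCells(x = c(0, 800), y = 0, type = c("DC", "CD8_T"),
                  palette = c("DC", "CD8_T"))
  expect_equal(minDistance(ct3, selectCells(ct3, "DC"),
                           selectCells(ct3, "CD8_T"))$records$distance,
               800)

  # brute force on a random fixture; overlapping source/target sets must
  # never return self-distances
  ctr <- CellTable(randomCells(150, 9, types = c("DC", "CD8_T"),
                               field = 200))
  src <- selectCells(ctr, c("DC", "CD8_T"))  # everyone
  tgt <- selectCells(ctr, "CD8_T")
  got <- minDistance(ctr, src, tgt, max_dist_px = 800)$records
  xy <- spatialCoords(ctr)
  expected <- vapply(which(src), function(i) {
    d <- sqrt((xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2)
    d[!tgt] <- Inf; d[i] <- Inf
    min(d)
  }, 0)
  expect_equal(got$distance, expected, tolerance = 1e-9)
  expect_true(all(got$distance > 0))
  expect_error(minDistance(ctr, rep(FALSE, 150), tgt), "at least one")
})

test_that("planted proximity contrast is detected by the rank-sum test", {
  # high-class sources sit ~20 um from their nearest target, low ~60 um
  withr::with_seed(77, {
    n <- 200
    tgt_x <- runif(n, 0, 4000); tgt_y <- runif(n, 0, 4000)
    ang <- runif(2 * n, 0, 2 * pi)
    off <- c(abs(rnorm(n, 20, 4)), abs(rnorm(n, 60, 4)))
  })
  df <- data.frame(
    cell_id = sprintf("c%04d", seq_len(3 * n)),
    image_id = "img1",
    x = c(tgt_x, rep(tgt_x, 2) + off * cos(ang)),
    y = c(tgt_y, rep(tgt_y, 2) + off * sin(ang)),
    cell_type = c(rep("CD8_T", n), rep("DC", 2 * n)),
    stringsAsFactors = FALSE)
  ct <- CellTable(df)
  cls <- c(rep(NA, n), rep("high", n), rep("low", n))
  res <- minDistance(ct, selectCells(ct, "DC"), selectCells(ct, "CD8_T"),
                     source_class = cls, alternative = "less")
  expect_lt(res$test$p.value, 0.001)
  # the planted means are recovered approximately
  med <- tapply(res$records$distance, res$records$class, median)
  expect_lt(med[["high"]], 30)
  expect_gt(med[["low"]], 45)
})

test_that("cross-section profiles reflect the tissue geometry", {
  tt <- generateTissue(tissueSpec(seed = 4))
  lab <- labelingFromGroundTruth(tt$truth, tt$cells)
  nm <- lab@params$community_names
  cs <- crossSectionProfile(tt$cells, lab, axis = "x", n_bins = 16,
                            range = 400, slab_halfwidth = 40)
  interface <- which(nm == "interface")
  normal <- which(nm == "normal")
  pos <- cs$centers
  # interface community: bimodal, peaks near +/- tumor_radius (240-310 um)
  inner <- abs(pos) < 180; ring <- abs(pos) > 230 & abs(pos) < 330
  expect_gt(mean(cs$counts[interface, ring]),
            5 * mean(cs$counts[interface, inner]))
  # normal community is depleted inside the tumor
  expect_lt(sum(cs$counts[normal, abs(pos) < 180]),
            0.05 * sum(cs$counts[normal, ]))
  # with an infinite slab, bin counts sum to community sizes
  cs_all <- crossSectionProfile(tt$cells, lab, axis = "x", n_bins = 10)
  expect_equal(unname(rowSums(cs_all$counts)),
               as.numeric(communitySizes(lab)))

  # a single cell at the tumor center lands in the middle bin
  one <- toyCells(100, 100, "Tumor", palette = c("Tumor", "X"))
  lab1 <- labelingFromGroundTruth(data.frame(community = "c"), one)
  cs1 <- crossSectionProfile(one, lab1, axis = "x", n_bins = 5)
  expect_equal(unname(cs1$counts[1, ]), c(0, 0, 1, 0, 0))
  # centering falls back to all cells when no tumor type exists
  noT <- toyCells(c(0, 1), c(0, 0), c("X", "X"), palette = c("Tumor", "X"))
  labX <- labelingFromGroundTruth(data.frame(community = c("a", "a")), noT)
  expect_warning(crossSectionProfile(noT, labX, axis = "x", n_bins = 3),
                 "centering on all cells")
})

test_that("pairwise correlations match the closed form and mask constants", {
  comp <- cbind(A = c(0.1, 0.2, 0.3, 0.4, 0.5),
                B = c(0.2, 0.4, 0.6, 0.8, 1.0),      # perfectly tied to A
                C = c(0.5, 0.1, 0.4, 0.2, 0.3),
                D = rep(0.25, 5))                     # constant
  expect_warning(pc <- pairwiseCorrelation(comp), "zero-variance")
  expect_equal(pc$r["A", "B"], 1.0)
  expect_true(is.na(pc$r["A", "D"]))
  # closed form: r via product-moment formula, p via the t transform
  r_manual <- sum(scale(comp[, "A"]) * scale(comp[, "C"])) / 4
  expect_equal(pc$r["A", "C"], r_manual, tolerance = 1e-12)
  tstat <- r_manual * sqrt(3 / (1 - r_manual^2))
  expect_equal(pc$p["A", "C"], 2 * pt(-abs(tstat), df = 3),
               tolerance = 1e-12)
  expect_equal(pc$tiers["A", "B"], "***")
  expect_error(pairwiseCorrelation(comp[1:2, ]), "at least 3")
})

test_that("ROI clustering separates treatment arms and matches the oracle", {
  # identical ROIs merge first, at height zero
  m <- rbind(r1 = c(0.5, 0.5, 0), r2 = c(0.5, 0.5, 0), r3 = c(0, 0, 1))
  cl <- clusterROIs(m)
  expect_equal(cl$row_hclust$height[1], 0)

  # arm-specific community frequencies split at the top level
  withr::with_seed(41, {
    arm <- rep(c("vehicle", "treated"), each = 4)
    base <- rbind(c(0.6, 0.3, 0.1), c(0.2, 0.3, 0.5))[(arm == "treated") + 1, ]
    mat <- base + matrix(runif(24, 0, 0.05), 8, 3)
  })
  rownames(mat) <- paste0(arm, 1:8)
  cl2 <- clusterROIs(mat)
  expect_equal(ariScore(cutree(cl2$row_hclust, 2), arm), 1.0)

  # merge sequence equals brute-force average linkage on 6 ROIs
  withr::with_seed(15, m6 <- matrix(runif(18), 6, 3))
  cl3 <- clusterROIs(m6)
  oracle <- bruteAverageLinkage(m6)
  for (s in 1:5)
    expect_equal(ariScore(cutree(cl3$row_hclust, 6 - s), oracle[[s]]), 1.0)
})

test_that("density and co-occurrence arithmetic is exact", {
  df <- randomCells(100, 3, types = c("A", "B"))
  ct <- CellTable(df)
  lab <- labelingFromGroundTruth(
    data.frame(community = rep("c1", 100)), ct)
  d <- as.data.frame(communityDensity(ct, lab, areas = c(img1 = 2)))
  expect_equal(d$density, 50)
  expect_true(d$present)  # 50 >= 25

  # the presence boundary is inclusive at exactly 25 cells/mm^2
  d25 <- as.data.frame(communityDensity(ct, lab, areas = c(img1 = 4)))
  expect_equal(d25$density, 25)
  expect_true(d25$present)
  d24 <- as.data.frame(communityDensity(ct, lab, areas = c(img1 = 4.01)))
  expect_false(d24$present)
  expect_error(communityDensity(ct, lab, areas = c(img1 = 0)), "positive")

  # co-occurrence over a 4-image truth table: both / one / one / neither
  rec <- S4Vectors::DataFrame(
    image_id = rep(sprintf("i%d", 1:4), each = 2),
    community = rep(1:2, 4),
    present = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  co <- coOccurrence(rec, 1, 2)
  expect_equal(co$fraction, 0.25)
  expect_equal(co$n_both, 1)

  # default area: convex hull of a 1000 x 1000 um grid is 1 mm^2
  gx <- expand.grid(x = seq(0, 1000, 100), y = seq(0, 1000, 100))
  ctg <- toyCells(gx$x, gx$y, rep(c("A", "B"), length.out = nrow(gx)))
  labg <- labelingFromGroundTruth(
    data.frame(community = rep("c", nrow(gx))), ctg)
  dg <- as.data.frame(communityDensity(ctg, labg))
  expect_equal(dg$area_mm2, 1)
  expect_equal(dg$density, nrow(gx))
})

test_that("covariate correlation is exact on ranks and flags constants", {
  x <- c(10, 20, 30, 40, 50, 60)
  expect_equal(covariateCorrelation(x, x^2)$rho, 1.0)
  expect_equal(covariateCorrelation(x, -x)$rho, -1.0)
  withr::with_seed(2, y <- runif(6))
  got <- covariateCorrelation(x, y)
  expect_equal(got$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_warning(res <- covariateCorrelation(rep(1, 5), 1:5), "constant")
  expect_true(is.na(res$rho))
  expect_error(covariateCorrelation(1:3, 1:3), "at least 4")
})

test_that("per-community correlation finds hub-restricted co-occurrence that per-ROI misses", {
  # CD8 T cells and CD103+ DCs co-localize only inside the planted T/DC
  # hubs; with few ROIs the ROI-level composition barely varies, while
  # community-level composition exposes the pair
  reps <- 8
  hits <- 0
  for (r in seq_len(reps)) {
    spec <- tissueSpec(seed = 400 + r)
    cohort <- generateCohort(spec, 4)
    cells <- combineCellTables(lapply(cohort, `[[`, "cells"))
    truth <- do.call(rbind, lapply(cohort, `[[`, "truth"))
    lab <- labelingFromGroundTruth(truth, cells)
    commComp <- typeComposition(lab)
    img <- imageIds(cells)
    roiComp <- unclass(table(img, cellTypes(cells)))
    roiComp <- sweep(roiComp, 1, rowSums(roiComp), "/")
    p_comm <- suppressWarnings(
      stats::cor.test(commComp[, "CD8_T"], commComp[, "CD103_DC"]))$p.value
    p_roi <- suppressWarnings(
      stats::cor.test(roiComp[, "CD8_T"], roiComp[, "CD103_DC"]))$p.value
    if (p_comm < 0.05 && p_roi > 0.05) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.8)
})
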