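# toy image: 2 CD8 and 2 DC in mutual contact, 8 tumor cells isolated
# from them and from each other
enrichmentToy <- function() {
  far <- cbind(x = rep(c(200, 240, 280, 320), 2),
               y = rep(c(200, 260), each = 4))
  toyCells(x = c(0, 0, 8, 8, far[, "x"]),
           y = c(0, 8, 0, 8, far[, "y"]),
           type = c("CD8_T", "CD8_T", "DC", "DC", rep("Tumor", 8)),
           palette = c("CD8_T", "DC", "Tumor"))
}

# the enrichment statistic, recomputed directly from an edge list
meanNeighborCount <- function(lab, from, to, focal, target) {
  f <- which(lab == focal)
  if (length(f) == 0) return(0)
  sum(lab[from] == focal & lab[to] == target) / length(f)
}

test_that("Monte-Carlo p-values match exhaustive permutation enumeration", {
  ct <- enrichmentToy()
  g <- buildNeighborGraph(ct, 15)
  e <- edgeMatrix(g)
  from <- c(e[, 1], e[, 2]); to <- c(e[, 2], e[, 1])
  lab0 <- as.character(cellTypes(ct))

  # every distinct assignment of the label multiset, equally weighted
  stats_enum <- list(DC = c(), Tumor = c())
  for (cd8 in asplit(utils::combn(12, 2), 2)) {
    rest <- setdiff(1:12, cd8)
    for (dc in asplit(utils::combn(rest, 2), 2)) {
      lab <- rep("Tumor", 12); lab[cd8] <- "CD8_T"; lab[dc] <- "DC"
      for (t in names(stats_enum))
        stats_enum[[t]] <- c(stats_enum[[t]],
                             meanNeighborCount(lab, from, to, "CD8_T", t))
    }
  }
  res <- permutationEnrichment(ct, g, "CD8_T", n_perm = 10000, seed = 3)
  res <- as.data.frame(res)
  for (t in c("DC", "Tumor")) {
    obs <- meanNeighborCount(lab0, from, to, "CD8_T", t)
    row <- res[res$neighbor_type == t, ]
    expect_equal(row$observed, obs)
    expect_lt(abs(row$p_enrich - mean(stats_enum[[t]] >= obs - 1e-12)),
              0.02)
    expect_lt(abs(row$p_deplete - mean(stats_enum[[t]] <= obs + 1e-12)),
              0.02)
  }
  # p-values respect the add-one floor and the significance rule
  expect_true(all(res$p_enrich >= 1 / 10001 & res$p_enrich <= 1))
  expect_equal(res$significant,
               pmin(res$p_enrich, res$p_deplete) <= 0.01)
})

test_that("a single-type community yields null enrichment", {
  ct <- toyCells(x = c(0, 5, 10, 100), y = 0,
                 type = rep("Tumor", 4), palette = c("Tumor", "CD8_T"))
  g <- buildNeighborGraph(ct, 15)
  res <- as.data.frame(
    suppressWarnings(permutationEnrichment(ct, g, "Tumor", n_perm = 200,
                                           seed = 1)))
  expect_equal(res$log2fc, rep(0, 2))
  expect_equal(res$p_enrich, rep(1, 2))
  expect_equal(res$p_deplete, rep(1, 2))
})

test_that("type-I error is controlled under exchangeable labels", {
  palette <- c("CD8_T", "DC", "Tumor", "Treg", "Mac", "NK", "B", "Fib",
               "Endo", "Neut", "CD4_T", "Epi", "M2", "CD103_DC")
  dfs <- lapply(1:40, function(i) {
    df <- randomCells(60, seed = 1000 + i, types = palette, field = 100)
    df$image_id <- sprintf("img%02d", i)
    # guarantee focal cells, otherwise labels are exchangeable by design
    df$cell_type[1:5] <- "CD8_T"
    df
  })
  ct <- CellTable(do.call(rbind, dfs), palette = palette)
  g <- buildNeighborGraph(ct, 15)
  res <- as.data.frame(permutationEnrichment(ct, g, "CD8_T",
                                             n_perm = 499, seed = 17))
  expect_gte(nrow(res), 500)
  expect_lte(mean(res$p_enrich <= 0.01), 0.03)
  expect_lte(mean(res$significant), 0.03 + 2 * sqrt(0.02 / nrow(res)))
})

test_that("conditional split stratifies by conditioning-type adjacency", {
  ct <- toyCells(x = c(0, 10, 100, 110, 300), y = 0,
                 type = c("CD8_T", "Treg", "CD8_T", "DC", "Treg"),
                 palette = c("CD8_T", "Treg", "DC"))
  g <- buildNeighborGraph(ct, 15)
  s <- conditionalSplit(ct, g, "Treg")
  expect_equal(as.character(s),
               c("with", "without", "without", "without", "without"))
  expect_error(conditionalSplit(ct, g, "Foo"), "not in palette")

  # stratified enrichment reports both strata and holds Tregs fixed
  res <- as.data.frame(permutationEnrichment(ct, g, "CD8_T",
                                             n_perm = 100, seed = 2,
                                             conditioning_type = "Treg"))
  expect_setequal(unique(res$stratum), c("with", "without"))
  expect_equal(res$observed[res$stratum == "without" &
                              res$neighbor_type == "DC"], 1)
})

test_that("images without focal cells are skipped with a warning", {
  df1 <- randomCells(30, 5, types = c("Tumor", "DC"), field = 60)
  df2 <- randomCells(30, 6, types = c("Tumor", "CD8_T"), field = 60)
  df2$image_id <- "img2"; df2$cell_id <- paste0("b", df2$cell_id)
  ct <- CellTable(rbind(df1, df2),
                  palette = c("Tumor", "DC", "CD8_T"))
  g <- buildNeighborGraph(ct, 15)
  expect_warning(res <- permutationEnrichment(ct, g, "CD8_T",
                                              n_perm = 100, seed = 1),
                 "no focal cells")
  expect_equal(unique(as.data.frame(res)$image_id), "img2")
})

test_that("statistics are invariant to input row order", {
  ct <- enrichmentToy()
  df <- as.data.frame(ct)
  perm <- withr::with_seed(13, sample(nrow(df)))
  ct2 <- CellTable(df[perm, ], palette = cellTypePalette(ct))
  run <- function(x) {
    r <- as.data.frame(permutationEnrichment(
      x, buildNeighborGraph(x, 15), "CD8_T", n_perm = 2000, seed = 5))
    r[order(r$neighbor_type), ]
  }
  a <- run(ct); b <- run(ct2)
  expect_equal(a$observed, b$observed)
  expect_equal(a$n_focal, b$n_focal)
  expect_lt(max(abs(a$p_enrich - b$p_enrich)), 0.03)
})

test_that("interaction counts follow the worked arithmetic and flag zero prevalence", {
  # 1 CD8 with 2 marker-positive tumor neighbors; 10 tumor cells, 4 positive
  tx <- c(5, 0, 8, 12, 200, 210, 220, 230, 240, 250)
  ty <- c(0, 5, 8, -9, 0, 0, 0, 0, 0, 0)
  cas <- c(1, 1, 0.2, 0.1, 1, 1, 0.1, 0.1, 0.2, 0)
  ct <- toyCells(x = c(0, tx), y = c(0, ty),
                 type = c("CD8_T", rep("Tumor", 10)),
                 palette = c("CD8_T", "Tumor"),
                 cCasp3 = c(0, cas))
  g <- buildNeighborGraph(ct, 15)
  res <- as.data.frame(interactionCount(ct, g, "CD8_T", "Tumor", "cCasp3",
                                        expr_threshold = 0.5))
  expect_equal(res$mean_count, 2)
  expect_equal(res$normalizer, 0.4)
  expect_equal(res$relative_count, 5.0)
  expect_false(res$undefined)

  # no positive target cells anywhere -> flagged undefined
  ct0 <- toyCells(x = c(0, 5), y = 0, type = c("CD8_T", "Tumor"),
                  palette = c("CD8_T", "Tumor"), cCasp3 = c(0, 0.1))
  res0 <- as.data.frame(interactionCount(ct0, buildNeighborGraph(ct0, 15),
                                         "CD8_T", "Tumor", "cCasp3"))
  expect_true(res0$undefined)
  expect_true(is.na(res0$relative_count))
  expect_error(interactionCount(ct0, g, "CD8_T", "Tumor", "nope"),
               "marker")

  # brute-force recount on a random fixture
  df <- randomCells(200, 33, types = c("CD8_T", "Tumor", "DC"),
                    field = 120, markers = "cCasp3")
  ctr <- CellTable(df)
  gr <- buildNeighborGraph(ctr, 15)
  got <- as.data.frame(interactionCount(ctr, gr, "CD8_T", "Tumor",
                                        "cCasp3", 0.5))
  xy <- spatialCoords(ctr)
  pos <- as.character(cellTypes(ctr)) == "Tumor" &
    intensities(ctr)["cCasp3", ] > 0.5
  focal <- which(as.character(cellTypes(ctr)) == "CD8_T")
  cnt <- vapply(focal, function(i) {
    d <- sqrt((xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2)
    sum(pos & d <= 15 & seq_len(nrow(xy)) != i)
  }, 0)
  expect_equal(got$mean_count, mean(cnt))
  expect_equal(got$normalizer,
               mean(intensities(ctr)["cCasp3",
                                     cellTypes(ctr) == "Tumor"] > 0.5))
})
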