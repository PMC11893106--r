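makeCommToy <- function(n_per = 20, seed = 2) {
  set.seed(seed)
  cells <- sprintf("c%03d", 1:(3 * n_per))
  clusters <- rep(c("supporting", "germ", "other"), each = n_per)
  names(clusters) <- cells
  genes <- c("Lig", "RecA", "RecB", "Flat1", "Flat2", "Rare")
  m <- matrix(stats::rexp(length(genes) * length(cells), 1),
              length(genes), length(cells),
              dimnames = list(genes, cells))
  m["Lig", ] <- 0.01
  m["Lig", clusters == "supporting"] <- 5 + stats::rexp(n_per)
  m["Rare", ] <- 0
  m["Rare", sample(which(clusters == "supporting"), 1)] <- 3  # 5% of sender
  list(m = m, clusters = clusters)
}

test_that("complex expression uses the minimum-subunit rule and gates on fraction", {
  toy <- makeCommToy()
  pair <- data.frame(pair_id = "L_RARB", ligand = "Lig",
                     receptor = "RecA;RecB", pathway_label = "toy")
  res <- lrMean(toy$m, toy$clusters, pair, "supporting", "germ")
  germ <- toy$clusters == "germ"; supp <- toy$clusters == "supporting"
  expected <- (mean(toy$m["Lig", supp]) +
                 min(mean(toy$m["RecA", germ]), mean(toy$m["RecB", germ]))) / 2
  expect_equal(res$mean_expr, expected)
  # single-subunit arithmetic: cluster means 2 and 4 -> 3
  m2 <- matrix(c(2, 4), 2, 10, byrow = FALSE,
               dimnames = list(c("L", "R"), sprintf("c%02d", 1:10)))
  m2["L", ] <- 2; m2["R", ] <- 4
  cl2 <- stats::setNames(rep(c("s", "g"), each = 5), colnames(m2))
  p2 <- data.frame(pair_id = "LR", ligand = "L", receptor = "R",
                   pathway_label = "x")
  expect_equal(lrMean(m2, cl2, p2, "s", "g")$mean_expr, 3)
  # ligand expressed in 5% of sender cells: excluded at min_frac 0.10
  p3 <- data.frame(pair_id = "RARE", ligand = "Rare", receptor = "RecA",
                   pathway_label = "x")
  res3 <- lrMean(toy$m, toy$clusters, p3, "supporting", "germ")
  expect_true(res3$excluded)
  expect_equal(res3$reason, "below min_frac")
  # missing gene
  p4 <- data.frame(pair_id = "MISS", ligand = "NotHere", receptor = "RecA",
                   pathway_label = "x")
  expect_equal(lrMean(toy$m, toy$clusters, p4, "supporting", "germ")$reason,
               "missing gene")
})

test_that("permutation p uses the add-one rule and detects planted signal", {
  toy <- makeCommToy()
  pairs <- data.frame(pair_id = c("PLANTED", "FLAT"),
                      ligand = c("Lig", "Flat1"),
                      receptor = c("RecA", "Flat2"),
                      pathway_label = c("sig", "null"))
  res <- lrPermutationTest(toy$m, toy$clusters, pairs, "supporting", "germ",
                           n_perm = 200, seed = 1)
  # planted ligand is maximal in the true labeling: p at the add-one floor
  expect_equal(res$p_value[res$pair_id == "PLANTED"], 1 / 201)
  expect_true(res$significant[res$pair_id == "PLANTED"])
  expect_gt(res$p_value[res$pair_id == "FLAT"], 0.05)
  expect_true(all(res$p_value >= 1 / 201, na.rm = TRUE))
  expect_error(lrPermutationTest(toy$m, rep("one", ncol(toy$m)), pairs,
                                 "one", "one"), "two clusters")
})

test_that("permutation screen is calibrated on null pairs", {
  set.seed(9)
  n <- 120
  cells <- sprintf("c%03d", 1:n)
  clusters <- stats::setNames(rep(c("supporting", "germ", "other"),
                                  length.out = n), cells)
  genes <- sprintf("g%02d", 1:40)
  m <- matrix(stats::rexp(length(genes) * n, 1), length(genes), n,
              dimnames = list(genes, cells))
  pairs <- data.frame(pair_id = sprintf("pair%02d", 1:20),
                      ligand = genes[1:20], receptor = genes[21:40],
                      pathway_label = "null")
  res <- lrPermutationTest(m, clusters, pairs, "supporting", "germ",
                           n_perm = 400, seed = 3)
  frac <- mean(res$significant[!res$excluded])
  se <- sqrt(0.05 * 0.95 / sum(!res$excluded))
  expect_lte(frac, 0.05 + 2 * se + 1e-12)
})

test_that("small clusters exclude pairs with a warning", {
  toy <- makeCommToy(n_per = 2)
  pairs <- data.frame(pair_id = "P", ligand = "Lig", receptor = "RecA",
                      pathway_label = "x")
  expect_warning(
    res <- lrPermutationTest(toy$m, toy$clusters, pairs, "supporting", "germ",
                             n_perm = 50),
    "fewer than 3")
  expect_true(all(res$excluded))
})

test_that("interaction counting and cross-sex overlap partition", {
  mk <- function(ids, sig) data.frame(pair_id = ids, pathway_label = "w",
                                      significant = ids %in% sig)
  results <- list(
    "XX.E13.5" = mk(c("a", "b", "c", "d"), c("a", "b", "c")),
    "XY.E13.5" = mk(c("a", "b", "c", "d"), c("b", "d")))
  out <- countAndOverlap(results)
  expect_equal(unname(out$counts_per_group), c(3L, 2L))
  ov <- out$overlaps[["E13.5"]]
  expect_equal(ov$xx_only, c("a", "c"))
  expect_equal(ov$shared, "b")
  expect_equal(ov$xy_only, "d")
  # identical tables: all shared
  out2 <- countAndOverlap(list("XX.E12.5" = mk(letters[1:3], letters[1:2]),
                               "XY.E12.5" = mk(letters[1:3], letters[1:2])))
  expect_equal(out2$overlaps[["E12.5"]]$shared, c("a", "b"))
  expect_length(out2$overlaps[["E12.5"]]$xx_only, 0)
  # nothing significant: zero counts, empty overlaps
  out0 <- countAndOverlap(list("XX.E11.5" = mk("a", character(0)),
                               "XY.E11.5" = mk("a", character(0))))
  expect_equal(unname(out0$counts_per_group), c(0L, 0L))
  expect_length(out0$overlaps[["E11.5"]]$shared, 0)
})

test_that("observed statistics are invariant to global cell reordering", {
  toy <- makeCommToy()
  pairs <- data.frame(pair_id = "PLANTED", ligand = "Lig", receptor = "RecA",
                      pathway_label = "sig")
  perm <- sample(ncol(toy$m))
  r1 <- lrPermutationTest(toy$m, toy$clusters, pairs, "supporting", "germ",
                          n_perm = 200, seed = 1)
  r2 <- lrPermutationTest(toy$m[, perm], toy$clusters[perm], pairs,
                          "supporting", "germ", n_perm = 200, seed = 1)
  expect_equal(r1$mean_expr, r2$mean_expr)
  expect_equal(r1$excluded, r2$excluded)
  expect_equal(r1$significant, r2$significant)
})
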