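test_that("candidate pairs respect the window boundary and chromosome", {
  pr <- GenomicRanges::GRanges(c("chr1", "chr1", "chr2"),
                               IRanges::IRanges(start = c(599751, 700001, 99751),
                                                width = 500))
  names(pr) <- c("pA", "pB", "pC")  # midpoints 600000, 700250, 100000
  gm <- data.frame(gene_id = c("g1", "g2"), chrom = c("chr1", "chr2"),
                   tss = c(100000L, 100000L), strand = c("+", "-"))
  cp <- candidatePairs(pr, gm, window_bp = 5e5)
  key <- paste(cp$peak_id, cp$gene_id)
  expect_true("pA g1" %in% key)       # exactly at the 500 kb boundary
  expect_false("pB g1" %in% key)      # beyond the window
  expect_false("pA g2" %in% key)      # different chromosome
  expect_true("pC g2" %in% key)
  expect_equal(cp$distance[key == "pA g1"], 500000)
  expect_equal(cp$distance[key == "pC g2"], 0)
  gm$tss[2] <- NA
  expect_warning(candidatePairs(pr, gm), "without TSS")
})

test_that("background matching equals brute-force nearest neighbors", {
  set.seed(9)
  feats <- data.frame(gc_fraction = runif(10), mean_accessibility = runif(10),
                      width = runif(10, 200, 800),
                      row.names = sprintf("p%02d", 1:10))
  bg <- matchBackgroundPeaks(feats, n_background = 4)
  z <- scale(as.matrix(feats))
  for (q in rownames(feats)) {
    d <- colSums((t(z) - z[q, ])^2)
    d[q] <- Inf
    expected <- names(sort(d))[1:4]
    expect_setequal(bg[q, ], expected)
    # the nearest neighbor is always included
    expect_true(names(which.min(d)) %in% bg[q, ])
  }
  # all-identical features: ties broken by id order, query excluded
  feats2 <- data.frame(gc_fraction = rep(0.5, 6),
                       mean_accessibility = rep(1, 6), width = rep(500, 6),
                       row.names = sprintf("p%02d", 1:6))
  bg2 <- matchBackgroundPeaks(feats2, n_background = 3)
  expect_equal(unname(bg2["p01", ]), c("p02", "p03", "p04"))
  expect_equal(unname(bg2["p03", ]), c("p01", "p02", "p04"))
  expect_warning(matchBackgroundPeaks(feats2, n_background = 10), "fewer")
})

test_that("matched backgrounds are closer in GC than random sets", {
  sim <- tinySim()
  feats <- linkFeatures(sim$dataset)
  qs <- rownames(feats)[seq(1, 400, by = 20)]
  bg <- matchBackgroundPeaks(feats, query = qs, n_background = 30)
  set.seed(4)
  gc <- feats$gc_fraction
  names(gc) <- rownames(feats)
  d_match <- mean(vapply(qs, function(q) mean(abs(gc[q] - gc[bg[q, ]])), 0))
  d_rand <- mean(vapply(qs, function(q)
    mean(abs(gc[q] - gc[sample(setdiff(names(gc), q), 30)])), 0))
  expect_lte(d_match, d_rand)
})

test_that("link acceptance: perfect coupling accepted, degenerate null dropped", {
  set.seed(21)
  n_cells <- 50
  cells <- sprintf("c%02d", 1:n_cells)
  # 12 peaks: p01 mirrors the gene exactly; others independent noise
  atac <- matrix(rnorm(12 * n_cells), 12, n_cells,
                 dimnames = list(sprintf("p%02d", 1:12), cells))
  gene <- atac[1, , drop = FALSE]
  rownames(gene) <- "g1"
  feats <- data.frame(gc_fraction = runif(12), mean_accessibility = 1,
                      width = 500, row.names = rownames(atac))
  pairs <- data.frame(peak_id = "p01", gene_id = "g1", distance = 0)
  lk <- linkPeaks(atac, gene, pairs, feats, n_background = 8)
  expect_equal(lk$r, 1)
  expect_true(lk$z > 0 && lk$accepted)
  # a constant peak is dropped with a zero-variance reason
  atac2 <- atac; atac2["p01", ] <- 5
  lk2 <- linkPeaks(atac2, gene, pairs, feats, n_background = 8)
  expect_equal(nrow(lk2), 0)
  expect_equal(attr(lk2, "dropped")$reason, "zero variance")
  # identical background peaks give sd(null) = 0 -> degenerate null
  atac3 <- atac
  for (i in 2:12) atac3[i, ] <- atac[2, ]
  lk3 <- linkPeaks(atac3, gene, pairs, feats, n_background = 8)
  expect_equal(nrow(lk3), 0)
  expect_equal(attr(lk3, "dropped")$reason, "degenerate null")
})

test_that("link z is invariant to affine rescaling of accessibility", {
  set.seed(22)
  n_cells <- 40
  cells <- sprintf("c%02d", 1:n_cells)
  atac <- matrix(rnorm(15 * n_cells), 15, n_cells,
                 dimnames = list(sprintf("p%02d", 1:15), cells))
  gene <- matrix(atac[1, ] + rnorm(n_cells, 0, 0.8), 1,
                 dimnames = list("g1", cells))
  feats <- data.frame(gc_fraction = runif(15), mean_accessibility = 1,
                      width = 500, row.names = rownames(atac))
  pairs <- data.frame(peak_id = "p01", gene_id = "g1", distance = 0)
  lk <- linkPeaks(atac, gene, pairs, feats, n_background = 10)
  lk_scaled <- linkPeaks(atac * 3.7 + 2, gene, pairs, feats, n_background = 10)
  expect_equal(lk$z, lk_scaled$z, tolerance = 1e-10)
  expect_equal(lk$r, lk_scaled$r, tolerance = 1e-10)
})

test_that("peak annotation follows the fixed priority on a hand-drawn model", {
  gene_model <- GenomicRanges::GRanges(
    rep("chr1", 5),
    IRanges::IRanges(start = c(10000, 10000, 10150, 29800, 29950),
                     end = c(30000, 10100, 10300, 29900, 30000)),
    strand = c("+", "+", "+", "+", "+"),
    type = c("gene", "utr5", "exon", "exon", "utr3"))
  peaks <- GenomicRanges::GRanges(
    rep("chr1", 6),
    IRanges::IRanges(start = c(9500, 10050, 15000, 29850, 31000, 300000),
                     width = 100))
  names(peaks) <- paste0("pk", 1:6)
  ann <- annotatePeaks(peaks, gene_model, tss_region = 3000)$annotation
  cat_of <- stats::setNames(ann$category, ann$peak_id)
  expect_equal(unname(cat_of["pk1"]), "promoter")   # spans TSS-3kb window
  expect_equal(unname(cat_of["pk2"]), "promoter")   # TSS+3kb beats UTR
  expect_equal(unname(cat_of["pk3"]), "intron")     # gene body, no exon
  expect_equal(unname(cat_of["pk4"]), "exon")       # exon beats intron
  expect_equal(unname(cat_of["pk5"]), "downstream") # within 3 kb of gene end
  expect_equal(unname(cat_of["pk6"]), "distal_intergenic")
  pct <- annotatePeaks(peaks, gene_model)$percentages
  expect_equal(sum(pct), 100)
  # empty model: everything distal
  ann0 <- annotatePeaks(peaks, gene_model[0])$annotation
  expect_true(all(ann0$category == "distal_intergenic"))
})
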