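# hand-built dataset: 3 genes (one mitochondrial), 2 peaks, custom fragments
handDataset <- function(frags, rna_counts = NULL) {
  cells <- unique(frags$cell)
  genes <- c("g1", "g2", "mt-x")
  if (is.null(rna_counts))
    rna_counts <- matrix(5, length(genes), length(cells))
  dimnames(rna_counts) <- list(genes, cells)
  atac <- matrix(1, 2, length(cells),
                 dimnames = list(c("p1", "p2"), cells))
  gm <- S4Vectors::DataFrame(
    gene_id = genes, chrom = "chr1", tss = c(5000L, 50000L, 100000L),
    strand = "+", gene_end = c(10000L, 60000L, 101000L),
    is_chrY = FALSE, is_mito = c(FALSE, FALSE, TRUE),
    is_marker_of = NA_character_, row.names = genes)
  cm <- S4Vectors::DataFrame(cell_id = cells, sex = "XX", stage = "E11.5",
                             replicate = "rep1", compartment = "germ",
                             row.names = cells)
  pr <- GenomicRanges::GRanges(c("chr1", "chr1"),
                               IRanges::IRanges(c(4800, 70000), width = 400),
                               gc_fraction = c(0.5, 0.5))
  names(pr) <- c("p1", "p2")
  MultiomeExperiment(rna = rna_counts, atac = atac, colData = cm,
                     geneData = gm, peakRanges = pr, fragments = frags)
}

test_that("nucleosome signal counts mono vs sub-nucleosomal fragments", {
  frags <- data.frame(
    cell = c(rep("c1", 3), rep("c2", 2)),
    chrom = "chr1",
    start = c(1000, 2000, 3000, 1000, 2000),
    end = c(1080, 2100, 3200, 1150, 2200))  # c1: 80,100,200; c2: 150,200
  qc <- computeQC(handDataset(frags))
  expect_equal(qc["c1", "nucleosome_signal"], 1 / 2)
  expect_equal(qc["c2", "nucleosome_signal"], Inf)  # no sub-nucleosomal
  flt <- filterCells(qc, min_count_rna = 0, min_count_atac = 0,
                     min_tss_enrichment = -1)
  expect_false("c2" %in% flt$kept)
})

test_that("TSS enrichment matches a hand computation on placed fragments", {
  # gene g1 TSS at 5000: center [4500,5500), flanks [3500,4500) + [5500,6500)
  frags <- data.frame(
    cell = rep("c1", 4), chrom = "chr1",
    start = c(4950, 5100, 3950, 9000),
    end = c(5050, 5300, 4050, 9100))  # midpoints 5000, 5200, 4000, 9050
  ds <- handDataset(frags)
  qc <- computeQC(ds, tss_flank = 1000)
  # 2 center hits, 1 flank hit: (2/1000) / (1/2000) = 4
  expect_equal(qc["c1", "tss_enrichment"], 4)
  # no flank hit but central hits: +Inf; no hits at all: 0
  frags2 <- data.frame(cell = c("c1", "c2"), chrom = "chr1",
                       start = c(4950, 9000), end = c(5050, 9100))
  qc2 <- computeQC(handDataset(frags2), tss_flank = 1000)
  expect_equal(qc2["c1", "tss_enrichment"], Inf)
  expect_equal(qc2["c2", "tss_enrichment"], 0)
})

test_that("cell filtering uses strict inequalities at printed thresholds", {
  qc <- data.frame(
    cell_id = c("boundary_rna", "good", "boundary_mt", "high_atac"),
    n_count_rna = c(1000, 5000, 5000, 5000),
    percent_mt = c(10, 10, 25, 10),
    n_count_atac = c(20000, 20000, 20000, 100000),
    nucleosome_signal = c(0.8, 0.8, 0.8, 0.8),
    tss_enrichment = c(2, 2, 2, 2))
  flt <- filterCells(qc)
  expect_setequal(flt$kept, "good")
  expect_equal(unname(flt$failures["n_count_rna_low"]), 1L)
  expect_equal(unname(flt$failures["percent_mt"]), 1L)
  expect_equal(unname(flt$failures["n_count_atac_high"]), 1L)
})

test_that("peak filtering: width bounds exclusive, nonstandard contigs dropped", {
  pr <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr1", "chrUn_random", "chr2"),
    IRanges::IRanges(start = 1, width = c(20, 21, 10000, 500, 500)))
  names(pr) <- paste0("p", 1:5)
  flt <- filterPeaks(pr)
  expect_setequal(flt$kept, c("p2", "p5"))
  bl <- GenomicRanges::GRanges("chr2", IRanges::IRanges(100, 200))
  flt2 <- filterPeaks(pr, blacklist = bl)
  expect_setequal(flt2$kept, "p2")
})

test_that("binned module score: self-control zero, determinism, arithmetic", {
  # identical rows: any sampled control equals the set mean -> score 0
  m <- matrix(rep(c(1, 2, 3, 4, 5), each = 3), nrow = 3,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:5)))
  s <- moduleScoreBinned(m, c("g1", "g2"), n_bins = 1, n_ctrl = 10, seed = 1)
  expect_equal(unname(s), rep(0, 5))
  # per-bin constant rows -> control mean is known exactly
  m2 <- rbind(matrix(1, 3, 4), matrix(10, 3, 4))
  rownames(m2) <- paste0("g", 1:6); colnames(m2) <- paste0("c", 1:4)
  s2 <- moduleScoreBinned(m2, c("g4", "g5"), n_bins = 2, n_ctrl = 25, seed = 1)
  expect_equal(unname(s2), rep(0, 4))  # controls come from the value-10 bin
  s3 <- moduleScoreBinned(m2, "g4", n_bins = 1, n_ctrl = 500, seed = 7)
  # controls drawn from both bins; expected control mean between 1 and 10
  expect_true(all(s3 > 0 & s3 < 9))
  expect_identical(moduleScoreBinned(m2, "g4", n_bins = 1, n_ctrl = 50, seed = 5),
                   moduleScoreBinned(m2, "g4", n_bins = 1, n_ctrl = 50, seed = 5))
  expect_error(moduleScoreBinned(m2, character(0)), "non-empty")
})

test_that("binned module score has mean zero over random gene sets", {
  sim <- tinySim()
  norm <- logNormalize(rnaCounts(sim$dataset))
  set.seed(42)
  means <- replicate(200, {
    gs <- sample(rownames(norm), 8)
    mean(moduleScoreBinned(norm, gs, seed = sample.int(1e6, 1)))
  })
  expect_lt(abs(mean(means)), 3 * stats::sd(means) / sqrt(length(means)))
})

test_that("rank module score matches the U-statistic formula", {
  # 6 genes, one cell with distinct values
  m <- matrix(c(6, 5, 4, 3, 2, 1), 6, 1,
              dimnames = list(paste0("g", 1:6), "c1"))
  # set at the top ranks -> score 1
  expect_equal(unname(moduleScoreRank(m, c("g1", "g2"), r_max = 4)), 1)
  # set at ranks 5,6 with r_max 3: clipped to 4 -> U' = 8 - 3 = 5
  expect_equal(unname(moduleScoreRank(m, c("g5", "g6"), r_max = 3)),
               1 - 5 / (2 * 3))
  # hand-assigned mixed ranks 2 and 5 with r_max 6: U' = 7 - 3 = 4
  expect_equal(unname(moduleScoreRank(m, c("g2", "g5"), r_max = 6)),
               1 - 4 / (2 * 6))
  # ties get average ranks
  m2 <- matrix(c(3, 3, 1, 1, 1, 1), 6, 1,
               dimnames = list(paste0("g", 1:6), "c1"))
  # g1,g2 tie at ranks (1,2) -> 1.5 each; U' = 3 - 3 = 0 -> score 1
  expect_equal(unname(moduleScoreRank(m2, c("g1", "g2"), r_max = 4)), 1)
  expect_error(moduleScoreRank(m, character(0)), "non-empty")
  expect_error(moduleScoreRank(m, paste0("g", 1:4), r_max = 3), "r_max")
})

test_that("sex assignment applies the fragment and score rules", {
  # reference stage cells define the thresholds
  cells <- sprintf("c%02d", 1:12)
  scores <- stats::setNames(
    c(0.9, 0.88, 0.92, 0.86,   # XY reference (E13.5)
      0.50, 0.52, 0.48, 0.51,  # XX reference (E13.5)
      0.89, 0.30, 0.51, 0.52), cells)
  frag <- stats::setNames(c(10, 8, 12, 9, 0, 0, 0, 0, 0, 11, 1, 2), cells)
  sex <- c(rep("XY", 4), rep("XX", 4), "XY", "XY", "XX", "XX")
  stage <- c(rep("E13.5", 8), rep("E11.5", 4))
  calls <- assignSex(scores, frag, sex, stage, ref_stage = "E13.5")
  # male cell with zero chrY fragments: removed despite a high score
  expect_equal(calls["c09", "call"], "removed")
  # male cell with fragments but a score far below the male bound: removed
  expect_equal(calls["c10", "call"], "removed")
  # female cell with one chrY fragment is tolerated (> 1 removes)
  expect_equal(calls["c11", "call"], "XX")
  # female cell with two chrY fragments: removed
  expect_equal(calls["c12", "call"], "removed")
  # reference cells mostly survive their own filter
  expect_true(all(calls$call[1:4] %in% c("XY", "removed")))
  expect_error(assignSex(scores[1:3], frag[1:3], sex[1:3], stage[1:3],
                         ref_stage = "E13.5"), "at least 2")
})

test_that("sex assignment on generator output recovers planted sex", {
  sim <- tinySim()
  ds <- sim$dataset
  gm <- geneData(ds)
  norm <- logNormalize(rnaCounts(ds))
  score <- moduleScoreRank(norm, rownames(gm)[gm$is_chrY])
  yfrag <- chrYFragmentCounts(ds)
  cm <- cellData(ds)
  calls <- assignSex(score, yfrag, cm$sex, cm$stage)
  surv <- calls[calls$call != "removed", ]
  truth <- sexOfCell(sim$truth)
  expect_gte(mean(surv$call == truth[surv$cell_id]), 0.99)
  # no surviving XX call carries chrY expression
  chrY_expr <- Matrix::colSums(rnaCounts(ds)[rownames(gm)[gm$is_chrY], ])
  expect_true(all(chrY_expr[surv$cell_id[surv$call == "XX"]] == 0))
})

test_that("marker rules select and exclude cells as specified", {
  rules <- gonadMarkerRules()
  genes <- unique(unlist(lapply(rules, function(r)
    c(r$require_expressed, r$require_absent))))
  m <- matrix(0, length(genes), 3,
              dimnames = list(genes, c("pgc", "doublet", "support")))
  m[c("Ddx4", "Pou5f1"), "pgc"] <- c(3, 2)
  m[c("Ddx4", "Pou5f1", "Sox9"), "doublet"] <- c(3, 2, 2)
  m["Wt1", "support"] <- 4
  pops <- selectPopulation(m, rules)
  expect_equal(pops$PGC, "pgc")
  expect_equal(pops$supporting, "support")
  badrule <- markerRule("x", "NotAGene")
  expect_error(selectPopulation(m, list(badrule)), "unknown gene")
  expect_error(markerRule("x", "Ddx4", "Ddx4"), "disjoint")
  expect_equal(selectPopulation(m, list()), list())
})
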