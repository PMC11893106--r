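test_that("target prediction is the motif-hit / accepted-link intersection", {
  peaks <- sprintf("p%d", 1:8)
  hits <- Matrix::Matrix(matrix(FALSE, 8, 1), sparse = TRUE,
                         dimnames = list(peaks, "m1"))
  hits[c("p1", "p3", "p7"), "m1"] <- TRUE
  links <- data.frame(
    peak_id = c("p1", "p2", "p3", "p4", "p7", "p8"),
    gene_id = c("gA", "gB", "gC", "gD", "gE", "gA"),
    r = 0.5, z = 2, p_value = 0.01,
    accepted = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  deg <- c("gA", "gB", "gC", "gD", "gE")
  res <- predictTargets("m1", hits, links, deg)
  # gA via p1, gC via p3, gE via p7; gD's link is not accepted
  expect_setequal(res$targets, c("gA", "gC", "gE"))
  expect_equal(res$coverage, 3 / 5)
  # provenance witnesses re-validate
  expect_true(all(res$provenance$peak_id %in% peaks[as.vector(hits[, 1])]))
  expect_true(all(paste(res$provenance$peak_id, res$provenance$gene_id) %in%
                    paste(links$peak_id, links$gene_id)[links$accepted]))
  # no hit on any linked peak -> empty targets, coverage 0
  hits0 <- hits; hits0[, 1] <- FALSE
  expect_equal(predictTargets("m1", hits0, links, deg)$coverage, 0)
  # hit on every linked peak -> coverage 1
  hits1 <- hits; hits1[, 1] <- TRUE
  expect_equal(predictTargets("m1", hits1, links, deg)$coverage, 4 / 5)
  # (gD unreachable: its only link is not accepted)
  expect_error(predictTargets("m1", hits, links, character(0)), "empty")
})

test_that("relaxing the link p threshold only grows target sets", {
  sim <- tinySim()
  set.seed(8)
  links <- data.frame(peak_id = sample(sprintf("p%d", 1:30), 60, TRUE),
                      gene_id = sample(sprintf("g%d", 1:15), 60, TRUE),
                      r = runif(60), z = rnorm(60, 1),
                      p_value = runif(60))
  hits <- Matrix::Matrix(matrix(runif(30) < 0.4, 30, 1), sparse = TRUE,
                         dimnames = list(sprintf("p%d", 1:30), "m1"))
  deg <- sprintf("g%d", 1:15)
  prev <- character(0)
  for (thr in c(0.01, 0.05, 0.2, 1)) {
    links$accepted <- links$p_value < thr & links$z > 0
    cur <- predictTargets("m1", hits, links, deg)$targets
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("TF cross-regulation finds planted directed edges and self-edges", {
  peaks <- GenomicRanges::GRanges(rep("chr1", 3),
                                  IRanges::IRanges(c(1000, 50000, 120000),
                                                   width = 500))
  names(peaks) <- c("pk1", "pk2", "pk3")
  gene_meta <- data.frame(gene_id = c("TfA", "TfB"), chrom = "chr1",
                          tss = c(200000L, 1200L))
  # TfA's motif hits pk2, which is link-accepted to TfB's gene;
  # pk1 sits in TfB's promoter but carries no motif
  hits <- Matrix::Matrix(matrix(c(FALSE, TRUE, FALSE,
                                  FALSE, FALSE, FALSE), 3, 2),
                         sparse = TRUE,
                         dimnames = list(names(peaks), c("mA", "mB")))
  links <- data.frame(peak_id = "pk2", gene_id = "TfB", r = 0.6, z = 3,
                      p_value = 0.001, accepted = TRUE)
  tfs <- data.frame(motif_id = c("mA", "mB"), tf_gene = c("TfA", "TfB"))
  out <- tfCrossRegulation(tfs, hits, links, peaks, gene_meta)
  expect_true(out$adjacency["TfA", "TfB"])
  expect_false(out$adjacency["TfB", "TfA"])
  expect_equal(unname(out$self_edges), c(FALSE, FALSE))
  # a motif with no hits anywhere has out-degree 0
  expect_equal(sum(out$adjacency["TfB", ]), 0)
  # promoter route: give TfB's motif a hit in TfA's promoter window
  hits2 <- hits
  peaks2 <- c(peaks, GenomicRanges::GRanges("chr1",
                                            IRanges::IRanges(199000, width = 500)))
  names(peaks2)[4] <- "pk4"
  hits2 <- Matrix::Matrix(rbind(as.matrix(hits2), c(FALSE, TRUE)),
                          sparse = TRUE,
                          dimnames = list(names(peaks2), c("mA", "mB")))
  out2 <- tfCrossRegulation(tfs, hits2, links, peaks2, gene_meta)
  expect_true(out2$adjacency["TfB", "TfA"])
  expect_error(tfCrossRegulation(data.frame(motif_id = "mA", tf_gene = "Nope"),
                                 hits, links, peaks, gene_meta), "absent")
})

test_that("over-representation p equals the exact hypergeometric tail", {
  universe <- sprintf("g%02d", 1:20)
  genes <- sprintf("g%02d", 1:5)
  sets <- list(contained = sprintf("g%02d", c(1:4)),
               disjoint = sprintf("g%02d", 11:15),
               absent = c("x1", "x2"))
  out <- overrepresentation(genes, universe, sets)
  expect_equal(out$p_value[out$set == "contained"], enumHyperP(4, 4, 20, 5))
  expect_equal(out$p_value[out$set == "disjoint"], enumHyperP(0, 5, 20, 5))
  expect_false("absent" %in% out$set)  # zero overlap with universe: skipped
  # query == universe: every set has p = 1
  out2 <- overrepresentation(universe, universe, sets["contained"])
  expect_equal(out2$p_value, 1)
  expect_error(overrepresentation(c("zz"), universe, sets), "subset")
})

test_that("candidate-TF selection is the stated conjunction", {
  de <- data.frame(feature_id = c("TfA", "TfB", "TfC"),
                   log2fc = c(1, 1, -1), significant = c(TRUE, TRUE, TRUE))
  enr <- data.frame(motif_id = c("mA", "mB", "mC", "mD"),
                    p_value = c(1e-6, 1e-4, 0.5, 1e-5),
                    p_adj = c(4e-6, 4e-4, 0.6, 4e-5))
  act <- c(mA = 2.0, mB = -0.5, mC = 1.0, mD = 1.5)
  map <- c(mA = "TfA", mB = "TfB", mC = "TfC", mD = NA)
  out <- selectCandidateTFs(de, enr, act, germline_set = c("TfA", "TfB"), map)
  expect_equal(out$selected[out$motif_id == "mA"], TRUE)
  # negative activity blocks selection despite DE + enrichment
  expect_equal(out$selected[out$motif_id == "mB"], FALSE)
  # wrong DE direction
  expect_equal(out$selected[out$motif_id == "mC"], FALSE)
  # unmapped motif flagged and never selected
  expect_true(out$unmapped[out$motif_id == "mD"])
  expect_false(out$selected[out$motif_id == "mD"])
  # ordered by enrichment p
  expect_equal(out$motif_id, c("mA", "mD", "mB", "mC"))
})

test_that("germline enrichment recovers compartment-restricted genes", {
  set.seed(6)
  n <- 40
  cells <- c(sprintf("germ%02d", 1:n), sprintf("soma%02d", 1:n))
  raw <- matrix(rpois(3 * 2 * n, 4), 3, 2 * n,
                dimnames = list(c("gGerm", "gFlat", "gSoma"), cells))
  raw["gGerm", (n + 1):(2 * n)] <- 0
  raw["gSoma", 1:n] <- 0
  norm <- logNormalize(raw)
  enr <- germlineEnrichment(norm, raw, cells[1:n], cells[(n + 1):(2 * n)])
  expect_true("gGerm" %in% enr)
  expect_false("gSoma" %in% enr)
  expect_false("gFlat" %in% enr)
})
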