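#' Run the full PGC multiome analysis flow
#'
#' Chains the pipeline on a paired multiome dataset: per-cell QC filtering;
#' mitochondrial gene removal; chrY-based sex filtering; marker-rule
#' selection of PGCs and supporting cells; per-sex differential expression
#' at the analysis stage; peak-gene linkage on the stage's PGCs; motif
#' scanning, GC-matched enrichment on peaks linked to sex-enriched DEGs, and
#' per-cell motif activity; candidate-TF selection with target-gene
#' prediction; joint embedding and clustering of PGCs; and the permutation
#' ligand-receptor screen between supporting cells and PGCs of each sex.
#'
#' @param dataset a [MultiomeExperiment-class] with fragments and peak
#'   sequences.
#' @param motifs a [MotifSet-class] (default: the shipped motif models).
#' @param lr_pairs ligand-receptor table (default: the shipped pair list).
#' @param stage analysis stage (default: the last stage present).
#' @param n_perm permutations for the ligand-receptor screen.
#' @param n_background matched background peaks per query.
#' @param weight_rna RNA weight of the joint embedding.
#' @param k_neighbors,resolution clustering parameters.
#' @param seed integer seed controlling every stochastic step.
#' @return list with elements `qc`, `kept_cells`, `sex_calls`,
#'   `populations`, `de` (per sex: XX = XX-enriched), `links`,
#'   `candidate_pairs`, `hits`, `enrichment` (per sex), `deviations`,
#'   `activity`, `germline`, `tf_candidates` (per sex), `tf_targets`
#'   (per selected TF), `clustering`, `lr` (per sex), `stage`.
#' @export
runPGCPipeline <- function(dataset,
                           motifs = readJaspar(system.file("extdata",
                             "motifs_jaspar.txt", package = "pgcMultiome")),
                           lr_pairs = shippedLRPairs(),
                           stage = NULL, n_perm = 1000, n_background = 200,
                           weight_rna = 0.5, k_neighbors = 20,
                           resolution = 0.3, seed = 1L) {
  ## QC filtering
  qc <- computeQC(dataset)
  flt <- filterCells(qc)
  ds <- subsetCells(dataset, flt$kept)
  gm <- geneData(ds)
  cm <- cellData(ds)
  if (is.null(stage)) stage <- max(sort(unique(cm$stage)))

  ## chrY sex filtering
  chrY_genes <- rownames(gm)[isTRUE_vec(gm$is_chrY)]
  norm_all <- logNormalize(rnaCounts(ds))
  score <- moduleScoreRank(norm_all, chrY_genes)
  yfrag <- chrYFragmentCounts(ds)
  sex_calls <- assignSex(score, yfrag, cm$sex, cm$stage)
  kept <- sex_calls$cell_id[sex_calls$call != "removed"]
  ds <- subsetCells(ds, kept)
  cm <- cellData(ds)

  ## mitochondrial genes removed from the RNA matrix after QC
  keep_genes <- rownames(gm)[!isTRUE_vec(gm$is_mito)]
  raw <- rnaCounts(ds)[keep_genes, , drop = FALSE]
  norm <- logNormalize(raw)

  ## populations
  pops <- selectPopulation(raw, gonadMarkerRules())
  pgc <- pops$PGC
  cl_labels <- ifelse(kept %in% pgc, "germ",
                      ifelse(kept %in% pops$supporting, "supporting",
                             "other-soma"))
  names(cl_labels) <- kept

  ## per-sex differential expression at the analysis stage (PGCs)
  g_xx <- pgc[cm[pgc, "sex"] == "XX" & cm[pgc, "stage"] == stage]
  g_xy <- pgc[cm[pgc, "sex"] == "XY" & cm[pgc, "stage"] == stage]
  de <- findMarkers(norm, raw, g_xx, g_xy)
  degs <- list(XX = de$feature_id[de$significant & de$log2fc > 0],
               XY = de$feature_id[de$significant & de$log2fc < 0])

  ## peak-gene links on the stage's PGCs
  pk <- filterPeaks(peakRanges(ds))
  peaks <- peakRanges(ds)[pk$kept]
  pgc_stage <- c(g_xx, g_xy)
  pairs <- candidatePairs(peaks, gm[keep_genes, ])
  feats <- linkFeatures(ds)[pk$kept, ]
  atac_n <- logNormalize(atacCounts(ds)[pk$kept, pgc_stage, drop = FALSE])
  links <- linkPeaks(atac_n, norm[, pgc_stage, drop = FALSE], pairs, feats,
                     n_background = n_background, seed = seed)
  acc <- links[links$accepted, , drop = FALSE]

  ## motifs: scan, enrichment on peaks linked to each sex's DEGs, activity
  hits <- scanPeaks(peakSequences(ds)[pk$kept], motifs)
  enrichment <- lapply(degs, function(dg) {
    q <- unique(acc$peak_id[acc$gene_id %in% dg])
    if (length(q) < 2) return(NULL)
    motifEnrichment(q, pooledBackground(feats, q, n_background, seed), hits)
  })
  dev <- chromvarDeviations(atacCounts(ds)[pk$kept, , drop = FALSE], hits,
                            feats, n_background = n_background, seed = seed)
  grp <- ifelse(kept %in% pgc, paste(cm$sex, cm$stage), "soma")
  activity <- motifActivity(dev, grp)

  ## germline enrichment and candidate TFs
  germline <- germlineEnrichment(norm, raw, pgc, setdiff(kept, pgc))
  motif_tf <- motifTfGene(names(motifs))
  tf_candidates <- list()
  for (sx in c("XX", "XY")) {
    if (is.null(enrichment[[sx]])) next
    de_sx <- de
    if (sx == "XY") de_sx$log2fc <- -de_sx$log2fc  # enrichment toward XY
    tf_candidates[[sx]] <- selectCandidateTFs(
      de_sx, enrichment[[sx]], activity[, paste(sx, stage)], germline,
      motif_tf)
  }

  ## predicted targets of selected TFs
  tf_targets <- list()
  for (sx in names(tf_candidates)) {
    cand <- tf_candidates[[sx]]
    deg_linked <- intersect(degs[[sx]], unique(acc$gene_id))
    if (!length(deg_linked)) next
    for (mid in cand$motif_id[cand$selected])
      tf_targets[[mid]] <- predictTargets(mid, hits, links, deg_linked)
  }

  ## joint embedding and clustering of PGCs
  clustering <- NULL
  if (length(pgc) > k_neighbors + 1) {
    emb_r <- pcaEmbed(norm[, pgc, drop = FALSE], seed = seed)
    emb_a <- tfidfLSI(atacCounts(ds)[pk$kept, pgc, drop = FALSE], seed = seed)
    emb_j <- jointEmbedding(emb_r, emb_a, weight_rna)
    clustering <- clusterGraph(emb_j, k_neighbors, resolution, seed)
  }

  ## ligand-receptor screen per sex at the analysis stage
  lr <- list()
  for (sx in c("XX", "XY")) {
    cells <- kept[cm$sex == sx & cm$stage == stage]
    lr[[paste0(sx, ".", stage)]] <-
      lrPermutationTest(norm[, cells, drop = FALSE], cl_labels[cells],
                        lr_pairs, "supporting", "germ", n_perm = n_perm,
                        seed = seed)
  }

  list(qc = qc, kept_cells = kept, sex_calls = sex_calls,
       populations = pops, de = de, degs = degs, links = links,
       candidate_pairs = pairs, hits = hits, enrichment = enrichment,
       deviations = dev, activity = activity, germline = germline,
       tf_candidates = tf_candidates, tf_targets = tf_targets,
       clustering = clustering, lr = lr, stage = stage,
       cell_meta = cm)
}

#' Recovery metrics of a pipeline run against planted truth
#'
#' @param res a [runPGCPipeline()] result.
#' @param truth the matching [MultiomeTruth-class].
#' @return named list of scalar metrics: DE sensitivity and empirical FDR,
#'   link sensitivity, sex-assignment accuracy, rank of the planted motif in
#'   the XX enrichment, TF selection true/false positives, target coverage
#'   of the planted TF, final-stage clustering ARI versus sex, and planted
#'   ligand-receptor outcomes.
#' @export
recoveryMetrics <- function(res, truth) {
  st <- res$stage
  tde <- trueDE(truth)
  t_genes <- unique(tde$gene[tde$stage == st])
  called <- res$de$feature_id[res$de$significant]
  de_sens <- mean(t_genes %in% called)
  de_fdr <- if (length(called)) mean(!(called %in% t_genes)) else 0
  tl <- trueLinks(truth)
  lk <- res$links
  acc_key <- paste(lk$peak_id[lk$accepted], lk$gene_id[lk$accepted])
  link_sens <- mean(paste(tl$peak, tl$gene) %in% acc_key)
  surv <- res$sex_calls[res$sex_calls$call != "removed", ]
  sex_acc <- mean(surv$call == sexOfCell(truth)[surv$cell_id])
  tt <- trueTFTargets(truth)
  planted_xx <- tt$motif_id[1]
  enr <- res$enrichment$XX
  motif_rank <- if (!is.null(enr)) match(planted_xx, enr$motif_id) else NA
  cand <- res$tf_candidates$XX
  sel <- cand$motif_id[cand$selected]
  tf_tp <- as.integer(planted_xx %in% sel)
  tf_fp <- length(setdiff(sel, planted_xx))
  coverage <- if (planted_xx %in% names(res$tf_targets))
    res$tf_targets[[planted_xx]]$coverage else 0
  ari <- NA_real_
  if (!is.null(res$clustering) && requireNamespace("mclust", quietly = TRUE)) {
    lab <- res$clustering$labels
    cmm <- res$cell_meta[names(lab), ]
    s3 <- cmm$stage == st
    ari <- mclust::adjustedRandIndex(lab[s3], cmm$sex[s3])
  }
  tlr <- trueLR(truth)
  lr_ok <- lr_wrong <- 0L
  for (i in seq_len(nrow(tlr))) {
    own <- res$lr[[paste0(tlr$sex[i], ".", st)]]
    oth <- res$lr[[paste0(setdiff(c("XX", "XY"), tlr$sex[i]), ".", st)]]
    lr_ok <- lr_ok + as.integer(own$significant[own$pair_id == tlr$pair_id[i]])
    lr_wrong <- lr_wrong +
      as.integer(isTRUE(oth$significant[oth$pair_id == tlr$pair_id[i]]))
  }
  list(de_sensitivity = de_sens, de_fdr = de_fdr, link_sensitivity = link_sens,
       sex_accuracy = sex_acc, planted_motif_rank = motif_rank,
       tf_selected_true = tf_tp, tf_selected_decoys = tf_fp,
       tf_target_coverage = coverage, clustering_ari_final_stage = ari,
       lr_planted_significant = lr_ok, lr_wrong_sex_significant = lr_wrong,
       n_lr_planted = nrow(tlr))
}
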