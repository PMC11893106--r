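#' Configuration for the synthetic multiome generator
#'
#' Defines the study conditions emulated by [simulateMultiome()]: two sexes
#' by three embryonic stages of gonadal nuclei; germ, supporting and
#' other-somatic compartments; Y-linked genes and peaks present only in XY
#' nuclei; planted differentially expressed genes and differentially
#' accessible peaks whose numbers grow with stage; planted peak-gene
#' couplings; planted TF -> motif -> peak -> gene wiring; and planted
#' ligand-receptor pairs between supporting cells and germ cells.
#'
#' @param n_cells_per_group nuclei per sex x stage group.
#' @param stages ordered stage labels (at least two).
#' @param sexes sex labels; fixed to XX/XY semantics.
#' @param n_genes,n_peaks feature counts (genes include the named marker,
#'   Y-linked, mitochondrial, TF and ligand-receptor genes).
#' @param frac_germ,frac_supporting fractions of each group's nuclei that are
#'   germ cells and supporting cells; the remainder is other somatic cells.
#' @param n_chrY_genes number of Y-linked genes (the first four are
#'   Kdm5d, Eif2s3y, Uty, Ddx3y).
#' @param n_chrY_peaks number of peaks on chrY, placed within
#'   chrY:1-90,000,000.
#' @param n_motifs number of shipped motifs used (3..10); the first motif is
#'   the planted XX-germline TF (TFAP2C), the second the planted XY TF
#'   (FOXK2).
#' @param n_de_genes_per_stage cumulative number of planted DE genes active
#'   at each stage (non-decreasing).
#' @param n_da_peaks_per_stage cumulative number of planted DA peaks active
#'   at each stage (non-decreasing).
#' @param n_links_true number of planted peak-gene couplings.
#' @param link_window maximum TSS distance (bp) used when placing linked
#'   peaks and when forming candidate pairs downstream.
#' @param effect_size_logfc planted log2 fold change for DE genes.
#' @param da_effect_logfc planted log2 fold change for DA peaks.
#' @param link_coupling_sd standard deviation of the shared log-normal latent
#'   factor coupling a linked peak to its gene (default tuned so that the
#'   Pearson correlation of normalized values is about 0.3-0.6).
#' @param sequencing_depth_rna,sequencing_depth_atac mean counts (fragments)
#'   per nucleus.
#' @param mito_frac_mean mean mitochondrial fraction of RNA counts.
#' @param frac_fail_qc fraction of nuclei planted to violate one QC
#'   threshold (low RNA depth, high mitochondrial fraction, low ATAC depth,
#'   or high nucleosome signal).
#' @param frac_sex_mislabel fraction of nuclei whose true chromosomal sex
#'   differs from the dataset (nominal) sex; these are the contaminants the
#'   chrY sex filter must remove.
#' @param n_lr_pairs_true number of planted ligand-receptor pairs (up to 4;
#'   two XX-restricted, two XY-restricted, sender = supporting, receiver =
#'   germ).
#' @param peak_width width of every simulated peak (bp).
#' @param motif_background_rate probability that any given non-planted peak
#'   receives a background insertion of each motif's consensus.
#' @param seed integer seed; the generator is byte-deterministic given the
#'   full configuration.
#' @return A validated list of class `"MultiomeConfig"`.
#' @export
multiomeConfig <- function(n_cells_per_group = 400,
                           stages = c("E11.5", "E12.5", "E13.5"),
                           sexes = c("XX", "XY"),
                           n_genes = 1000,
                           n_peaks = 2000,
                           frac_germ = 0.5,
                           frac_supporting = 0.25,
                           n_chrY_genes = 4,
                           n_chrY_peaks = 21,
                           n_motifs = 10,
                           n_de_genes_per_stage = c(10, 35, 60),
                           n_da_peaks_per_stage = c(30, 80, 150),
                           n_links_true = 50,
                           link_window = 5e5,
                           effect_size_logfc = 1.5,
                           da_effect_logfc = 1.5,
                           link_coupling_sd = 0.6,
                           sequencing_depth_rna = 5000,
                           sequencing_depth_atac = 2500,
                           mito_frac_mean = 0.05,
                           frac_fail_qc = 0.04,
                           frac_sex_mislabel = 0.01,
                           n_lr_pairs_true = 4,
                           peak_width = 500,
                           motif_background_rate = 0.01,
                           seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "MultiomeConfig"
  validateMultiomeConfig(cfg)
  cfg
}

#' @rdname multiomeConfig
#' @param cfg a `MultiomeConfig` list.
#' @export
validateMultiomeConfig <- function(cfg) {
  stopifnot(inherits(cfg, "MultiomeConfig"))
  if (length(cfg$stages) < 2)
    stop("at least two stages are required (trajectory structure undefined)")
  if (anyDuplicated(cfg$stages))
    stop("stages must be distinct ordered labels")
  pos <- c("n_cells_per_group", "n_genes", "n_peaks", "link_window",
           "sequencing_depth_rna", "sequencing_depth_atac", "peak_width")
  for (p in pos) if (cfg[[p]] <= 0) stop(sprintf("%s must be positive", p))
  if (cfg$frac_germ <= 0 || cfg$frac_germ >= 1)
    stop("frac_germ must lie in (0, 1)")
  if (cfg$frac_germ + cfg$frac_supporting >= 1)
    stop("frac_germ + frac_supporting must be < 1")
  if (length(cfg$n_de_genes_per_stage) != length(cfg$stages) ||
      length(cfg$n_da_peaks_per_stage) != length(cfg$stages))
    stop("per-stage DE/DA counts must have one entry per stage")
  if (is.unsorted(cfg$n_de_genes_per_stage) || is.unsorted(cfg$n_da_peaks_per_stage))
    stop("DE/DA counts must be non-decreasing across stages")
  if (cfg$n_motifs < 3 || cfg$n_motifs > 10)
    stop("n_motifs must be between 3 and 10 (shipped motif models)")
  if (cfg$n_chrY_genes < 1 || cfg$n_chrY_genes > 20)
    stop("n_chrY_genes must be between 1 and 20")
  if (cfg$n_lr_pairs_true < 0 || cfg$n_lr_pairs_true > 4)
    stop("n_lr_pairs_true must be between 0 and 4")
  invisible(TRUE)
}

# Named genes with roles in the simulation. Marker genes follow the
# population-selection rules for PGCs and supporting cells.
.sim_gene_roster <- function(cfg) {
  chrY <- c("Kdm5d", "Eif2s3y", "Uty", "Ddx3y",
            sprintf("GmY%d", 5:20))[seq_len(cfg$n_chrY_genes)]
  mito <- paste0("mt-", c("Nd1", "Nd2", "Co1", "Co2", "Co3",
                          "Atp6", "Atp8", "Cytb", "Nd4", "Nd5"))
  germ_markers <- c("Ddx4", "Pou5f1")
  pgc_exclude <- c("Foxl2", "Runx1", "Sox9", "Insl3", "Wt1", "Plvap",
                   "Mafb", "Pdgfra", "Nr2f2", "Tspan8", "Krt19")
  extra_soma <- "Pecam1"
  tf_genes <- motifTfGene(shippedMotifIds()[seq_len(cfg$n_motifs)])
  lr <- shippedLRPairs()
  lr_genes <- unique(unlist(c(strsplit(lr$ligand, ";"), strsplit(lr$receptor, ";"))))
  special <- unique(c(chrY, mito, germ_markers, pgc_exclude, extra_soma,
                      tf_genes, lr_genes))
  if (cfg$n_genes <= length(special) + 100)
    stop(sprintf("n_genes must exceed %d (named genes plus room for planted effects)",
                 length(special) + 100))
  generic <- sprintf("Gene%04d", seq_len(cfg$n_genes - length(special)))
  list(chrY = chrY, mito = mito, germ_markers = germ_markers,
       pgc_exclude = pgc_exclude, extra_soma = extra_soma,
       tf_genes = tf_genes, lr = lr, lr_genes = lr_genes,
       generic = generic, all = c(special, generic))
}

#' Simulate a paired single-nucleus multiome dataset with planted truth
#'
#' Draws RNA counts from a negative-binomial model on per-cell depth times
#' per-gene abundance, and ATAC counts from a low-count negative binomial.
#' Planted structure: sex/stage-specific log fold changes on DE genes and DA
#' peaks (germ cells only, growing with stage); a shared log-normal latent
#' factor coupling each planted peak-gene link; exact consensus insertions of
#' TF motifs into the sequences of planted peaks; Y-linked genes and peaks
#' zeroed in XX nuclei; a mitochondrial fraction of RNA depth; and a
#' configurable fraction of nuclei violating QC thresholds.
#'
#' @param cfg a [multiomeConfig()].
#' @return list with elements `dataset` ([MultiomeExperiment-class]) and
#'   `truth` ([MultiomeTruth-class]).
#' @export
simulateMultiome <- function(cfg = multiomeConfig()) {
  validateMultiomeConfig(cfg)
  set.seed(cfg$seed)
  roster <- .sim_gene_roster(cfg)
  genes <- roster$all
  n_genes <- length(genes)
  stages <- cfg$stages
  n_stage <- length(stages)
  motifs <- readJaspar(system.file("extdata", "motifs_jaspar.txt",
                                   package = "pgcMultiome"))
  motifs@motifs <- motifs@motifs[seq_len(cfg$n_motifs)]

  ## ---- cells ----
  groups <- expand.grid(sex = cfg$sexes, stage = stages,
                        stringsAsFactors = FALSE)
  n_cells <- cfg$n_cells_per_group * nrow(groups)
  cell_sex <- rep(groups$sex, each = cfg$n_cells_per_group)
  cell_stage <- factor(rep(groups$stage, each = cfg$n_cells_per_group),
                       levels = stages)
  barcodes <- sprintf("cell_%05d", seq_len(n_cells))
  n_germ <- round(cfg$frac_germ * cfg$n_cells_per_group)
  n_supp <- round(cfg$frac_supporting * cfg$n_cells_per_group)
  comp_group <- c(rep("germ", n_germ), rep("supporting", n_supp),
                  rep("other-soma", cfg$n_cells_per_group - n_germ - n_supp))
  compartment <- rep(comp_group, nrow(groups))
  replicate <- rep(rep(c("rep1", "rep2"), length.out = cfg$n_cells_per_group),
                   nrow(groups))
  # true chromosomal sex: a small fraction of nuclei are contaminants whose
  # true sex differs from the dataset (nominal) sex
  true_sex <- cell_sex
  n_swap <- round(cfg$frac_sex_mislabel * n_cells)
  if (n_swap > 0) {
    swap <- sample.int(n_cells, n_swap)
    true_sex[swap] <- ifelse(cell_sex[swap] == "XX", "XY", "XX")
  }
  # planted QC failures
  fail_mode <- rep("none", n_cells)
  n_fail <- round(cfg$frac_fail_qc * n_cells)
  if (n_fail > 0) {
    idx <- sample.int(n_cells, n_fail)
    fail_mode[idx] <- sample(c("rna_low", "mito_high", "atac_low", "nuc_bad"),
                             n_fail, replace = TRUE)
  }
  is_germ <- compartment == "germ"
  is_supp <- compartment == "supporting"
  stage_i <- as.integer(cell_stage)

  ## ---- gene annotation ----
  contigs <- c(chr1 = 120e6, chr2 = 120e6, chr3 = 120e6, chrY = 91e6, chrM = 16299)
  gchrom <- sample(c("chr1", "chr2", "chr3"), n_genes, replace = TRUE)
  gtss <- as.integer(floor(runif(n_genes, 1e5, 119e6)))
  gstrand <- sample(c("+", "-"), n_genes, replace = TRUE)
  glen <- sample(2000:20000, n_genes, replace = TRUE)
  names(gchrom) <- names(gtss) <- names(gstrand) <- names(glen) <- genes
  gchrom[roster$chrY] <- "chrY"
  gtss[roster$chrY] <- as.integer(floor(runif(length(roster$chrY), 1e6, 8.9e7)))
  gchrom[roster$mito] <- "chrM"
  gtss[roster$mito] <- as.integer(seq(100, by = 1500,
                                      length.out = length(roster$mito)))
  gstrand[roster$mito] <- "+"
  glen[roster$mito] <- 1000L
  gene_end <- as.integer(ifelse(gstrand == "+", gtss + glen, gtss - glen))
  is_marker_of <- rep(NA_character_, n_genes)
  names(is_marker_of) <- genes
  is_marker_of[roster$germ_markers] <- "germ"
  is_marker_of[c("Wt1", "Runx1", "Sox9", "Foxl2", "Tspan8")] <- "supporting"
  is_marker_of[c("Plvap", "Pecam1", "Pdgfra", "Nr2f2", "Mafb", "Krt19", "Insl3")] <- "other-soma"

  ## ---- planted DE genes ----
  n_de_total <- cfg$n_de_genes_per_stage[n_stage]
  de_genes <- character(0); de_sex <- character(0); de_from_stage <- integer(0)
  if (n_de_total > 0) {
    de_genes <- sample(roster$generic, n_de_total)
    de_sex <- rep(c("XX", "XY"), length.out = n_de_total)
    new_per_stage <- diff(c(0, cfg$n_de_genes_per_stage))
    de_from_stage <- rep(seq_len(n_stage), times = new_per_stage)
    # interleave so each activation stage holds both sexes
    de_sex <- unlist(lapply(split(de_sex, de_from_stage), function(x)
      rep(c("XX", "XY"), length.out = length(x))), use.names = FALSE)
  }

  ## ---- planted links ----
  # XX-up DE genes receive linked peaks carrying the planted XX TF motif;
  # a share of XY-up DE genes receive FOXK2-motif peaks; the remainder are
  # neutral couplings on non-DE genes.
  xx_de <- de_genes[de_sex == "XX"]
  xy_de <- de_genes[de_sex == "XY"]
  n_link_xx <- min(length(xx_de), ceiling(cfg$n_links_true * 0.6))
  n_link_xy <- min(length(xy_de), floor(cfg$n_links_true * 0.2))
  n_link_neutral <- max(cfg$n_links_true - n_link_xx - n_link_xy, 0)
  neutral_pool <- setdiff(roster$generic, de_genes)
  link_genes <- c(xx_de[seq_len(n_link_xx)], xy_de[seq_len(n_link_xy)],
                  sample(neutral_pool, n_link_neutral))
  link_kind <- rep(c("xx", "xy", "neutral"),
                   c(n_link_xx, n_link_xy, n_link_neutral))
  n_links <- length(link_genes)

  ## ---- peaks ----
  n_peaks <- cfg$n_peaks
  pk_id <- sprintf("peak_%05d", seq_len(n_peaks))
  w <- cfg$peak_width
  # layout: chrY peaks, then one peak per planted link (placed near its
  # gene), then promoter-proximal peaks, then random intergenic peaks
  pchrom <- character(n_peaks); pstart <- numeric(n_peaks)
  iY <- seq_len(cfg$n_chrY_peaks)
  pchrom[iY] <- "chrY"
  pstart[iY] <- floor(runif(cfg$n_chrY_peaks, 1e4, 9e7 - w - 1))
  iLink <- cfg$n_chrY_peaks + seq_len(n_links)
  pchrom[iLink] <- gchrom[link_genes]
  off <- floor(runif(n_links, 5e3, 1e5)) * sample(c(-1, 1), n_links, TRUE)
  pstart[iLink] <- pmax(1e4, pmin(gtss[link_genes] + off - w / 2,
                                  119e6 - w))
  n_rest <- n_peaks - cfg$n_chrY_peaks - n_links
  n_prom <- round(0.3 * n_rest)
  iProm <- cfg$n_chrY_peaks + n_links + seq_len(n_prom)
  prom_genes <- sample(setdiff(genes, c(roster$chrY, roster$mito)), n_prom,
                       replace = n_prom > n_genes)
  pchrom[iProm] <- gchrom[prom_genes]
  pstart[iProm] <- pmax(1, gtss[prom_genes] - w / 2 +
                          floor(runif(n_prom, -100, 100)))
  iRand <- setdiff(seq_len(n_peaks), c(iY, iLink, iProm))
  pchrom[iRand] <- sample(c("chr1", "chr2", "chr3"), length(iRand), TRUE)
  pstart[iRand] <- floor(runif(length(iRand), 1e4, 119e6 - w))
  pstart <- as.integer(pstart)
  link_peaks <- pk_id[iLink]

  ## ---- planted DA peaks ----
  n_da_total <- cfg$n_da_peaks_per_stage[n_stage]
  da_peaks <- character(0); da_sex <- character(0); da_from_stage <- integer(0)
  if (n_da_total > 0) {
    # link-DE peaks are DA for their gene's sex from the gene's stage on
    sel <- link_kind != "neutral"
    da_peaks <- link_peaks[sel]
    da_sex <- c(xx = "XX", xy = "XY")[link_kind[sel]]
    da_from_stage <- de_from_stage[match(link_genes[sel], de_genes)]
    quota <- diff(c(0, cfg$n_da_peaks_per_stage))
    planted_per_stage <- tabulate(da_from_stage, n_stage)
    extra <- pmax(quota - planted_per_stage, 0)
    pool <- setdiff(pk_id[iRand], da_peaks)
    extra_peaks <- sample(pool, sum(extra))
    da_peaks <- c(da_peaks, extra_peaks)
    da_from_stage <- c(da_from_stage, rep(seq_len(n_stage), times = extra))
    da_sex <- c(da_sex, rep(c("XX", "XY"), length.out = sum(extra)))
  }

  ## ---- RNA abundance weights ----
  W <- matrix(rep(exp(rnorm(n_genes, 0, 1)), n_cells), n_genes, n_cells,
              dimnames = list(genes, barcodes))
  setw <- function(g, cells, value) W[g, cells] <<- value
  # germ markers and exclusion markers
  setw(roster$germ_markers, !is_germ, 0.001)
  setw(roster$germ_markers, is_germ, 4)
  soma_all <- c(roster$pgc_exclude, roster$extra_soma)
  setw(soma_all, TRUE, 0.001)
  setw("Wt1", is_supp, 4)
  setw("Tspan8", is_supp, 3)
  setw("Runx1", is_supp & true_sex == "XX", 4)
  setw("Foxl2", is_supp & true_sex == "XX", 3)
  setw("Sox9", is_supp & true_sex == "XY", 4)
  other <- compartment == "other-soma"
  setw(c("Pdgfra", "Nr2f2"), other, 4)
  setw(c("Plvap", "Pecam1", "Mafb", "Krt19"), other, 3)
  setw("Insl3", other & true_sex == "XY", 3)
  # chrY genes: XY nuclei only (zeroed in XX by construction)
  setw(roster$chrY, true_sex == "XY", 2)
  setw(roster$chrY, true_sex == "XX", 0)
  # TF genes: germline-enriched set
  germl_tfs <- intersect(c("Tfap2c", "Foxk2", "Tcfl5", "Zfx", "Nr6a1", "Rreb1"),
                         roster$tf_genes)
  flat_tfs <- setdiff(roster$tf_genes, germl_tfs)
  setw(germl_tfs, is_germ, 3)
  setw(germl_tfs, !is_germ, 0.4)
  setw(flat_tfs, TRUE, 1.5)
  # DE effects for TF genes (Rreb1 is the decoy: DE and germline-enriched
  # but its motif is never planted in linked/DA peaks)
  fc <- 2^cfg$effect_size_logfc
  for (g in intersect(c("Tfap2c", "Rreb1"), roster$tf_genes))
    W[g, is_germ & true_sex == "XX" & stage_i >= 2] <-
      W[g, is_germ & true_sex == "XX" & stage_i >= 2] * fc
  if ("Foxk2" %in% roster$tf_genes)
    W["Foxk2", is_germ & true_sex == "XY" & stage_i >= 2] <-
      W["Foxk2", is_germ & true_sex == "XY" & stage_i >= 2] * fc
  # ligand-receptor structure
  lr <- roster$lr
  planted_lr <- .plantedLRPlan(cfg)
  marker_like <- c(roster$germ_markers, soma_all)
  rec_genes <- setdiff(unique(unlist(strsplit(lr$receptor, ";"))), marker_like)
  lig_genes <- setdiff(unique(unlist(strsplit(lr$ligand, ";"))), marker_like)
  setw(rec_genes, TRUE, 2)
  setw(lig_genes, TRUE, 1.5)
  if (nrow(planted_lr)) {
    p_lig <- unique(unlist(strsplit(planted_lr$ligand, ";")))
    setw(p_lig, TRUE, 0.02)
    for (i in seq_len(nrow(planted_lr))) {
      lg <- strsplit(planted_lr$ligand[i], ";")[[1]]
      sel <- is_supp & true_sex == planted_lr$sex[i]
      W[lg, sel] <- 6
    }
  }
  # generic planted DE genes: floor the baseline so effects are detectable
  if (n_de_total > 0) {
    W[de_genes, ] <- pmax(W[de_genes, ], 1)
    for (k in seq_len(n_de_total)) {
      sel <- is_germ & true_sex == de_sex[k] & stage_i >= de_from_stage[k]
      W[de_genes[k], sel] <- W[de_genes[k], sel] * fc
    }
  }
  # mitochondrial share of depth
  mito_w <- cfg$mito_frac_mean / (1 - cfg$mito_frac_mean)
  col_nonmito <- colSums(W[setdiff(genes, roster$mito), ])
  W[roster$mito, ] <- rep(col_nonmito * mito_w / length(roster$mito),
                          each = length(roster$mito))
  W[roster$mito, fail_mode == "mito_high"] <-
    W[roster$mito, fail_mode == "mito_high"] * 12

  ## ---- ATAC abundance weights ----
  A <- matrix(rep(exp(rnorm(n_peaks, 0, 0.8)), n_cells), n_peaks, n_cells,
              dimnames = list(pk_id, barcodes))
  A[iY, true_sex == "XX"] <- 0
  A[iY, true_sex == "XY"] <- pmax(A[iY, true_sex == "XY"], 0.8)
  A[iLink, ] <- pmax(A[iLink, ], 1.2)
  dfc <- 2^cfg$da_effect_logfc
  if (length(da_peaks)) {
    for (k in seq_along(da_peaks)) {
      sel <- is_germ & true_sex == da_sex[k] & stage_i >= da_from_stage[k]
      A[da_peaks[k], sel] <- A[da_peaks[k], sel] * dfc
    }
  }

  ## ---- link coupling: shared log-normal latent factor ----
  s <- cfg$link_coupling_sd
  if (n_links > 0 && s > 0) {
    Z <- matrix(rnorm(n_links * n_cells), n_links, n_cells)
    Fl <- exp(s * Z - s^2 / 2)
    W[link_genes, ] <- W[link_genes, ] * Fl
    A[link_peaks, ] <- A[link_peaks, ] * Fl
  }

  ## ---- draw counts ----
  depth_rna <- rlnorm(n_cells, log(cfg$sequencing_depth_rna) - 0.3^2 / 2, 0.3)
  depth_rna[fail_mode == "rna_low"] <- depth_rna[fail_mode == "rna_low"] * 0.12
  P <- sweep(W, 2, colSums(W), "/")
  mu <- sweep(P, 2, depth_rna, "*")
  size_g <- exp(rnorm(n_genes, log(4), 0.5))
  rna <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                        size = rep(size_g, n_cells)),
                n_genes, n_cells, dimnames = dimnames(W))
  depth_atac <- rlnorm(n_cells, log(cfg$sequencing_depth_atac) - 0.25^2 / 2, 0.25)
  depth_atac[fail_mode == "atac_low"] <- depth_atac[fail_mode == "atac_low"] * 0.2
  Pa <- sweep(A, 2, colSums(A), "/")
  mua <- sweep(Pa, 2, depth_atac, "*")
  atac <- matrix(rnbinom(length(mua), mu = as.vector(mua), size = 6),
                 n_peaks, n_cells, dimnames = dimnames(A))
  rna <- Matrix::Matrix(rna, sparse = TRUE)
  atac <- Matrix::Matrix(atac, sparse = TRUE)

  ## ---- peak sequences with planted motif sites ----
  gc_target <- 0.3 + 0.4 * rbeta(n_peaks, 4, 4)
  seqs <- vapply(seq_len(n_peaks), function(i) {
    paste(sample(c("A", "C", "G", "T"), w, replace = TRUE,
                 prob = c((1 - gc_target[i]) / 2, gc_target[i] / 2,
                          gc_target[i] / 2, (1 - gc_target[i]) / 2)),
          collapse = "")
  }, "")
  plant <- data.frame(motif_id = character(0), peak = character(0),
                      offset = integer(0))
  addPlants <- function(plant, motif_id, peaks) {
    if (!length(peaks)) return(plant)
    cons <- motifs@motifs[[match(motif_id, names(motifs))]]$consensus
    L <- nchar(cons)
    offs <- floor(runif(length(peaks), 0, w - L + 1))
    idx <- match(peaks, pk_id)
    substr(seqs[idx], offs + 1, offs + L) <<- cons
    rbind(plant, data.frame(motif_id = motif_id, peak = peaks, offset = offs))
  }
  # background insertions for every motif
  for (mid in names(motifs)) {
    bg <- pk_id[runif(n_peaks) < cfg$motif_background_rate]
    plant <- addPlants(plant, mid, bg)
  }
  # planted TF wiring: XX TF motif in the XX link-DE peaks, XY TF motif in
  # the XY link-DE peaks (planted last so these sites survive collisions)
  mid_xx <- names(motifs)[1]; mid_xy <- names(motifs)[2]
  plant <- addPlants(plant, mid_xx, link_peaks[link_kind == "xx"])
  plant <- addPlants(plant, mid_xy, link_peaks[link_kind == "xy"])
  peakSeqs <- Biostrings::DNAStringSet(seqs)
  names(peakSeqs) <- pk_id
  gc_frac <- as.numeric(Biostrings::letterFrequency(peakSeqs, "GC",
                                                    as.prob = TRUE))

  ## ---- fragments ----
  bad_nuc <- fail_mode == "nuc_bad"
  frags <- .simFragments(atac, pchrom, pstart, w, bad_nuc)

  ## ---- assemble ----
  pr <- GenomicRanges::GRanges(pchrom,
                               IRanges::IRanges(start = pstart + 1,
                                                width = w),
                               gc_fraction = gc_frac)
  names(pr) <- pk_id
  gene_meta <- DataFrame(
    gene_id = genes, chrom = unname(gchrom), tss = unname(gtss),
    strand = unname(gstrand), gene_end = unname(gene_end),
    is_chrY = genes %in% roster$chrY, is_mito = genes %in% roster$mito,
    is_marker_of = unname(is_marker_of), row.names = genes)
  cell_meta <- DataFrame(
    cell_id = barcodes, sex = cell_sex, stage = as.character(cell_stage),
    replicate = replicate, compartment = compartment, row.names = barcodes)
  ds <- MultiomeExperiment(rna = rna, atac = atac, colData = cell_meta,
                           geneData = gene_meta, peakRanges = pr,
                           fragments = frags, peakSeqs = peakSeqs)

  de_tab <- if (n_de_total > 0 || length(germl_tfs)) {
    tf_de <- data.frame(
      gene = intersect(c("Tfap2c", "Rreb1", "Foxk2"), roster$tf_genes),
      sex_up = c(Tfap2c = "XX", Rreb1 = "XX", Foxk2 = "XY")[
        intersect(c("Tfap2c", "Rreb1", "Foxk2"), roster$tf_genes)],
      from_stage = 2L)
    # Y-linked genes are XY-restricted by construction, hence true DE at
    # every stage (logfc unquantified: presence/absence)
    chrY_de <- data.frame(gene = roster$chrY, sex_up = "XY", from_stage = 1L)
    gen_de <- data.frame(gene = de_genes, sex_up = de_sex,
                         from_stage = de_from_stage)
    both <- rbind(gen_de, tf_de, chrY_de)
    both$logfc <- c(rep(cfg$effect_size_logfc, nrow(gen_de) + nrow(tf_de)),
                    rep(NA_real_, nrow(chrY_de)))
    do.call(rbind, lapply(seq_len(n_stage), function(s) {
      act <- both[both$from_stage <= s, , drop = FALSE]
      if (!nrow(act)) return(NULL)
      data.frame(gene = act$gene, stage = stages[s], sex_up = act$sex_up,
                 logfc = act$logfc, row.names = NULL)
    }))
  } else data.frame(gene = character(0), stage = character(0),
                    sex_up = character(0), logfc = numeric(0))
  da_tab <- if (length(da_peaks)) {
    do.call(rbind, lapply(seq_len(n_stage), function(s) {
      k <- da_from_stage <= s
      if (!any(k)) return(NULL)
      data.frame(peak = da_peaks[k], stage = stages[s], sex_up = da_sex[k],
                 logfc = cfg$da_effect_logfc, row.names = NULL)
    }))
  } else data.frame(peak = character(0), stage = character(0),
                    sex_up = character(0), logfc = numeric(0))
  tf_targets <- rbind(
    if (n_link_xx) data.frame(motif_id = mid_xx,
                              gene = link_genes[link_kind == "xx"]),
    if (n_link_xy) data.frame(motif_id = mid_xy,
                              gene = link_genes[link_kind == "xy"]))
  if (is.null(tf_targets))
    tf_targets <- data.frame(motif_id = character(0), gene = character(0))
  truth <- new("MultiomeTruth",
               de = de_tab, da = da_tab,
               links = data.frame(peak = link_peaks, gene = unname(link_genes)),
               tfTargets = tf_targets,
               motifPositions = plant,
               lr = planted_lr,
               sexOfCell = stats::setNames(true_sex, barcodes))
  list(dataset = ds, truth = truth)
}

# Planted ligand-receptor pairs: first two XX-restricted, next two
# XY-restricted; sender = supporting cells, receiver = germ cells.
.plantedLRPlan <- function(cfg) {
  lr <- shippedLRPairs()
  plan <- data.frame(
    pair_id = c("WNT4_FZD3_LRP6", "BMP2_BMPR1A_ACVR2B",
                "FGF9_FGFR2", "DHH_PTCH1"),
    sex = c("XX", "XX", "XY", "XY"))
  plan <- plan[seq_len(cfg$n_lr_pairs_true), , drop = FALSE]
  m <- match(plan$pair_id, lr$pair_id)
  data.frame(pair_id = plan$pair_id, ligand = lr$ligand[m],
             receptor = lr$receptor[m],
             sender = rep("supporting", nrow(plan)),
             receiver = rep("germ", nrow(plan)), sex = plan$sex,
             row.names = NULL)
}

# Emit one fragment record per ATAC count: midpoint uniform within the peak,
# length from a sub-nucleosomal/mono-nucleosomal mixture (inverted for
# planted nucleosome-signal failures). Coordinates 0-based half-open.
.simFragments <- function(atac, pchrom, pstart, width, bad_nuc) {
  tr <- Matrix::summary(atac)
  tr <- tr[tr$x > 0, , drop = FALSE]
  n <- sum(tr$x)
  if (n == 0)
    return(data.frame(cell = character(0), chrom = character(0),
                      start = integer(0), end = integer(0)))
  peak_i <- rep(tr$i, tr$x)
  cell_i <- rep(tr$j, tr$x)
  mids <- pstart[peak_i] + floor(runif(n, 0, width))
  p_mono <- ifelse(bad_nuc[cell_i], 0.8, 0.25)
  mono <- runif(n) < p_mono
  len <- ifelse(mono, round(rnorm(n, 200, 25)), round(rnorm(n, 80, 15)))
  len <- pmin(pmax(len, 30L), 400L)
  start <- pmax(mids - len %/% 2, 0)
  data.frame(cell = colnames(atac)[cell_i],
             chrom = pchrom[peak_i],
             start = as.integer(start),
             end = as.integer(start + len))
}
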