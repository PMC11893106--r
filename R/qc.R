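#' Per-cell quality-control metrics
#'
#' Computes, for every cell: total RNA counts, mitochondrial percentage,
#' total ATAC fragment counts, nucleosome signal (fragments of
#' mono-nucleosomal length 147-294 bp divided by sub-nucleosomal fragments
#' < 147 bp; +Inf when no sub-nucleosomal fragment exists), and TSS
#' enrichment (mean fragment-midpoint coverage in TSS +/- `tss_flank/2`,
#' aggregated over all TSSs, divided by the mean coverage in two flanking
#' windows of width `tss_flank` each; 0 when the cell has no midpoint near
#' any TSS, +Inf when it has central but no flanking coverage).
#'
#' @param dataset a [MultiomeExperiment-class] with fragments.
#' @param mito_genes genes treated as mitochondrial (default: the
#'   `is_mito` column of `geneData`).
#' @param tss_flank width (bp) of the central TSS window; flanking windows
#'   have the same width on each side.
#' @return data.frame with one row per cell: `cell_id`, `n_count_rna`,
#'   `percent_mt`, `n_count_atac`, `nucleosome_signal`, `tss_enrichment`.
#' @export
computeQC <- function(dataset, mito_genes = NULL, tss_flank = 1000) {
  rna <- rnaCounts(dataset)
  atac <- atacCounts(dataset)
  cells <- colnames(rna)
  if (is.null(mito_genes)) {
    gm <- geneData(dataset)
    mito_genes <- rownames(gm)[isTRUE_vec(gm$is_mito)]
  }
  n_rna <- Matrix::colSums(rna)
  mt <- if (length(mito_genes))
    Matrix::colSums(rna[mito_genes, , drop = FALSE]) else 0
  pct_mt <- ifelse(n_rna > 0, 100 * mt / n_rna, 0)
  fr <- fragments(dataset)
  if (!nrow(fr)) stop("fragments are required for ATAC QC metrics")
  len <- fr$end - fr$start
  cell_f <- factor(fr$cell, levels = cells)
  mono <- tabulate(cell_f[len >= 147 & len <= 294], nbins = length(cells))
  sub <- tabulate(cell_f[len < 147], nbins = length(cells))
  nuc <- ifelse(sub > 0, mono / sub, Inf)
  gm <- geneData(dataset)
  half <- tss_flank / 2
  mids <- floor((fr$start + fr$end) / 2)
  midgr <- GenomicRanges::GRanges(fr$chrom, IRanges::IRanges(mids + 1L, width = 1L))
  tssgr <- GenomicRanges::GRanges(gm$chrom,
                                  IRanges::IRanges(gm$tss + 1L, width = 1L))
  center <- GenomicRanges::resize(tssgr, width = tss_flank, fix = "center")
  upfl <- GenomicRanges::shift(center, -tss_flank)
  dnfl <- GenomicRanges::shift(center, tss_flank)
  countw <- function(win) {
    hits <- GenomicRanges::findOverlaps(midgr, win)
    tabulate(cell_f[S4Vectors::queryHits(hits)], nbins = length(cells))
  }
  nc <- countw(center)
  nf <- countw(upfl) + countw(dnfl)
  tss_enr <- ifelse(nf > 0, (nc / tss_flank) / (nf / (2 * tss_flank)),
                    ifelse(nc > 0, Inf, 0))
  data.frame(cell_id = cells, n_count_rna = as.numeric(n_rna),
             percent_mt = as.numeric(pct_mt),
             n_count_atac = as.numeric(Matrix::colSums(atac)),
             nucleosome_signal = nuc, tss_enrichment = tss_enr,
             row.names = cells)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Filter cells on QC thresholds
#'
#' All inequalities are strict, as thresholds are conventionally printed:
#' a cell is kept iff `n_count_rna > min_count_rna`,
#' `n_count_rna < max_count_rna`, `percent_mt < max_percent_mt`,
#' `n_count_atac > min_count_atac`, `n_count_atac < max_count_atac`,
#' `nucleosome_signal < max_nucleosome_signal`, and
#' `tss_enrichment > min_tss_enrichment`.
#'
#' @param qc data.frame from [computeQC()].
#' @param min_count_rna,max_count_rna,max_percent_mt RNA thresholds.
#' @param min_count_atac,max_count_atac,max_nucleosome_signal,min_tss_enrichment
#'   ATAC thresholds.
#' @return list with `kept` (cell ids) and `failures` (named tally of cells
#'   failing each condition; one cell can fail several).
#' @export
filterCells <- function(qc, min_count_rna = 1000, max_count_rna = 25000,
                        max_percent_mt = 25, min_count_atac = 1000,
                        max_count_atac = 1e5, max_nucleosome_signal = 2,
                        min_tss_enrichment = 1) {
  conds <- list(
    n_count_rna_low = qc$n_count_rna > min_count_rna,
    n_count_rna_high = qc$n_count_rna < max_count_rna,
    percent_mt = qc$percent_mt < max_percent_mt,
    n_count_atac_low = qc$n_count_atac > min_count_atac,
    n_count_atac_high = qc$n_count_atac < max_count_atac,
    nucleosome_signal = qc$nucleosome_signal < max_nucleosome_signal,
    tss_enrichment = qc$tss_enrichment > min_tss_enrichment)
  pass <- Reduce(`&`, conds)
  list(kept = qc$cell_id[pass],
       failures = vapply(conds, function(x) sum(!x), 0L))
}

#' Filter peaks on width, contig and blacklist
#'
#' Keeps a peak iff its width (end minus start in 0-based half-open
#' coordinates) is strictly between `min_width` and `max_width`, it lies on
#' a standard contig, and it does not overlap the blacklist.
#'
#' @param peaks a `GRanges` of peaks (names = peak ids).
#' @param min_width,max_width exclusive width bounds (defaults 20 and 10,000).
#' @param standard_pattern regular expression defining standard contigs.
#' @param blacklist optional `GRanges` of excluded regions (empty allowed).
#' @return list with `kept` (peak ids) and `failures` tally.
#' @export
filterPeaks <- function(peaks, min_width = 20, max_width = 10000,
                        standard_pattern = "^chr([0-9]+|X|Y)$",
                        blacklist = NULL) {
  w <- GenomicRanges::width(peaks)  # GRanges width == BED end - start
  ok_w <- w > min_width & w < max_width
  ok_chr <- grepl(standard_pattern,
                  as.character(GenomicRanges::seqnames(peaks)))
  ok_bl <- rep(TRUE, length(peaks))
  if (!is.null(blacklist) && length(blacklist))
    ok_bl <- !IRanges::overlapsAny(peaks, blacklist)
  list(kept = names(peaks)[ok_w & ok_chr & ok_bl],
       failures = c(width = sum(!ok_w), nonstandard_contig = sum(!ok_chr),
                    blacklist = sum(!ok_bl)))
}

#' Expression-binned module score
#'
#' Genes are binned by mean normalized expression into `n_bins` bins; for
#' each gene of the set, `n_ctrl` control genes are sampled with replacement
#' from the gene's bin. The score is the per-cell mean over set genes minus
#' the mean over the sampled control multiset.
#'
#' @param norm_expr normalized gene x cell matrix.
#' @param gene_set character vector of gene ids (non-empty, present).
#' @param n_bins number of expression bins (default 24).
#' @param n_ctrl controls sampled per set gene (default 100).
#' @param seed integer seed for the control sampling.
#' @return named numeric vector of per-cell scores.
#' @export
moduleScoreBinned <- function(norm_expr, gene_set, n_bins = 24, n_ctrl = 100,
                              seed = 1L) {
  if (length(gene_set) == 0) stop("gene_set must be non-empty")
  if (!all(gene_set %in% rownames(norm_expr)))
    stop("gene_set contains genes absent from the matrix")
  set.seed(seed)
  avg <- Matrix::rowMeans(norm_expr)
  n_bins <- max(1, min(n_bins, length(avg)))
  bin <- if (n_bins == 1) rep(1L, length(avg))
         else cut(rank(avg, ties.method = "first"), breaks = n_bins,
                  labels = FALSE)
  names(bin) <- rownames(norm_expr)
  ctrl <- unlist(lapply(gene_set, function(g) {
    pool <- names(bin)[bin == bin[g]]
    sample(pool, n_ctrl, replace = TRUE)
  }), use.names = FALSE)
  set_mean <- Matrix::colMeans(norm_expr[gene_set, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(norm_expr[ctrl, , drop = FALSE])
  set_mean - ctrl_mean
}

#' Rank-based (U-statistic) module score
#'
#' Per cell, genes are ranked by decreasing expression (ties: average rank;
#' ranks beyond `r_max` are clipped to `r_max + 1`). With U' =
#' sum over set genes of the clipped rank minus |set|(|set|+1)/2, the score
#' is `1 - U' / (|set| * r_max)`, in \[0, 1\] up to the clipping floor.
#'
#' @param norm_expr normalized gene x cell matrix.
#' @param gene_set character vector of gene ids (non-empty, present).
#' @param r_max rank ceiling (default 1500; must be >= |gene_set|).
#' @return named numeric vector of per-cell scores.
#' @export
moduleScoreRank <- function(norm_expr, gene_set, r_max = 1500) {
  if (length(gene_set) == 0) stop("gene_set must be non-empty")
  if (!all(gene_set %in% rownames(norm_expr)))
    stop("gene_set contains genes absent from the matrix")
  if (r_max < length(gene_set))
    stop("r_max must be at least the gene-set size")
  m <- as.matrix(norm_expr)
  ls <- length(gene_set)
  scores <- apply(m, 2, function(x) {
    r <- rank(-x, ties.method = "average")
    r <- pmin(r, r_max + 1)
    u <- sum(r[gene_set]) - ls * (ls + 1) / 2
    1 - u / (ls * r_max)
  })
  names(scores) <- colnames(norm_expr)
  scores
}

#' Count ATAC fragments per cell within the chrY peak region
#'
#' @param dataset a [MultiomeExperiment-class].
#' @param chrom,start,end the region (default chrY:0-90,000,000, 0-based
#'   half-open).
#' @return named integer vector per cell.
#' @export
chrYFragmentCounts <- function(dataset, chrom = "chrY", start = 0, end = 9e7) {
  fr <- fragments(dataset)
  cells <- colnames(rnaCounts(dataset))
  sel <- fr$chrom == chrom & fr$end > start & fr$start < end
  cnt <- tabulate(factor(fr$cell[sel], levels = cells), nbins = length(cells))
  stats::setNames(as.integer(cnt), cells)
}

#' Assign chromosomal sex from chrY module scores and chrY fragments
#'
#' Reference distributions come from the final-stage cells of each nominal
#' sex. The male lower bound is `mean - male_sd * sd` of the XY reference
#' scores; the female upper bound is `mean + female_sd * sd` of the XX
#' reference scores. A cell of a male (XY) dataset is removed iff it has
#' zero chrY fragments or a score below the male bound; a cell of a female
#' (XX) dataset is removed iff it has more than `max_frag_female` chrY
#' fragments or a score above the female bound. Survivors are called
#' XY / XX respectively.
#'
#' @param scores per-cell chrY module score (named by cell).
#' @param chrY_frag per-cell chrY-region fragment counts (named by cell).
#' @param dataset_sex per-cell nominal sex of the library (XX/XY).
#' @param stage per-cell stage labels.
#' @param ref_stage stage used for the reference sets (default the last
#'   sorted stage present).
#' @param male_sd,female_sd standard-deviation multipliers for the bounds.
#' @param max_frag_female maximum tolerated chrY fragments in a female
#'   dataset (default 1: cells with more than one are removed).
#' @return data.frame: `cell_id`, `chrY_module_score`,
#'   `chrY_fragment_count`, `call` in XX/XY/removed.
#' @export
assignSex <- function(scores, chrY_frag, dataset_sex, stage,
                      ref_stage = NULL, male_sd = 1, female_sd = 1,
                      max_frag_female = 1) {
  cells <- names(scores)
  stopifnot(length(chrY_frag) == length(scores),
            length(dataset_sex) == length(scores),
            length(stage) == length(scores))
  if (is.null(ref_stage)) ref_stage <- max(sort(unique(stage)))
  ref_xy <- scores[dataset_sex == "XY" & stage == ref_stage]
  ref_xx <- scores[dataset_sex == "XX" & stage == ref_stage]
  if (length(ref_xy) < 2 || length(ref_xx) < 2)
    stop("reference sets must contain at least 2 cells each")
  t_m <- mean(ref_xy) - male_sd * stats::sd(ref_xy)
  t_f <- mean(ref_xx) + female_sd * stats::sd(ref_xx)
  call <- character(length(scores))
  male <- dataset_sex == "XY"
  call[male] <- ifelse(chrY_frag[male] == 0 | scores[male] < t_m,
                       "removed", "XY")
  call[!male] <- ifelse(chrY_frag[!male] > max_frag_female |
                          scores[!male] > t_f, "removed", "XX")
  data.frame(cell_id = cells, chrY_module_score = unname(scores),
             chrY_fragment_count = unname(chrY_frag), call = call,
             row.names = cells)
}

#' Marker rules for population selection
#'
#' A rule labels a cell iff every `require_expressed` gene has raw count
#' strictly above `threshold` and every `require_absent` gene has raw count
#' strictly below `threshold`.
#'
#' @param label population name.
#' @param require_expressed,require_absent disjoint gene lists.
#' @param threshold count threshold (default 1).
#' @return a list of class `"MarkerRule"`.
#' @export
markerRule <- function(label, require_expressed, require_absent = character(0),
                       threshold = 1) {
  if (length(intersect(require_expressed, require_absent)))
    stop("require_expressed and require_absent must be disjoint")
  structure(list(label = label, require_expressed = require_expressed,
                 require_absent = require_absent, threshold = threshold),
            class = "MarkerRule")
}

#' Shipped marker rules for PGCs and gonadal supporting cells
#'
#' PGCs: Ddx4 and Pou5f1 expressed; granulosa (Foxl2, Runx1), Sertoli
#' (Sox9), Leydig (Insl3), stromal (Wt1), endothelial (Plvap), immune
#' (Mafb), interstitial (Pdgfra, Nr2f2), supporting (Tspan8) and epithelial
#' (Krt19) markers absent. Supporting cells: Wt1 expressed; germ (Ddx4,
#' Pou5f1), endothelial (Plvap, Pecam1) and interstitial (Pdgfra, Nr2f2)
#' markers absent.
#'
#' @return list of [markerRule()] objects.
#' @export
gonadMarkerRules <- function() {
  list(
    markerRule("PGC",
               require_expressed = c("Ddx4", "Pou5f1"),
               require_absent = c("Foxl2", "Runx1", "Sox9", "Insl3", "Wt1",
                                  "Plvap", "Mafb", "Pdgfra", "Nr2f2",
                                  "Tspan8", "Krt19")),
    markerRule("supporting",
               require_expressed = "Wt1",
               require_absent = c("Ddx4", "Pou5f1", "Plvap", "Pecam1",
                                  "Pdgfra", "Nr2f2")))
}

#' Select cell populations by marker rules
#'
#' @param rna_counts raw gene x cell count matrix.
#' @param rules list of [markerRule()] objects.
#' @return named list (one element per rule label) of cell-id vectors.
#' @export
selectPopulation <- function(rna_counts, rules) {
  out <- list()
  for (rule in rules) {
    genes <- c(rule$require_expressed, rule$require_absent)
    missing <- setdiff(genes, rownames(rna_counts))
    if (length(missing))
      stop("unknown gene(s) in rule '", rule$label, "': ",
           paste(missing, collapse = ", "))
    keep <- rep(TRUE, ncol(rna_counts))
    for (g in rule$require_expressed)
      keep <- keep & (rna_counts[g, ] > rule$threshold)
    for (g in rule$require_absent)
      keep <- keep & (rna_counts[g, ] < rule$threshold)
    out[[rule$label]] <- colnames(rna_counts)[keep]
  }
  out
}
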