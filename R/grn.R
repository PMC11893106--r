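#' Germline-enriched genes
#'
#' Genes with higher expression in germ cells than in the somatic
#' compartment: [findMarkers()] germ vs soma, enriched iff `p_adj < alpha`
#' and `log2fc > logfc_threshold` toward germ.
#'
#' @param norm_expr,raw_counts gene x cell matrices.
#' @param germ_cells,soma_cells non-empty disjoint cell groups.
#' @param min_pct,logfc_threshold,alpha gates (gene-level defaults).
#' @return character vector of enriched gene ids (attribute `table` holds
#'   the full marker table).
#' @export
germlineEnrichment <- function(norm_expr, raw_counts, germ_cells, soma_cells,
                               min_pct = 0.25, logfc_threshold = 0.25,
                               alpha = 0.05) {
  stopifnot(length(germ_cells) > 0, length(soma_cells) > 0)
  tab <- findMarkers(norm_expr, raw_counts, germ_cells, soma_cells,
                     min_pct = min_pct, logfc_threshold = logfc_threshold,
                     alpha = alpha, direction = "up")
  enriched <- tab$feature_id[tab$significant & tab$log2fc > logfc_threshold]
  attr(enriched, "table") <- tab
  enriched
}

#' Select candidate transcription factors
#'
#' A TF is selected for a group (sex x stage) iff its gene is differentially
#' expressed toward that group, germline-enriched, its motif is enriched
#' (`p_adj < alpha`) in the group's query peaks, and its mean motif-activity
#' deviation z in the group is positive. Motifs without a mapped gene are
#' flagged and excluded from selection. Output is ordered by motif
#' enrichment p.
#'
#' @param de_table [findMarkers()] result for the group comparison, with the
#'   group of interest as `cells_a`.
#' @param enrichment_table [motifEnrichment()] result on the group's peaks.
#' @param activity named per-motif mean deviation z in the group (e.g. one
#'   column of [motifActivity()]).
#' @param germline_set gene ids from [germlineEnrichment()].
#' @param motif_tf named character vector motif id -> TF gene symbol.
#' @param alpha significance level used for the DE and enrichment flags.
#' @return data.frame per motif: `motif_id`, `tf_gene`, `is_de`,
#'   `germline_enriched`, `motif_enriched`, `mean_motif_activity_z`,
#'   `unmapped`, `selected`.
#' @export
selectCandidateTFs <- function(de_table, enrichment_table, activity,
                               germline_set, motif_tf, alpha = 0.05) {
  mids <- enrichment_table$motif_id
  tf <- unname(motif_tf[mids])
  de_up <- de_table$feature_id[de_table$significant & de_table$log2fc > 0]
  out <- data.frame(
    motif_id = mids,
    tf_gene = tf,
    is_de = !is.na(tf) & tf %in% de_up,
    germline_enriched = !is.na(tf) & tf %in% germline_set,
    motif_enriched = enrichment_table$p_adj < alpha,
    mean_motif_activity_z = unname(activity[mids]),
    unmapped = is.na(tf))
  out$selected <- !out$unmapped & out$is_de & out$germline_enriched &
    out$motif_enriched & out$mean_motif_activity_z > 0
  out[order(enrichment_table$p_value), , drop = FALSE]
}

#' Predict target genes of a candidate TF
#'
#' A gene of `deg_set` is a predicted target iff some peak carries the TF's
#' motif and has an accepted link to that gene. Coverage is the fraction of
#' `deg_set` targeted.
#'
#' @param motif_id the TF's motif.
#' @param hits a [scanPeaks()] result or logical peak x motif matrix.
#' @param links accepted rows of a [linkPeaks()] table.
#' @param deg_set DEGs that have at least one accepted link (non-empty).
#' @return list: `targets` (character), `coverage` in \[0, 1\], and the
#'   per-edge `provenance` (motif, peak, gene witnesses).
#' @export
predictTargets <- function(motif_id, hits, links, deg_set) {
  if (!length(deg_set))
    stop("deg_set is empty: coverage undefined")
  H <- if (inherits(hits, "HitMatrix")) hits$hits else hits
  acc <- links[links$accepted & links$gene_id %in% deg_set, , drop = FALSE]
  hit_peaks <- rownames(H)[H[, motif_id]]
  edge <- acc[acc$peak_id %in% hit_peaks, , drop = FALSE]
  targets <- sort(unique(edge$gene_id))
  list(targets = targets,
       coverage = length(targets) / length(deg_set),
       provenance = data.frame(motif_id = rep(motif_id, nrow(edge)),
                               peak_id = edge$peak_id,
                               gene_id = edge$gene_id))
}

#' TF cross-regulation adjacency
#'
#' Edge A -> B iff A's motif hits a peak with an accepted link to B's gene,
#' or a peak within B's promoter window (TSS +/- `tss_region`). Self-edges
#' are permitted and reported separately.
#'
#' @param tfs data.frame with columns `motif_id` and `tf_gene`.
#' @param hits a [scanPeaks()] result or logical peak x motif matrix.
#' @param links [linkPeaks()] table (only accepted rows are used).
#' @param peaks `GRanges` of peaks (names = peak ids).
#' @param gene_meta data.frame/DataFrame with `gene_id`, `chrom`, `tss`.
#' @param tss_region promoter half-width (default 3000).
#' @return list: `adjacency` (TF x TF logical matrix, rows regulate
#'   columns), `self_edges` (named logical).
#' @export
tfCrossRegulation <- function(tfs, hits, links, peaks, gene_meta,
                              tss_region = 3000) {
  H <- if (inherits(hits, "HitMatrix")) hits$hits else hits
  gm <- as.data.frame(gene_meta)
  missing <- setdiff(tfs$tf_gene, gm$gene_id)
  if (length(missing))
    stop("TF gene(s) absent from gene_meta: ", paste(missing, collapse = ", "))
  acc <- links[links$accepted, , drop = FALSE]
  n <- nrow(tfs)
  adj <- matrix(FALSE, n, n, dimnames = list(tfs$tf_gene, tfs$tf_gene))
  for (bi in seq_len(n)) {
    g <- tfs$tf_gene[bi]
    i <- match(g, gm$gene_id)
    prom <- GenomicRanges::GRanges(gm$chrom[i],
                                   IRanges::IRanges(max(gm$tss[i] + 1 - tss_region, 1),
                                                    gm$tss[i] + 1 + tss_region))
    prom_peaks <- names(peaks)[IRanges::overlapsAny(peaks, prom,
                                                    ignore.strand = TRUE)]
    linked_peaks <- acc$peak_id[acc$gene_id == g]
    target_peaks <- union(prom_peaks, linked_peaks)
    if (!length(target_peaks)) next
    for (ai in seq_len(n)) {
      adj[ai, bi] <- any(H[target_peaks, tfs$motif_id[ai]])
    }
  }
  self <- diag(adj)
  names(self) <- tfs$tf_gene
  list(adjacency = adj, self_edges = self)
}

#' Hypergeometric over-representation of gene sets
#'
#' Upper-tail hypergeometric p per set for the overlap between `genes` and
#' each set, restricted to the `universe`; BH over sets. Sets with zero
#' overlap with the universe are skipped.
#'
#' @param genes query genes (subset of `universe`).
#' @param universe background genes.
#' @param gene_sets named list of gene vectors (e.g. from [readGmt()]).
#' @param alpha significance level (default 0.05).
#' @return data.frame per set: `set`, `k` (query overlap), `K` (universe
#'   overlap), `n_query`, `n_universe`, `p_value`, `p_adj`, `significant`;
#'   sorted by p.
#' @export
overrepresentation <- function(genes, universe, gene_sets, alpha = 0.05) {
  if (!length(gene_sets)) stop("gene_sets must be non-empty")
  if (!all(genes %in% universe)) stop("genes must be a subset of universe")
  universe <- unique(universe)
  genes <- unique(genes)
  K <- vapply(gene_sets, function(s) length(intersect(s, universe)), 0L)
  keep <- K > 0
  gene_sets <- gene_sets[keep]; K <- K[keep]
  if (!length(gene_sets))
    return(data.frame(set = character(0), k = integer(0), K = integer(0),
                      n_query = integer(0), n_universe = integer(0),
                      p_value = numeric(0), p_adj = numeric(0),
                      significant = logical(0)))
  k <- vapply(gene_sets, function(s) length(intersect(s, genes)), 0L)
  N <- length(universe); nq <- length(genes)
  p <- stats::phyper(k - 1, K, N - K, nq, lower.tail = FALSE)
  out <- data.frame(set = names(gene_sets), k = k, K = K, n_query = nq,
                    n_universe = N, p_value = p, p_adj = bhAdjust(p),
                    row.names = NULL)
  out$significant <- out$p_adj < alpha
  out[order(out$p_value), , drop = FALSE]
}
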