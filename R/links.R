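#' Candidate peak-gene pairs within a TSS window
#'
#' All (peak, gene) pairs on the same chromosome with
#' `|peak midpoint - TSS| <= window_bp` (boundary included). Distance is
#' signed by gene strand (positive = downstream of the TSS).
#'
#' @param peaks `GRanges` of peaks (names = peak ids).
#' @param gene_meta data.frame/DataFrame with `gene_id`, `chrom`, `tss`,
#'   `strand`; genes with missing TSS are skipped with a warning.
#' @param window_bp maximum distance (default 500,000).
#' @return data.frame: `peak_id`, `gene_id`, `distance`.
#' @export
candidatePairs <- function(peaks, gene_meta, window_bp = 5e5) {
  stopifnot(window_bp > 0)
  gm <- as.data.frame(gene_meta)
  bad <- is.na(gm$tss)
  if (any(bad)) {
    warning(sum(bad), " gene(s) without TSS skipped")
    gm <- gm[!bad, , drop = FALSE]
  }
  mid <- floor((GenomicRanges::start(peaks) - 1 + GenomicRanges::end(peaks)) / 2)
  tssgr <- GenomicRanges::GRanges(gm$chrom, IRanges::IRanges(gm$tss + 1L, width = 1))
  midgr <- GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(peaks)),
                                  IRanges::IRanges(mid + 1L, width = 1))
  lv <- union(GenomeInfoDb::seqlevels(midgr), GenomeInfoDb::seqlevels(tssgr))
  GenomeInfoDb::seqlevels(midgr) <- lv
  GenomeInfoDb::seqlevels(tssgr) <- lv
  hits <- GenomicRanges::findOverlaps(midgr, tssgr, maxgap = window_bp)
  pi <- S4Vectors::queryHits(hits); gi <- S4Vectors::subjectHits(hits)
  d <- mid[pi] - gm$tss[gi]
  d <- ifelse(gm$strand[gi] == "-", -d, d)
  keep <- abs(d) <= window_bp
  data.frame(peak_id = names(peaks)[pi][keep], gene_id = gm$gene_id[gi][keep],
             distance = d[keep])
}

#' Background peaks matched on GC, accessibility and width
#'
#' Features (per-peak GC fraction, mean accessibility, width) are z-scored
#' over all peaks; the background of a query peak is its `n_background`
#' nearest peaks in Euclidean feature space, excluding the query, with ties
#' broken by peak id order.
#'
#' @param features data.frame/matrix with one row per peak (row names = peak
#'   ids) and the matching feature columns.
#' @param query peak ids to match (default: all peaks).
#' @param n_background background size per query (default 200); when fewer
#'   peaks exist, all non-query peaks are used with a warning.
#' @param seed accepted for interface stability; the matching itself is
#'   deterministic.
#' @return character matrix (queries x n_background) of peak ids.
#' @export
matchBackgroundPeaks <- function(features, query = NULL, n_background = 200,
                                 seed = 1L) {
  features <- as.matrix(features)
  ids <- rownames(features)
  if (is.null(ids)) stop("features must have peak ids as row names")
  if (is.null(query)) query <- ids
  n <- nrow(features)
  if (n_background > n - 1) {
    warning("fewer than n_background peaks available; using all ", n - 1)
    n_background <- n - 1
  }
  z <- scale(features)
  z[, attr(z, "scaled:scale") == 0] <- 0
  out <- matrix(NA_character_, length(query), n_background,
                dimnames = list(query, NULL))
  qi <- match(query, ids)
  if (anyNA(qi)) stop("unknown query peak id(s)")
  block <- 500L
  for (b in seq(1, length(qi), by = block)) {
    rows <- b:min(b + block - 1L, length(qi))
    d2 <- outer(rowSums(z[qi[rows], , drop = FALSE]^2), rowSums(z^2), "+") -
      2 * z[qi[rows], , drop = FALSE] %*% t(z)
    for (k in seq_along(rows)) {
      dd <- d2[k, ]
      dd[qi[rows[k]]] <- Inf  # exclude the query itself
      ord <- order(dd, seq_len(n))
      out[rows[k], ] <- ids[ord[seq_len(n_background)]]
    }
  }
  out
}

#' Link peaks to genes against a matched-background null
#'
#' For each candidate pair the Pearson correlation `r` between peak
#' accessibility and gene expression (normalized values) is compared with
#' the null correlations of the same gene against the peak's matched
#' background peaks: `z = (r - mean(null)) / sd(null)`, with a one-sided
#' upper-tail normal p. A link is accepted iff `p < p_threshold` and
#' `z > 0`. Pairs with a zero-variance peak or gene, or a degenerate
#' (zero-sd) null, are dropped with a reason.
#'
#' @param atac_norm normalized peak x cell matrix.
#' @param rna_norm normalized gene x cell matrix (same cells, same order).
#' @param pairs data.frame from [candidatePairs()].
#' @param features per-peak matching features (see
#'   [matchBackgroundPeaks()]); default: GC is not available here, so
#'   callers normally pass `linkFeatures()` output.
#' @param n_background matched background peaks per query (default 200).
#' @param p_threshold acceptance p-value (default 0.05).
#' @param method "pearson" (default) or "spearman".
#' @param seed passed to [matchBackgroundPeaks()].
#' @return data.frame: `peak_id`, `gene_id`, `r`, `z`, `p_value`,
#'   `accepted`, plus a `dropped` attribute tabulating dropped pairs.
#' @export
linkPeaks <- function(atac_norm, rna_norm, pairs, features,
                      n_background = 200, p_threshold = 0.05,
                      method = c("pearson", "spearman"), seed = 1L) {
  method <- match.arg(method)
  if (!identical(colnames(atac_norm), colnames(rna_norm)))
    stop("cell order differs between modalities")
  n <- ncol(atac_norm)
  present <- pairs$peak_id %in% rownames(atac_norm) &
    pairs$gene_id %in% rownames(rna_norm)
  missing_pairs <- pairs[!present, c("peak_id", "gene_id"), drop = FALSE]
  pairs <- pairs[present, , drop = FALSE]
  peaks_needed <- unique(pairs$peak_id)
  genes_needed <- unique(pairs$gene_id)
  bg <- matchBackgroundPeaks(features, query = peaks_needed,
                             n_background = n_background, seed = seed)
  used_peaks <- unique(c(peaks_needed, as.vector(bg)))
  stdRows <- function(m, rows) {
    x <- as.matrix(m[rows, , drop = FALSE])
    if (method == "spearman")
      x <- t(apply(x, 1, rank))
    x <- x - rowMeans(x)
    s <- sqrt(rowSums(x^2))
    list(x = x / pmax(s, .Machine$double.eps), ok = s > 0)
  }
  ga <- stdRows(rna_norm, genes_needed)
  pa <- stdRows(atac_norm, used_peaks)
  R <- ga$x %*% t(pa$x)  # genes x peaks, Pearson correlations
  rownames(R) <- genes_needed; colnames(R) <- used_peaks
  res <- data.frame(peak_id = pairs$peak_id, gene_id = pairs$gene_id,
                    r = NA_real_, z = NA_real_, p_value = NA_real_,
                    accepted = FALSE, reason = NA_character_)
  gene_ok <- stats::setNames(ga$ok, genes_needed)
  peak_ok <- stats::setNames(pa$ok, used_peaks)
  for (k in seq_len(nrow(res))) {
    pk <- res$peak_id[k]; gn <- res$gene_id[k]
    if (!gene_ok[gn] || !peak_ok[pk]) {
      res$reason[k] <- "zero variance"
      next
    }
    bgk <- bg[pk, ]
    nullr <- R[gn, bgk]
    nullr <- nullr[peak_ok[bgk]]
    sdn <- stats::sd(nullr)
    if (!is.finite(sdn) || sdn == 0) {
      res$reason[k] <- "degenerate null"
      next
    }
    r <- R[gn, pk]
    z <- (r - mean(nullr)) / sdn
    res$r[k] <- r
    res$z[k] <- z
    res$p_value[k] <- stats::pnorm(z, lower.tail = FALSE)
    res$accepted[k] <- res$p_value[k] < p_threshold && z > 0
  }
  missing_pairs$reason <- rep("missing feature", nrow(missing_pairs))
  dropped <- rbind(res[!is.na(res$reason), c("peak_id", "gene_id", "reason")],
                   missing_pairs)
  res <- res[is.na(res$reason), setdiff(colnames(res), "reason"),
             drop = FALSE]
  attr(res, "dropped") <- dropped
  res
}

#' Per-peak features for background matching
#'
#' @param dataset a [MultiomeExperiment-class].
#' @return data.frame (rows = peaks): `gc_fraction`, `mean_accessibility`,
#'   `width`.
#' @export
linkFeatures <- function(dataset) {
  pr <- peakRanges(dataset)
  data.frame(gc_fraction = pr$gc_fraction,
             mean_accessibility = Matrix::rowMeans(atacCounts(dataset)),
             width = GenomicRanges::width(pr),
             row.names = names(pr))
}

#' Annotate peaks by genomic feature
#'
#' Assigns exactly one category per peak with priority
#' promoter > 5' UTR > 3' UTR > exon > intron > downstream >
#' distal_intergenic. The promoter is the TSS +/- `tss_region` window;
#' downstream is within `tss_region` past the gene end; introns are gene
#' body not covered by an exon.
#'
#' @param peaks `GRanges` of peaks (names = peak ids).
#' @param gene_model `GRanges` with a metadata column `type` in
#'   `gene`, `exon`, `utr5`, `utr3`; `gene` rows must carry strand and
#'   span TSS to gene end.
#' @param tss_region promoter half-width (default 3000).
#' @return list: `annotation` data.frame (`peak_id`, `category`) and
#'   `percentages` (named, sums to 100).
#' @export
annotatePeaks <- function(peaks, gene_model, tss_region = 3000) {
  categories <- c("promoter", "utr5", "utr3", "exon", "intron",
                  "downstream", "distal_intergenic")
  cat_of <- rep("distal_intergenic", length(peaks))
  if (length(gene_model)) {
    genes <- gene_model[gene_model$type == "gene"]
    tss <- GenomicRanges::resize(genes, width = 1, fix = "start")
    prom <- GenomicRanges::promoters(tss, upstream = tss_region,
                                     downstream = tss_region + 1)
    tes <- GenomicRanges::resize(genes, width = 1, fix = "end")
    down <- GenomicRanges::flank(tes, width = tss_region, start = FALSE)
    regions <- list(
      promoter = prom,
      utr5 = gene_model[gene_model$type == "utr5"],
      utr3 = gene_model[gene_model$type == "utr3"],
      exon = gene_model[gene_model$type == "exon"],
      intron = genes,  # body; exon-overlapping peaks matched earlier
      downstream = down)
    assigned <- rep(FALSE, length(peaks))
    for (nm in names(regions)) {
      if (!length(regions[[nm]])) next
      hit <- IRanges::overlapsAny(peaks, regions[[nm]], ignore.strand = TRUE)
      cat_of[hit & !assigned] <- nm
      assigned <- assigned | hit
    }
  }
  pct <- 100 * table(factor(cat_of, levels = categories)) / length(peaks)
  list(annotation = data.frame(peak_id = names(peaks), category = cat_of),
       percentages = c(pct))
}
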