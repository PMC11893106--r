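.BASES <- c("A", "C", "G", "T")

.encodeSeqs <- function(seqs) {
  # concatenated integer encoding, A=1..T=4, anything else (N) = 5
  s <- paste(seqs, collapse = "")
  enc <- match(strsplit(s, "")[[1]], .BASES)
  enc[is.na(enc)] <- 5L
  enc
}

.revcompPWM <- function(pwm) pwm[4:1, rev(seq_len(ncol(pwm))), drop = FALSE]

#' Scan peak sequences with position weight matrices
#'
#' Slides each motif's log-odds matrix over both strands of every sequence.
#' A window is a hit iff its score reaches `threshold_frac` of the motif's
#' maximum achievable score; N bases contribute 0 (the background odds).
#' Sequences shorter than the motif yield no hit. Hit offsets are 0-based
#' relative to the peak start and always refer to the plus-strand
#' coordinate of the matched window.
#'
#' @param seqs `DNAStringSet` or named character vector of peak sequences.
#' @param motifs a [MotifSet-class].
#' @param threshold_frac fraction of the maximum log-odds score required
#'   (default 0.8).
#' @return list of class `"HitMatrix"`: `hits` (peak x motif logical sparse
#'   matrix), `positions` (data.frame `peak_id`, `motif_id`, `offset`,
#'   `strand`, `score`), and the scan parameters.
#' @export
scanPeaks <- function(seqs, motifs, threshold_frac = 0.8) {
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  ids <- names(seqs)
  if (is.null(ids)) stop("sequences must be named by peak id")
  widths <- nchar(seqs)
  enc <- .encodeSeqs(seqs)
  n_total <- length(enc)
  starts <- cumsum(c(1L, widths[-length(widths)]))  # global start per peak
  peak_of <- rep(seq_along(seqs), widths)
  mids <- names(motifs)
  hits <- Matrix::Matrix(FALSE, length(seqs), length(motifs), sparse = TRUE,
                         dimnames = list(ids, mids))
  pos <- list()
  for (k in seq_along(motifs@motifs)) {
    m <- motifs@motifs[[k]]
    L <- ncol(m$logodds)
    if (L > n_total) next
    maxsc <- sum(apply(m$logodds, 2, max))
    thr <- threshold_frac * maxsc
    for (strand in c("+", "-")) {
      pwm <- if (strand == "+") m$logodds else .revcompPWM(m$logodds)
      lut <- rbind(pwm, 0)  # row 5: N scores as background
      nw <- n_total - L + 1L
      sc <- lut[enc[seq_len(nw)], 1L]
      for (j in 2:L) sc <- sc + lut[enc[j:(nw + j - 1L)], j]
      ok <- which(sc >= thr)
      # discard windows crossing a peak boundary
      ok <- ok[peak_of[ok] == peak_of[ok + L - 1L]]
      if (!length(ok)) next
      pk <- peak_of[ok]
      hits[cbind(pk, k)] <- TRUE
      pos[[length(pos) + 1L]] <- data.frame(
        peak_id = ids[pk], motif_id = m$id, offset = ok - starts[pk],
        strand = strand, score = sc[ok])
    }
  }
  positions <- if (length(pos)) do.call(rbind, pos)
  else data.frame(peak_id = character(0), motif_id = character(0),
                  offset = integer(0), strand = character(0),
                  score = numeric(0))
  structure(list(hits = hits, positions = positions,
                 threshold_frac = threshold_frac,
                 pseudocount = motifs@pseudocount,
                 background = motifs@background),
            class = "HitMatrix")
}

#' @export
print.HitMatrix <- function(x, ...) {
  cat(sprintf("HitMatrix: %d peaks x %d motifs, %d hit peaks-motif pairs (threshold %.0f%% of max score)\n",
              nrow(x$hits), ncol(x$hits), sum(x$hits), 100 * x$threshold_frac))
  invisible(x)
}

#' GC-matched hypergeometric motif enrichment
#'
#' Tests, per motif, whether query peaks carry the motif more often than
#' expected from the (query + background) universe, with an upper-tail
#' hypergeometric p. The background is conventionally built by pooling
#' [matchBackgroundPeaks()] selections over the query peaks and removing
#' duplicates (see [pooledBackground()]).
#'
#' @param query_peaks,background_peaks peak-id vectors; the background must
#'   be disjoint from the query or a superset of it (the mode is recorded).
#' @param hits a [scanPeaks()] result (or its logical peak x motif matrix).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return data.frame per motif: `motif_id`, `n_query_hits`, `n_bg_hits`,
#'   `fold_enrichment`, `p_value`, `p_adj`, `enriched`; sorted by p.
#' @export
motifEnrichment <- function(query_peaks, background_peaks, hits,
                            alpha = 0.05) {
  H <- if (inherits(hits, "HitMatrix")) hits$hits else hits
  if (all(query_peaks %in% background_peaks)) {
    mode <- "superset"
    bg_only <- setdiff(background_peaks, query_peaks)
  } else if (!length(intersect(query_peaks, background_peaks))) {
    mode <- "disjoint"
    bg_only <- background_peaks
  } else {
    stop("background must be disjoint from the query or a superset of it")
  }
  universe <- c(query_peaks, bg_only)
  Hq <- H[query_peaks, , drop = FALSE]
  Hb <- H[bg_only, , drop = FALSE]
  k <- Matrix::colSums(Hq)
  kb <- Matrix::colSums(Hb)
  K <- k + kb
  N <- length(universe); nq <- length(query_peaks)
  p <- stats::phyper(k - 1, K, N - K, nq, lower.tail = FALSE)
  qrate <- k / nq
  brate <- kb / max(length(bg_only), 1)
  fold <- ifelse(brate > 0, qrate / brate, ifelse(qrate > 0, Inf, NaN))
  out <- data.frame(motif_id = colnames(H), n_query_hits = as.integer(k),
                    n_bg_hits = as.integer(kb), fold_enrichment = fold,
                    p_value = p, p_adj = bhAdjust(p))
  out$enriched <- out$p_adj < alpha
  attr(out, "background_mode") <- mode
  out[order(out$p_value, -out$fold_enrichment), , drop = FALSE]
}

#' Pooled, de-duplicated matched background for a peak set
#'
#' @param features per-peak matching features (see [matchBackgroundPeaks()]).
#' @param query_peaks peak ids whose matched backgrounds are pooled.
#' @param n_background matched peaks per query before pooling.
#' @param seed passed through.
#' @return character vector of background peak ids (disjoint from the query).
#' @export
pooledBackground <- function(features, query_peaks, n_background = 200,
                             seed = 1L) {
  bg <- matchBackgroundPeaks(features, query = query_peaks,
                             n_background = n_background, seed = seed)
  setdiff(unique(as.vector(bg)), query_peaks)
}

#' Per-cell motif activity deviations
#'
#' For motif m and cell c with observed counts `X_mc` summed over the
#' motif's peaks, the expected counts are
#' `E_mc = (sum of motif-peak totals / total counts) * cell depth`, and the
#' raw deviation is `Y_mc = (X_mc - E_mc) / E_mc`. For each of
#' `n_background_sets` iterations every peak is replaced by one of its
#' matched background peaks (same GC/accessibility/width neighborhood) and
#' the background deviations are recomputed; the bias-corrected deviation is
#' `Y - mean(background Y)` and the deviation z-score divides by the
#' background standard deviation.
#'
#' @param atac_counts raw peak x cell count matrix.
#' @param hits a [scanPeaks()] result or logical peak x motif matrix.
#' @param features per-peak matching features (see
#'   [matchBackgroundPeaks()]).
#' @param n_background_sets background iterations (default 50).
#' @param n_background size of each peak's matched pool (default 200).
#' @param seed integer seed for the background draws.
#' @return list of class `"DeviationMatrix"`: `raw` and `z` (motif x cell
#'   matrices), `dropped` motif ids.
#' @export
chromvarDeviations <- function(atac_counts, hits, features,
                               n_background_sets = 50, n_background = 200,
                               seed = 1L) {
  M <- if (inherits(hits, "HitMatrix")) hits$hits else hits
  M <- as(M, "dMatrix") * 1
  stopifnot(identical(rownames(M), rownames(atac_counts)))
  d <- Matrix::colSums(atac_counts)
  if (any(d == 0)) stop("cell(s) with zero ATAC counts present")
  a <- Matrix::rowSums(atac_counts)
  tot <- sum(a)
  motif_tot <- as.vector(Matrix::crossprod(M, a))
  drop <- motif_tot == 0 | Matrix::colSums(M) == 0
  dropped_ids <- colnames(M)[drop]
  if (any(drop))
    warning("dropping motif(s) with no counts in their peaks: ",
            paste(dropped_ids, collapse = ", "))
  M <- M[, !drop, drop = FALSE]
  motif_tot <- motif_tot[!drop]
  devOf <- function(Mm) {
    X <- as.matrix(Matrix::crossprod(Mm, atac_counts))
    E <- (as.vector(Matrix::crossprod(Mm, a)) / tot) %o% d
    (X - E) / E
  }
  Y <- devOf(M)
  pool <- matchBackgroundPeaks(features, n_background = n_background,
                               seed = seed)
  pool_idx <- matrix(match(pool, rownames(M)), nrow(pool), ncol(pool))
  set.seed(seed)
  tr <- Matrix::summary(M)
  bg_mean <- 0 * Y
  bg_m2 <- 0 * Y
  for (it in seq_len(n_background_sets)) {
    draw <- pool_idx[cbind(seq_len(nrow(M)),
                           sample.int(ncol(pool_idx), nrow(M), replace = TRUE))]
    Mi <- Matrix::sparseMatrix(i = draw[tr$i], j = tr$j, x = 1,
                               dims = dim(M), dimnames = dimnames(M))
    Yi <- devOf(Mi)
    bg_mean <- bg_mean + Yi
    bg_m2 <- bg_m2 + Yi^2
  }
  bg_mean <- bg_mean / n_background_sets
  bg_sd <- sqrt(pmax(bg_m2 / n_background_sets - bg_mean^2, 0) *
                  n_background_sets / (n_background_sets - 1))
  corrected <- Y - bg_mean
  z <- corrected / bg_sd
  z[!is.finite(z)] <- 0
  structure(list(raw = Y, corrected = corrected, z = z,
                 dropped = dropped_ids,
                 n_background_sets = n_background_sets, seed = seed),
            class = "DeviationMatrix")
}

#' Mean motif activity per cell group
#'
#' @param dev a [chromvarDeviations()] result (or a motif x cell z matrix).
#' @param groups per-cell group labels aligned with the columns.
#' @return motif x group matrix of mean deviation z-scores.
#' @export
motifActivity <- function(dev, groups) {
  z <- if (inherits(dev, "DeviationMatrix")) dev$z else dev
  groups <- as.factor(groups)
  out <- sapply(levels(groups), function(g)
    rowMeans(z[, groups == g, drop = FALSE]))
  out
}
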