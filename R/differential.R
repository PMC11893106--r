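#' Log2 fold change and percent-expressing per feature
#'
#' The fold change is computed on de-normalized means:
#' `log2((mean(expm1(x'_A)) + pseudocount) / (mean(expm1(x'_B)) + pseudocount))`.
#' `pct_1`/`pct_2` are the fractions of group cells with raw count > 0.
#'
#' @param norm_expr normalized feature x cell matrix (natural-log scale).
#' @param raw_counts raw feature x cell count matrix (for the pct columns).
#' @param cells_a,cells_b disjoint non-empty cell-id vectors.
#' @param pseudocount added to both de-normalized means (default 1).
#' @return data.frame: `feature_id`, `log2fc`, `pct_1`, `pct_2`.
#' @export
foldChangeAndPct <- function(norm_expr, raw_counts, cells_a, cells_b,
                             pseudocount = 1) {
  stopifnot(length(cells_a) > 0, length(cells_b) > 0,
            length(intersect(cells_a, cells_b)) == 0)
  ma <- Matrix::rowMeans(expm1(norm_expr[, cells_a, drop = FALSE]))
  mb <- Matrix::rowMeans(expm1(norm_expr[, cells_b, drop = FALSE]))
  pct1 <- Matrix::rowMeans(raw_counts[, cells_a, drop = FALSE] > 0)
  pct2 <- Matrix::rowMeans(raw_counts[, cells_b, drop = FALSE] > 0)
  data.frame(feature_id = rownames(norm_expr),
             log2fc = log2((ma + pseudocount) / (mb + pseudocount)),
             pct_1 = pct1, pct_2 = pct2, row.names = rownames(norm_expr))
}

#' Two-sided Wilcoxon rank-sum test per feature
#'
#' Exact when both groups together contain at most `exact_max` cells and the
#' feature has no ties; otherwise the tie-corrected normal approximation
#' with continuity correction. A feature constant across both groups has
#' p = 1.
#'
#' @param expr feature x cell matrix (normalized values).
#' @param cells_a,cells_b disjoint cell-id vectors, each of size >= 3.
#' @param features optional subset of features to test.
#' @param exact_max combined group size up to which the exact null
#'   distribution is used (default 20).
#' @return named numeric vector of p-values.
#' @export
wilcoxonTest <- function(expr, cells_a, cells_b, features = NULL,
                         exact_max = 20) {
  stopifnot(length(cells_a) >= 3, length(cells_b) >= 3)
  if (is.null(features)) features <- rownames(expr)
  m <- as.matrix(expr[features, c(cells_a, cells_b), drop = FALSE])
  na <- length(cells_a); nb <- length(cells_b)
  p <- apply(m, 1, function(x) .wilcoxP(x[seq_len(na)],
                                        x[na + seq_len(nb)], exact_max))
  stats::setNames(p, features)
}

.wilcoxP <- function(a, b, exact_max = 20) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- table(r)
  mu <- na * nb / 2
  if ((na + nb) <= exact_max) {
    # exact two-sided p by enumeration of all group assignments of the
    # observed ranks (valid with and without ties)
    combs <- utils::combn(na + nb, na)
    us <- colSums(matrix(r[combs], na)) - na * (na + 1) / 2
    return(mean(abs(us - mu) >= abs(u - mu) - 1e-12))
  }
  n <- na + nb
  sigma2 <- (na * nb / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement.
#'
#' @param p p-values in \[0, 1\].
#' @return adjusted p-values in input order.
#' @export
bhAdjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Differential features between two cell groups
#'
#' Features are pre-filtered to `max(pct_1, pct_2) >= min_pct` and a
#' fold-change gate (|log2fc| when `direction = "both"`, signed otherwise);
#' survivors are Wilcoxon-tested and BH-adjusted within this comparison.
#'
#' @param norm_expr,raw_counts feature x cell matrices (normalized / raw).
#' @param cells_a,cells_b disjoint cell groups; `cells_a` is the group whose
#'   enrichment has positive sign.
#' @param min_pct minimum fraction expressing in either group (genes: 0.25;
#'   peaks: 0.001).
#' @param logfc_threshold minimum log2 fold change (genes: 0.25; peaks: 0.1).
#' @param alpha adjusted-p significance level (default 0.05).
#' @param direction "both" for two-sided gating, "up" ("down") to keep only
#'   features enriched in `cells_a` (`cells_b`).
#' @param pseudocount passed to [foldChangeAndPct()].
#' @return data.frame: `feature_id`, `log2fc`, `pct_1`, `pct_2`, `p_value`,
#'   `p_adj`, `group_up`, `significant`; empty when no feature survives the
#'   gates.
#' @export
findMarkers <- function(norm_expr, raw_counts, cells_a, cells_b,
                        min_pct = 0.25, logfc_threshold = 0.25, alpha = 0.05,
                        direction = c("both", "up", "down"),
                        pseudocount = 1) {
  direction <- match.arg(direction)
  stopifnot(min_pct >= 0, logfc_threshold >= 0)
  fc <- foldChangeAndPct(norm_expr, raw_counts, cells_a, cells_b, pseudocount)
  gate <- pmax(fc$pct_1, fc$pct_2) >= min_pct
  gate <- gate & switch(direction,
                        both = abs(fc$log2fc) >= logfc_threshold,
                        up = fc$log2fc >= logfc_threshold,
                        down = fc$log2fc <= -logfc_threshold)
  fc <- fc[gate, , drop = FALSE]
  if (!nrow(fc))
    return(data.frame(feature_id = character(0), log2fc = numeric(0),
                      pct_1 = numeric(0), pct_2 = numeric(0),
                      p_value = numeric(0), p_adj = numeric(0),
                      group_up = character(0), significant = logical(0)))
  p <- wilcoxonTest(norm_expr, cells_a, cells_b, features = fc$feature_id)
  fc$p_value <- unname(p)
  fc$p_adj <- bhAdjust(fc$p_value)
  fc$group_up <- ifelse(fc$log2fc >= 0, "A", "B")
  fc$significant <- fc$p_adj < alpha
  fc[order(fc$p_value, -abs(fc$log2fc)), , drop = FALSE]
}
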