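.subunits <- function(x) strsplit(x, ";", fixed = TRUE)[[1]]

#' Ligand-receptor pair mean expression between two clusters
#'
#' Complex expression in a cluster is the minimum over subunits of the
#' cluster mean (a complex is only as available as its weakest subunit).
#' A pair is testable only if every ligand subunit is expressed in at least
#' `min_frac` of sender cells and every receptor subunit in at least
#' `min_frac` of receiver cells; the score is the arithmetic mean of the
#' ligand (sender) and receptor (receiver) cluster means.
#'
#' @param norm_expr normalized gene x cell matrix.
#' @param clusters per-cell cluster labels (aligned with columns).
#' @param pair one row of a ligand-receptor table (`pair_id`, `ligand`,
#'   `receptor` with `;`-separated subunits).
#' @param sender,receiver cluster labels.
#' @param min_frac expression-fraction threshold (default 0.10).
#' @return list: `mean_expr` (or `NA`), `excluded` flag, `reason`.
#' @export
lrMean <- function(norm_expr, clusters, pair, sender, receiver,
                   min_frac = 0.10) {
  lig <- .subunits(pair$ligand)
  rec <- .subunits(pair$receptor)
  absent <- setdiff(c(lig, rec), rownames(norm_expr))
  if (length(absent))
    return(list(mean_expr = NA_real_, excluded = TRUE,
                reason = "missing gene"))
  s_cells <- clusters == sender
  r_cells <- clusters == receiver
  lig_m <- norm_expr[lig, s_cells, drop = FALSE]
  rec_m <- norm_expr[rec, r_cells, drop = FALSE]
  if (any(Matrix::rowMeans(lig_m > 0) < min_frac) ||
      any(Matrix::rowMeans(rec_m > 0) < min_frac))
    return(list(mean_expr = NA_real_, excluded = TRUE,
                reason = "below min_frac"))
  lv <- min(Matrix::rowMeans(lig_m))
  rv <- min(Matrix::rowMeans(rec_m))
  list(mean_expr = (lv + rv) / 2, excluded = FALSE, reason = NA_character_)
}

#' Permutation test for ligand-receptor interactions
#'
#' The null distribution of each pair's mean expression is built by
#' shuffling cluster labels over cells `n_perm` times; the add-one p-value
#' is `(1 + #(null >= observed)) / (1 + n_perm)`. Pairs excluded by the
#' expression-fraction gate (or missing genes) are reported with their
#' reason and no p-value.
#'
#' @param norm_expr normalized gene x cell matrix.
#' @param clusters per-cell cluster labels.
#' @param pairs ligand-receptor table ([readLRPairs()] layout).
#' @param sender,receiver cluster labels (clusters of fewer than 3 cells
#'   exclude all pairs with a warning).
#' @param n_perm permutations (default 1000).
#' @param min_frac expression-fraction threshold (default 0.10).
#' @param seed integer seed (recorded in the output).
#' @param alpha significance level (default 0.05).
#' @return data.frame per pair: `pair_id`, `pathway_label`, `sender`,
#'   `receiver`, `mean_expr`, `p_value`, `significant`, `excluded`,
#'   `reason`.
#' @export
lrPermutationTest <- function(norm_expr, clusters, pairs, sender, receiver,
                              n_perm = 1000, min_frac = 0.10, seed = 1L,
                              alpha = 0.05) {
  if (length(unique(clusters)) < 2)
    stop("at least two clusters are required")
  small <- sum(clusters == sender) < 3 || sum(clusters == receiver) < 3
  if (small)
    warning("sender or receiver cluster has fewer than 3 cells; ",
            "all pairs excluded")
  obs <- lapply(seq_len(nrow(pairs)), function(i) {
    if (small)
      return(list(mean_expr = NA_real_, excluded = TRUE,
                  reason = "cluster too small"))
    lrMean(norm_expr, clusters, pairs[i, ], sender, receiver, min_frac)
  })
  out <- data.frame(pair_id = pairs$pair_id,
                    pathway_label = pairs$pathway_label,
                    sender = sender, receiver = receiver,
                    mean_expr = vapply(obs, `[[`, 0, "mean_expr"),
                    p_value = NA_real_, significant = FALSE,
                    excluded = vapply(obs, `[[`, TRUE, "excluded"),
                    reason = vapply(obs, `[[`, "", "reason"))
  testable <- which(!out$excluded)
  if (length(testable)) {
    genes <- unique(unlist(lapply(testable, function(i)
      c(.subunits(pairs$ligand[i]), .subunits(pairs$receptor[i])))))
    sub <- as.matrix(norm_expr[genes, , drop = FALSE])
    set.seed(seed)
    exceed <- numeric(length(testable))
    lig_list <- lapply(testable, function(i) .subunits(pairs$ligand[i]))
    rec_list <- lapply(testable, function(i) .subunits(pairs$receptor[i]))
    for (b in seq_len(n_perm)) {
      perm <- clusters[sample.int(length(clusters))]
      sm <- rowMeans(sub[, perm == sender, drop = FALSE])
      rm_ <- rowMeans(sub[, perm == receiver, drop = FALSE])
      null_stat <- vapply(seq_along(testable), function(j)
        (min(sm[lig_list[[j]]]) + min(rm_[rec_list[[j]]])) / 2, 0)
      exceed <- exceed + (null_stat >= out$mean_expr[testable])
    }
    out$p_value[testable] <- (1 + exceed) / (1 + n_perm)
    out$significant[testable] <- out$p_value[testable] < alpha
  }
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  out
}

#' Interaction counts and cross-sex overlaps
#'
#' @param results named list of [lrPermutationTest()] tables, one per group;
#'   names like `"XX.E13.5"` (sex and stage separated by the first `.`).
#' @return list: `counts_per_group`, `counts_per_pathway` (pathway x group),
#'   and `overlaps` (per stage: XX-only, shared, XY-only significant pair
#'   ids).
#' @export
countAndOverlap <- function(results) {
  sig <- lapply(results, function(r) r$pair_id[r$significant])
  counts <- vapply(sig, length, 0L)
  pw <- sort(unique(unlist(lapply(results, `[[`, "pathway_label"))))
  per_pw <- sapply(results, function(r)
    vapply(pw, function(p) sum(r$significant & r$pathway_label == p), 0L))
  if (is.null(dim(per_pw))) per_pw <- matrix(per_pw, nrow = length(pw),
                                             dimnames = list(pw, names(results)))
  sexes <- sub("\\..*$", "", names(results))
  stages <- sub("^[^.]*\\.", "", names(results))
  overlaps <- list()
  for (st in unique(stages)) {
    xx <- unlist(sig[sexes == "XX" & stages == st], use.names = FALSE)
    xy <- unlist(sig[sexes == "XY" & stages == st], use.names = FALSE)
    overlaps[[st]] <- list(xx_only = sort(setdiff(xx, xy)),
                           shared = sort(intersect(xx, xy)),
                           xy_only = sort(setdiff(xy, xx)))
  }
  list(counts_per_group = counts, counts_per_pathway = per_pw,
       overlaps = overlaps)
}
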