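#' Log-normalize RNA counts
#'
#' `x' = ln(1 + scale_factor * x / colsum)`.
#'
#' @param counts gene x cell count matrix (sparse or dense).
#' @param scale_factor library-size target (default 10,000).
#' @return sparse normalized matrix with the input dimnames.
#' @export
logNormalize <- function(counts, scale_factor = 1e4) {
  stopifnot(scale_factor > 0)
  cs <- Matrix::colSums(counts)
  if (any(cs == 0))
    stop("all-zero cell(s) present; remove them with QC filtering first")
  out <- as(as(counts, "dMatrix"), "CsparseMatrix")
  out@x <- log1p(scale_factor * out@x / rep.int(cs, diff(out@p)))
  out
}

#' An embedding of cells
#'
#' @param coords cell x dim matrix.
#' @param modality "rna", "atac" or "joint".
#' @param dims_used indices of coordinates intended for downstream use.
#' @param depth_correlation optional per-dimension absolute correlation with
#'   per-cell sequencing depth.
#' @return list of class `"Embedding"`.
#' @export
embedding <- function(coords, modality, dims_used = seq_len(ncol(coords)),
                      depth_correlation = NULL) {
  stopifnot(ncol(coords) >= 2, all(is.finite(coords)))
  structure(list(coords = coords, modality = modality, dims_used = dims_used,
                 depth_correlation = depth_correlation),
            class = "Embedding")
}

#' @export
print.Embedding <- function(x, ...) {
  cat(sprintf("Embedding (%s): %d cells x %d dims; dims_used = %s\n",
              x$modality, nrow(x$coords), ncol(x$coords),
              paste(range(x$dims_used), collapse = ":")))
  invisible(x)
}

.truncSVD <- function(m, n_dims, seed = 1L) {
  # deterministic truncated SVD; exact base svd at small scale
  if (min(dim(m)) <= max(3 * n_dims, 100)) {
    s <- svd(as.matrix(m), nu = n_dims, nv = n_dims)
    list(u = s$u, d = s$d[seq_len(n_dims)], v = s$v)
  } else {
    set.seed(seed)
    s <- irlba::irlba(m, nv = n_dims)
    list(u = s$u, d = s$d, v = s$v)
  }
}

.fixSigns <- function(coords, loadings = NULL) {
  # sign convention: the largest-magnitude loading (or coordinate) positive
  ref <- if (is.null(loadings)) coords else loadings
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(ref[, j]))
    if (ref[i, j] < 0) {
      coords[, j] <- -coords[, j]
      if (!is.null(loadings)) ref[, j] <- -ref[, j]
    }
  }
  coords
}

#' TF-IDF / LSI embedding of ATAC counts
#'
#' Term frequency = count / cell total; inverse document frequency =
#' n_cells / number of cells in which the peak is observed; the transformed
#' value is `ln(1 + 10^4 * TF * IDF)`. Peaks with zero total count are
#' excluded. A truncated SVD yields the embedding; per-dimension absolute
#' correlation with per-cell depth is reported so callers can drop
#' depth-driven components (conventionally dimension 1, hence the default
#' `dims_used = 2:n_dims`).
#'
#' @param atac_counts peak x cell count matrix.
#' @param n_dims number of singular vectors (default 30).
#' @param seed seed for the truncated SVD.
#' @return an [embedding()] with modality "atac".
#' @export
tfidfLSI <- function(atac_counts, n_dims = 30, seed = 1L) {
  stopifnot(n_dims < min(dim(atac_counts)))
  keep <- Matrix::rowSums(atac_counts) > 0
  m <- as(as(atac_counts[keep, , drop = FALSE], "dMatrix"), "CsparseMatrix")
  depth <- Matrix::colSums(m)
  if (any(depth == 0)) stop("cell(s) with zero ATAC counts present")
  tf <- m
  tf@x <- tf@x / rep.int(depth, diff(tf@p))
  idf <- ncol(m) / Matrix::rowSums(m > 0)
  vals <- tf
  vals@x <- log1p(1e4 * tf@x * idf[tf@i + 1L])
  s <- .truncSVD(Matrix::t(vals), n_dims, seed)  # cells x peaks
  coords <- s$u %*% diag(s$d, n_dims)
  coords <- .fixSigns(coords, s$v)
  rownames(coords) <- colnames(atac_counts)
  colnames(coords) <- paste0("LSI_", seq_len(n_dims))
  dc <- abs(apply(coords, 2, function(x)
    if (stats::sd(x) == 0 || stats::sd(depth) == 0) 0
    else stats::cor(x, depth)))
  embedding(coords, "atac", dims_used = 2:n_dims, depth_correlation = dc)
}

#' PCA embedding of normalized RNA
#'
#' Genes are centered (and unit-scaled when `scale = TRUE`); the top
#' `n_dims` principal components by variance are returned with a fixed sign
#' convention (largest-magnitude gene loading positive).
#'
#' @param norm_expr normalized gene x cell matrix.
#' @param n_dims number of components (default 18).
#' @param scale unit-scale genes before the decomposition.
#' @param seed seed for the truncated SVD.
#' @return an [embedding()] with modality "rna".
#' @export
pcaEmbed <- function(norm_expr, n_dims = 18, scale = FALSE, seed = 1L) {
  stopifnot(n_dims >= 2)
  x <- as.matrix(Matrix::t(norm_expr))  # cells x genes
  x <- scale(x, center = TRUE, scale = scale)
  if (scale) x[, attr(x, "scaled:scale") == 0] <- 0
  x[is.na(x)] <- 0
  if (n_dims > min(dim(x)))
    stop("n_dims exceeds the rank of the matrix")
  s <- .truncSVD(x, n_dims, seed)
  coords <- s$u %*% diag(s$d, n_dims)
  coords <- .fixSigns(coords, s$v)
  rownames(coords) <- colnames(norm_expr)
  colnames(coords) <- paste0("PC_", seq_len(n_dims))
  embedding(coords, "rna")
}

#' Weighted joint embedding of two modalities
#'
#' Each embedding's used dimensions are z-scored per dimension, scaled by
#' the square root of the modality weight, and concatenated. Weight 1 (or 0)
#' reduces to the RNA-only (ATAC-only) embedding up to per-dimension
#' rescaling, so downstream clustering matches the single-modality result.
#'
#' @param rna_emb,atac_emb [embedding()] objects over the same cells in the
#'   same order.
#' @param weight_rna RNA weight in \[0, 1\] (default 0.5).
#' @return an [embedding()] with modality "joint".
#' @export
jointEmbedding <- function(rna_emb, atac_emb, weight_rna = 0.5) {
  stopifnot(weight_rna >= 0, weight_rna <= 1)
  if (!identical(rownames(rna_emb$coords), rownames(atac_emb$coords)))
    stop("cell order differs between the two embeddings")
  zs <- function(e, w) {
    m <- e$coords[, e$dims_used, drop = FALSE]
    m <- scale(m)
    m[, attr(m, "scaled:scale") == 0] <- 0
    m * sqrt(w)
  }
  parts <- list(zs(rna_emb, weight_rna), zs(atac_emb, 1 - weight_rna))
  keep <- c(weight_rna > 0, weight_rna < 1)
  coords <- do.call(cbind, parts[keep])
  embedding(coords, "joint")
}

#' Graph clustering of an embedding
#'
#' Builds a shared-nearest-neighbor graph from Euclidean k-nearest
#' neighbors (Jaccard weights over neighborhoods including the cell itself,
#' pruned below 1/15) and partitions it by modularity-based community
#' detection at the given resolution. Cluster ids are dense from 0, ordered
#' by decreasing size. Deterministic under a fixed seed.
#'
#' @param emb an [embedding()].
#' @param k_neighbors neighborhood size (default 20).
#' @param resolution modularity resolution (default 0.3).
#' @param seed integer seed.
#' @return list of class `"Clustering"`: `labels` (named integer vector),
#'   `resolution`, `modality`, `k_neighbors`, `seed`, `algorithm`.
#' @export
clusterGraph <- function(emb, k_neighbors = 20, resolution = 0.3, seed = 1L) {
  coords <- emb$coords[, emb$dims_used, drop = FALSE]
  n <- nrow(coords)
  if (n <= k_neighbors)
    stop("k_neighbors must be smaller than the number of cells")
  nn <- RANN::nn2(coords, k = k_neighbors + 1)$nn.idx  # includes self
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k_neighbors + 1),
                              j = as.vector(t(nn)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  tri <- Matrix::summary(shared)
  jac <- tri$x / (2 * (k_neighbors + 1) - tri$x)
  keep <- jac >= 1 / 15 & tri$i < tri$j
  g <- igraph::graph_from_data_frame(
    data.frame(from = tri$i[keep], to = tri$j[keep], weight = jac[keep]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 5)
  memb <- igraph::membership(cl)
  memb <- memb[match(seq_len(n), as.integer(names(memb)))]
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  labels <- stats::setNames(as.integer(relab[as.character(memb)]),
                            rownames(coords))
  structure(list(labels = labels, resolution = resolution,
                 modality = emb$modality, k_neighbors = k_neighbors,
                 seed = seed, algorithm = "leiden/modularity"),
            class = "Clustering")
}

#' @export
print.Clustering <- function(x, ...) {
  cat(sprintf("Clustering (%s): %d cells, %d clusters, resolution %.2f\n",
              x$modality, length(x$labels), length(unique(x$labels)),
              x$resolution))
  invisible(x)
}

#' Cluster composition by cell group
#'
#' @param clustering a [clusterGraph()] result (or named label vector).
#' @param groups per-cell group labels (e.g. sex x stage), named by cell or
#'   aligned with the clustering.
#' @return percentage matrix (group x cluster); each row sums to 100.
#' @export
compositionTable <- function(clustering, groups) {
  labels <- if (inherits(clustering, "Clustering")) clustering$labels else clustering
  tab <- table(group = groups, cluster = labels)
  out <- 100 * sweep(unclass(tab), 1, rowSums(tab), "/")
  empty <- rowSums(tab) == 0
  if (any(empty)) {
    warning("empty group(s): ", paste(rownames(tab)[empty], collapse = ", "))
    out[empty, ] <- 0
  }
  out
}
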