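# Shared fixtures: a small simulated dataset (memoized per seed) and toy
# motif constructors used across test files.

.fixture_env <- new.env(parent = emptyenv())

tinyConfig <- function(seed = 1, ...) {
  multiomeConfig(n_cells_per_group = 60, n_genes = 300, n_peaks = 400,
                 n_de_genes_per_stage = c(4, 8, 12),
                 n_da_peaks_per_stage = c(6, 12, 24),
                 n_links_true = 12, sequencing_depth_rna = 3000,
                 sequencing_depth_atac = 1500, seed = seed, ...)
}

tinySim <- function(seed = 1) {
  key <- paste0("sim", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- simulateMultiome(tinyConfig(seed))
  .fixture_env[[key]]
}

# a MotifSet built in code from consensus strings (sharp counts)
toyMotifSet <- function(consensus, ids = NULL, pseudocount = 0.8) {
  if (is.null(ids)) ids <- sprintf("TOY%03d", seq_along(consensus))
  tmp <- tempfile(fileext = ".txt")
  con <- file(tmp, "w")
  for (k in seq_along(consensus)) {
    writeLines(sprintf(">%s\t%s", ids[k], names(consensus)[k] %||% ids[k]), con)
    s <- strsplit(consensus[[k]], "")[[1]]
    for (b in c("A", "C", "G", "T"))
      writeLines(sprintf("%s [ %s ]", b,
                         paste(ifelse(s == b, 97, 1), collapse = " ")), con)
  }
  close(con)
  on.exit(unlink(tmp))
  readJaspar(tmp, pseudocount = pseudocount)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force PWM scan oracle: scores every window on both strands
bruteScan <- function(seqs, motif, threshold_frac = 0.8) {
  lo <- motif$logodds
  L <- ncol(lo)
  maxsc <- sum(apply(lo, 2, max))
  rc <- lo[4:1, rev(seq_len(L)), drop = FALSE]
  hits <- data.frame(peak_id = character(0), offset = integer(0),
                     strand = character(0))
  for (nm in names(seqs)) {
    chars <- strsplit(seqs[[nm]], "")[[1]]
    n <- length(chars)
    if (n < L) next
    for (o in 0:(n - L)) {
      win <- chars[(o + 1):(o + L)]
      for (strand in c("+", "-")) {
        mat <- if (strand == "+") lo else rc
        sc <- 0
        for (j in seq_len(L)) {
          bi <- match(win[j], c("A", "C", "G", "T"))
          sc <- sc + if (is.na(bi)) 0 else mat[bi, j]
        }
        if (sc >= threshold_frac * maxsc)
          hits <- rbind(hits, data.frame(peak_id = nm, offset = o,
                                         strand = strand))
      }
    }
  }
  hits
}

# exhaustive two-sided Mann-Whitney p over all group assignments
enumWilcoxP <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  uObs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  combs <- utils::combn(na + nb, na)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  mean(abs(us - mu) >= abs(uObs - mu) - 1e-12)
}

# direct hypergeometric upper tail by summation
enumHyperP <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
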