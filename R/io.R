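#' @importFrom data.table fread fwrite
#' @importFrom jsonlite write_json read_json
NULL

#' Shipped motif and ligand-receptor fixtures
#'
#' The package ships ten synthetic JASPAR-format position frequency matrices
#' named after transcription factors studied in germ cell sex determination,
#' a motif-to-gene mapping table, and a small ligand-receptor pair list.
#' These are synthetic stand-ins constructed for testing the pipeline, not
#' database extracts.
#'
#' @return `shippedMotifIds()`: character vector of motif ids in fixture
#'   order; `motifTfGene()`: named character vector motif id -> TF gene
#'   symbol; `shippedLRPairs()`: data.frame of ligand-receptor pairs.
#' @export
shippedMotifIds <- function() {
  map <- fread(system.file("extdata", "motif2tf.tsv", package = "pgcMultiome"),
               sep = "\t", header = TRUE, data.table = FALSE)
  map$motif_id
}

#' @rdname shippedMotifIds
#' @param motif_ids motif ids to map to TF gene symbols.
#' @export
motifTfGene <- function(motif_ids) {
  map <- fread(system.file("extdata", "motif2tf.tsv", package = "pgcMultiome"),
               sep = "\t", header = TRUE, data.table = FALSE)
  out <- map$tf_gene[match(motif_ids, map$motif_id)]
  names(out) <- motif_ids
  out
}

#' @rdname shippedMotifIds
#' @export
shippedLRPairs <- function() {
  readLRPairs(system.file("extdata", "lr_pairs.tsv", package = "pgcMultiome"))
}

#' Read a ligand-receptor pair list
#'
#' Tab-separated with header: `pair_id`, `ligand` (subunits separated by
#' `;`), `receptor` (same), `pathway_label`.
#'
#' @param file path to the TSV.
#' @return data.frame with those four character columns.
#' @export
readLRPairs <- function(file) {
  lr <- fread(file, sep = "\t", header = TRUE, data.table = FALSE,
              colClasses = "character")
  need <- c("pair_id", "ligand", "receptor", "pathway_label")
  if (!all(need %in% colnames(lr)))
    stop("ligand-receptor table must have columns ", paste(need, collapse = ", "))
  if (any(!nzchar(lr$ligand)) || any(!nzchar(lr$receptor)))
    stop("ligand/receptor subunit lists must be non-empty")
  lr
}

#' Read gene sets in GMT format
#'
#' @param file path to a GMT file.
#' @return named list of character vectors.
#' @export
readGmt <- function(file) fgsea::gmtPathways(file)

#' Read JASPAR-format position frequency matrices
#'
#' Parses the JASPAR text PFM format: a header line `>ID NAME` followed by
#' four rows `A [ n1 n2 ... ]` (rows A, C, G, T). Counts are converted to
#' probabilities with a total pseudocount split by the background, and to
#' natural-log odds against the background.
#'
#' @param file path to the PFM text file.
#' @param pseudocount total pseudocount added per column (default 0.8),
#'   split across bases proportionally to `background`.
#' @param background numeric(4) background probabilities (A, C, G, T).
#' @return A [MotifSet-class].
#' @export
readJaspar <- function(file, pseudocount = 0.8,
                       background = rep(0.25, 4)) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no '>' header lines found in ", file)
  motifs <- vector("list", length(hdr))
  ends <- c(hdr[-1] - 1L, length(lines))
  for (k in seq_along(hdr)) {
    h <- strsplit(sub("^>", "", lines[hdr[k]]), "[ \t]+")[[1]]
    body <- lines[(hdr[k] + 1L):ends[k]]
    if (length(body) != 4)
      stop(sprintf("motif starting at line %d: expected 4 count rows, found %d",
                   hdr[k], length(body)))
    rows <- lapply(seq_along(body), function(i) {
      ln <- body[i]
      base <- sub("^\\s*([ACGT]).*", "\\1", ln)
      rest <- sub("^\\s*[ACGT]", "", ln)
      nums <- regmatches(rest, gregexpr("[0-9.]+", rest))[[1]]
      if (!base %in% c("A", "C", "G", "T") || !length(nums))
        stop(sprintf("malformed count row at line %d", hdr[k] + i))
      list(base = base, counts = as.numeric(nums))
    })
    lens <- vapply(rows, function(r) length(r$counts), 0L)
    if (length(unique(lens)) != 1)
      stop(sprintf("motif starting at line %d: rows have unequal lengths", hdr[k]))
    pfm <- do.call(rbind, lapply(rows, `[[`, "counts"))
    rownames(pfm) <- vapply(rows, `[[`, "", "base")
    pfm <- pfm[c("A", "C", "G", "T"), , drop = FALSE]
    motifs[[k]] <- .makeMotif(id = h[1],
                              name = if (length(h) > 1) h[2] else h[1],
                              pfm = pfm, pseudocount = pseudocount,
                              background = background)
  }
  new("MotifSet", motifs = motifs, background = background,
      pseudocount = pseudocount)
}

.makeMotif <- function(id, name, pfm, pseudocount, background) {
  prob <- sweep(pfm, 2, colSums(pfm) + pseudocount, "/") +
    (background * pseudocount) / rep(colSums(pfm) + pseudocount,
                                     each = 4)
  logodds <- log(prob / background)
  rownames(prob) <- rownames(logodds) <- c("A", "C", "G", "T")
  cons <- paste(c("A", "C", "G", "T")[apply(prob, 2, which.max)],
                collapse = "")
  list(id = id, name = name, pfm = pfm, prob = prob, logodds = logodds,
       consensus = cons)
}

#' Write a MotifSet in JASPAR text format
#'
#' @param motifs a [MotifSet-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeJaspar <- function(motifs, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (m in motifs@motifs) {
    writeLines(sprintf(">%s\t%s", m$id, m$name), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(m$pfm[b, ], trim = TRUE), collapse = " ")),
                 con)
  }
  invisible(file)
}

#' Write a multiome dataset (and its planted truth) to a directory
#'
#' Emits `rna.mtx` + `genes.tsv` + `barcodes.tsv`, `atac.mtx` + `peaks.bed`
#' (BED3+name, 0-based half-open) + `peak_meta.tsv` + `peaks.fa`,
#' `fragments.tsv`, `cell_meta.tsv`, `truth/*.tsv`, and a `manifest.json`
#' listing every file with its row count. A failed write removes all partial
#' outputs before raising.
#'
#' @param dataset a [MultiomeExperiment-class].
#' @param truth optional [MultiomeTruth-class].
#' @param dir output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
writeMultiome <- function(dataset, truth = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(rel) {
    written <<- c(written, file.path(dir, rel))
    file.path(dir, rel)
  }
  manifest <- list(files = list())
  addf <- function(manifest, rel, n) {
    manifest$files[[rel]] <- list(path = rel, rows = n)
    manifest
  }
  ok <- FALSE
  on.exit(if (!ok) unlink(written, recursive = TRUE), add = TRUE)

  Matrix::writeMM(rnaCounts(dataset), emit("rna.mtx"))
  manifest <- addf(manifest, "rna.mtx", nrow(rnaCounts(dataset)))
  gm <- as.data.frame(geneData(dataset))
  fwrite(gm, emit("genes.tsv"), sep = "\t", na = "NA")
  manifest <- addf(manifest, "genes.tsv", nrow(gm))
  writeLines(colnames(rnaCounts(dataset)), emit("barcodes.tsv"))
  manifest <- addf(manifest, "barcodes.tsv", ncol(rnaCounts(dataset)))

  Matrix::writeMM(atacCounts(dataset), emit("atac.mtx"))
  manifest <- addf(manifest, "atac.mtx", nrow(atacCounts(dataset)))
  pr <- peakRanges(dataset)
  bed <- data.frame(chrom = as.character(GenomicRanges::seqnames(pr)),
                    start = GenomicRanges::start(pr) - 1L,
                    end = GenomicRanges::end(pr),
                    name = names(pr))
  fwrite(bed, emit("peaks.bed"), sep = "\t", col.names = FALSE)
  manifest <- addf(manifest, "peaks.bed", nrow(bed))
  pmeta <- data.frame(peak_id = names(pr), gc_fraction = pr$gc_fraction)
  fwrite(pmeta, emit("peak_meta.tsv"), sep = "\t")
  manifest <- addf(manifest, "peak_meta.tsv", nrow(pmeta))
  if (!is.null(peakSequences(dataset)) && length(peakSequences(dataset))) {
    Biostrings::writeXStringSet(peakSequences(dataset), emit("peaks.fa"))
    manifest <- addf(manifest, "peaks.fa", length(peakSequences(dataset)))
  }
  fwrite(fragments(dataset), emit("fragments.tsv"), sep = "\t")
  manifest <- addf(manifest, "fragments.tsv", nrow(fragments(dataset)))
  cm <- as.data.frame(cellData(dataset))
  fwrite(cm, emit("cell_meta.tsv"), sep = "\t", na = "NA")
  manifest <- addf(manifest, "cell_meta.tsv", nrow(cm))

  if (!is.null(truth)) {
    dir.create(file.path(dir, "truth"), showWarnings = FALSE)
    tabs <- list(de = trueDE(truth), da = trueDA(truth),
                 links = trueLinks(truth), tf_targets = trueTFTargets(truth),
                 motif_positions = plantedMotifPositions(truth),
                 lr = trueLR(truth),
                 sex_of_cell = data.frame(cell = names(sexOfCell(truth)),
                                          sex = unname(sexOfCell(truth))))
    for (nm in names(tabs)) {
      rel <- file.path("truth", paste0(nm, ".tsv"))
      fwrite(tabs[[nm]], emit(rel), sep = "\t", na = "NA")
      manifest <- addf(manifest, rel, nrow(tabs[[nm]]))
    }
  }
  write_json(manifest, emit("manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  ok <- TRUE
  invisible(manifest)
}

#' Read a multiome dataset written by [writeMultiome()]
#'
#' Validates the shared cell index across modalities instead of silently
#' reordering: a `barcodes.tsv` that disagrees with `cell_meta.tsv` is an
#' error. Per-peak GC fractions are recomputed from `peaks.fa` when present,
#' otherwise taken from `peak_meta.tsv`; if both are absent the read fails.
#'
#' @param dir directory containing a `manifest.json`.
#' @return A [MultiomeExperiment-class].
#' @export
readMultiome <- function(dir) {
  if (!file.exists(file.path(dir, "manifest.json")))
    stop("no manifest.json in ", dir, "; not a multiome dataset directory")
  rna <- as(Matrix::readMM(file.path(dir, "rna.mtx")), "CsparseMatrix")
  atac <- as(Matrix::readMM(file.path(dir, "atac.mtx")), "CsparseMatrix")
  gm <- fread(file.path(dir, "genes.tsv"), sep = "\t", header = TRUE,
              data.table = FALSE, na.strings = "NA")
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  cm <- fread(file.path(dir, "cell_meta.tsv"), sep = "\t", header = TRUE,
              data.table = FALSE, na.strings = "NA")
  if (!identical(barcodes, cm$cell_id))
    stop("cell index mismatch: barcodes.tsv does not match cell_meta.tsv ",
         "(refusing to reorder silently)")
  if (ncol(rna) != length(barcodes))
    stop("cell index mismatch: rna.mtx has ", ncol(rna),
         " columns but barcodes.tsv lists ", length(barcodes), " cells")
  if (ncol(atac) != length(barcodes))
    stop("cell index mismatch: atac.mtx has ", ncol(atac),
         " columns but barcodes.tsv lists ", length(barcodes), " cells")
  bed <- fread(file.path(dir, "peaks.bed"), sep = "\t", header = FALSE,
               data.table = FALSE,
               col.names = c("chrom", "start", "end", "name"))
  fa <- file.path(dir, "peaks.fa")
  if (file.exists(fa)) {
    seqs <- Biostrings::readDNAStringSet(fa)
    gc <- as.numeric(Biostrings::letterFrequency(seqs, "GC", as.prob = TRUE))
  } else {
    seqs <- NULL
    pm <- file.path(dir, "peak_meta.tsv")
    if (!file.exists(pm))
      stop("neither peaks.fa nor peak_meta.tsv present: ",
           "gc_fraction unavailable")
    pmeta <- fread(pm, sep = "\t", header = TRUE, data.table = FALSE)
    gc <- pmeta$gc_fraction[match(bed$name, pmeta$peak_id)]
  }
  pr <- GenomicRanges::GRanges(bed$chrom,
                               IRanges::IRanges(start = bed$start + 1L,
                                                end = bed$end),
                               gc_fraction = gc)
  names(pr) <- bed$name
  frags <- fread(file.path(dir, "fragments.tsv"), sep = "\t", header = TRUE,
                 data.table = FALSE)
  dimnames(rna) <- list(gm$gene_id, barcodes)
  dimnames(atac) <- list(bed$name, barcodes)
  rownames(gm) <- gm$gene_id
  rownames(cm) <- cm$cell_id
  MultiomeExperiment(rna = rna, atac = atac, colData = cm, geneData = gm,
                     peakRanges = pr, fragments = frags, peakSeqs = seqs)
}

#' Read the planted truth written by [writeMultiome()]
#'
#' @param dir dataset directory.
#' @return A [MultiomeTruth-class].
#' @export
readMultiomeTruth <- function(dir) {
  td <- file.path(dir, "truth")
  if (!dir.exists(td)) stop("no truth/ directory in ", dir)
  rd <- function(nm) fread(file.path(td, paste0(nm, ".tsv")), sep = "\t",
                           header = TRUE, data.table = FALSE,
                           na.strings = "NA")
  sex <- rd("sex_of_cell")
  new("MultiomeTruth", de = rd("de"), da = rd("da"), links = rd("links"),
      tfTargets = rd("tf_targets"), motifPositions = rd("motif_positions"),
      lr = rd("lr"), sexOfCell = stats::setNames(sex$sex, sex$cell))
}
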