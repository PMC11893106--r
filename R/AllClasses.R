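#' @import methods
#' @importClassesFrom Matrix dgCMatrix
#' @importFrom S4Vectors DataFrame
NULL

setClassUnion("DNAStringSetOrNULL", c("DNAStringSet", "NULL"))

#' Paired single-nucleus multiome container
#'
#' Holds a gene x cell RNA count matrix and a peak x cell ATAC count matrix
#' sharing one cell index, together with per-cell, per-gene and per-peak
#' metadata, the ATAC fragment records, and (optionally) the peak sequences.
#'
#' Peak coordinates are stored as a [GenomicRanges::GRanges] (1-based,
#' closed); on disk (BED, fragments) the package uses 0-based half-open
#' coordinates and converts at the I/O boundary.
#'
#' @slot rna sparse non-negative integer gene x cell matrix.
#' @slot atac sparse non-negative integer peak x cell matrix.
#' @slot colData [S4Vectors::DataFrame] of per-cell metadata (`sex`, `stage`,
#'   `replicate`, `compartment`), row names = cell barcodes.
#' @slot geneData [S4Vectors::DataFrame] of per-gene metadata (`chrom`,
#'   `tss`, `strand`, `gene_end`, `is_chrY`, `is_mito`, `is_marker_of`),
#'   row names = gene ids.
#' @slot peakRanges [GenomicRanges::GRanges], names = peak ids, metadata
#'   column `gc_fraction`.
#' @slot fragments data.frame with columns `cell`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @slot peakSeqs [Biostrings::DNAStringSet] of peak sequences, or `NULL`.
#'
#' @export
setClass("MultiomeExperiment",
  slots = c(
    rna = "dgCMatrix",
    atac = "dgCMatrix",
    colData = "DataFrame",
    geneData = "DataFrame",
    peakRanges = "GRanges",
    fragments = "data.frame",
    peakSeqs = "DNAStringSetOrNULL"
  )
)

setValidity("MultiomeExperiment", function(object) {
  msg <- character()
  cells <- colnames(object@rna)
  if (is.null(cells)) msg <- c(msg, "rna matrix must have cell barcodes as colnames")
  if (!identical(cells, colnames(object@atac)))
    msg <- c(msg, "cell index differs between rna and atac matrices")
  if (!identical(cells, rownames(object@colData)))
    msg <- c(msg, "cell index differs between rna matrix and colData")
  if (!identical(rownames(object@rna), rownames(object@geneData)))
    msg <- c(msg, "gene index differs between rna matrix and geneData")
  if (!identical(rownames(object@atac), names(object@peakRanges)))
    msg <- c(msg, "peak index differs between atac matrix and peakRanges")
  if (is.null(object@peakRanges$gc_fraction))
    msg <- c(msg, "peakRanges must carry a gc_fraction metadata column")
  else if (any(object@peakRanges$gc_fraction < 0 | object@peakRanges$gc_fraction > 1, na.rm = TRUE))
    msg <- c(msg, "gc_fraction must lie in [0, 1]")
  if (length(object@peakRanges) && any(GenomicRanges::width(object@peakRanges) < 1))
    msg <- c(msg, "peak intervals must satisfy start < end")
  need <- c("cell", "chrom", "start", "end")
  if (nrow(object@fragments) && !all(need %in% colnames(object@fragments)))
    msg <- c(msg, "fragments must have columns cell, chrom, start, end")
  if (!is.null(object@peakSeqs) && length(object@peakSeqs) &&
      !identical(names(object@peakSeqs), rownames(object@atac)))
    msg <- c(msg, "peakSeqs names differ from peak index")
  if (length(msg)) msg else TRUE
})

#' Construct a MultiomeExperiment
#'
#' @param rna,atac count matrices (coerced to sparse).
#' @param colData,geneData per-cell / per-gene metadata (coerced to
#'   [S4Vectors::DataFrame]).
#' @param peakRanges `GRanges` of peak intervals with `gc_fraction`.
#' @param fragments fragment records (`cell`, `chrom`, `start`, `end`).
#' @param peakSeqs optional `DNAStringSet` of peak sequences.
#' @return A validated [MultiomeExperiment-class] object.
#' @export
MultiomeExperiment <- function(rna, atac, colData, geneData, peakRanges,
                               fragments = data.frame(cell = character(),
                                                      chrom = character(),
                                                      start = integer(),
                                                      end = integer()),
                               peakSeqs = NULL) {
  new("MultiomeExperiment",
      rna = as(as(as(rna, "dMatrix"), "generalMatrix"), "CsparseMatrix"),
      atac = as(as(as(atac, "dMatrix"), "generalMatrix"), "CsparseMatrix"),
      colData = DataFrame(colData),
      geneData = DataFrame(geneData),
      peakRanges = peakRanges,
      fragments = as.data.frame(fragments),
      peakSeqs = peakSeqs)
}

setMethod("show", "MultiomeExperiment", function(object) {
  cat("MultiomeExperiment\n")
  cat(sprintf("  %d cells; %d genes (RNA); %d peaks (ATAC)\n",
              ncol(object@rna), nrow(object@rna), nrow(object@atac)))
  cat(sprintf("  fragments: %s records\n",
              format(nrow(object@fragments), big.mark = ",")))
  if (!is.null(object@peakSeqs) && length(object@peakSeqs))
    cat("  peak sequences: present\n")
  grp <- table(paste(object@colData$sex, object@colData$stage))
  cat("  groups:", paste(names(grp), "=", as.integer(grp), collapse = "; "), "\n")
})

#' Planted ground truth of a synthetic multiome dataset
#'
#' @slot de data.frame (`gene`, `stage`, `sex_up`, `logfc`) of planted
#'   differentially expressed genes, one row per stage at which the effect
#'   is active.
#' @slot da planted differentially accessible peaks, same layout.
#' @slot links data.frame (`peak`, `gene`) of planted peak-gene couplings.
#' @slot tfTargets data.frame (`motif_id`, `gene`) of planted TF target genes.
#' @slot motifPositions data.frame (`motif_id`, `peak`, `offset`) of planted
#'   consensus insertions (0-based offsets).
#' @slot lr data.frame of planted ligand-receptor pairs
#'   (`pair_id`, `ligand`, `receptor`, `sender`, `receiver`, `sex`).
#' @slot sexOfCell named character vector cell -> XX/XY.
#' @export
setClass("MultiomeTruth",
  slots = c(de = "data.frame", da = "data.frame", links = "data.frame",
            tfTargets = "data.frame", motifPositions = "data.frame",
            lr = "data.frame", sexOfCell = "character"))

setMethod("show", "MultiomeTruth", function(object) {
  cat("MultiomeTruth\n")
  cat(sprintf("  DE genes: %d (rows %d); DA peaks: %d (rows %d)\n",
              length(unique(object@de$gene)), nrow(object@de),
              length(unique(object@da$peak)), nrow(object@da)))
  cat(sprintf("  links: %d; TF target genes: %d; planted motif sites: %d; LR pairs: %d\n",
              nrow(object@links), nrow(object@tfTargets),
              nrow(object@motifPositions), nrow(object@lr)))
})

#' A set of position frequency matrices
#'
#' Each element is a list with fields `id`, `name` (TF name), `pfm` (4 x L
#' count matrix, rows A, C, G, T), `prob` (pseudocount-smoothed column
#' probabilities), `logodds` (natural-log odds versus the background), and
#' `consensus` (maximum-probability base per column).
#'
#' @slot motifs list of motif records as described above.
#' @slot background numeric(4) background base probabilities (A, C, G, T).
#' @slot pseudocount total pseudocount split across bases by background
#'   weight when converting counts to probabilities.
#' @export
setClass("MotifSet",
  slots = c(motifs = "list", background = "numeric", pseudocount = "numeric"))

setValidity("MotifSet", function(object) {
  msg <- character()
  if (length(object@background) != 4 || abs(sum(object@background) - 1) > 1e-8)
    msg <- c(msg, "background must be 4 probabilities summing to 1")
  for (m in object@motifs) {
    if (!is.matrix(m$pfm) || nrow(m$pfm) != 4)
      msg <- c(msg, sprintf("motif %s: pfm must be a 4-row matrix", m$id))
    else if (ncol(m$pfm) < 4)
      msg <- c(msg, sprintf("motif %s: motif length must be >= 4", m$id))
    else if (any(m$pfm < 0))
      msg <- c(msg, sprintf("motif %s: pfm counts must be non-negative", m$id))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "MotifSet", function(object) {
  cat(sprintf("MotifSet of %d motifs (pseudocount %.2f)\n",
              length(object@motifs), object@pseudocount))
  for (m in object@motifs)
    cat(sprintf("  %s %s (%d bp) %s\n", m$id, m$name, ncol(m$pfm), m$consensus))
})

setMethod("length", "MotifSet", function(x) length(x@motifs))
setMethod("names", "MotifSet", function(x) vapply(x@motifs, `[[`, "", "id"))
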