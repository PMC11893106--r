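#' Accessors for MultiomeExperiment and MultiomeTruth
#'
#' @param x a [MultiomeExperiment-class] or [MultiomeTruth-class] object.
#' @param cells character vector of cell barcodes (for `subsetCells`).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("rnaCounts", function(x) standardGeneric("rnaCounts"))
#' @rdname accessors
#' @export
setGeneric("atacCounts", function(x) standardGeneric("atacCounts"))
#' @rdname accessors
#' @export
setGeneric("cellData", function(x) standardGeneric("cellData"))
#' @rdname accessors
#' @export
setGeneric("geneData", function(x) standardGeneric("geneData"))
#' @rdname accessors
#' @export
setGeneric("peakRanges", function(x) standardGeneric("peakRanges"))
#' @rdname accessors
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))
#' @rdname accessors
#' @export
setGeneric("peakSequences", function(x) standardGeneric("peakSequences"))
#' @rdname accessors
#' @export
setGeneric("subsetCells", function(x, cells) standardGeneric("subsetCells"))

#' @rdname accessors
#' @export
setGeneric("trueDE", function(x) standardGeneric("trueDE"))
#' @rdname accessors
#' @export
setGeneric("trueDA", function(x) standardGeneric("trueDA"))
#' @rdname accessors
#' @export
setGeneric("trueLinks", function(x) standardGeneric("trueLinks"))
#' @rdname accessors
#' @export
setGeneric("trueTFTargets", function(x) standardGeneric("trueTFTargets"))
#' @rdname accessors
#' @export
setGeneric("plantedMotifPositions", function(x) standardGeneric("plantedMotifPositions"))
#' @rdname accessors
#' @export
setGeneric("trueLR", function(x) standardGeneric("trueLR"))
#' @rdname accessors
#' @export
setGeneric("sexOfCell", function(x) standardGeneric("sexOfCell"))

#' @rdname accessors
setMethod("rnaCounts", "MultiomeExperiment", function(x) x@rna)
#' @rdname accessors
setMethod("atacCounts", "MultiomeExperiment", function(x) x@atac)
#' @rdname accessors
setMethod("cellData", "MultiomeExperiment", function(x) x@colData)
#' @rdname accessors
setMethod("geneData", "MultiomeExperiment", function(x) x@geneData)
#' @rdname accessors
setMethod("peakRanges", "MultiomeExperiment", function(x) x@peakRanges)
#' @rdname accessors
setMethod("fragments", "MultiomeExperiment", function(x) x@fragments)
#' @rdname accessors
setMethod("peakSequences", "MultiomeExperiment", function(x) x@peakSeqs)

#' @rdname accessors
setMethod("subsetCells", "MultiomeExperiment", function(x, cells) {
  if (!all(cells %in% colnames(x@rna)))
    stop("unknown cell barcodes in subsetCells()")
  fr <- x@fragments
  if (nrow(fr)) fr <- fr[fr$cell %in% cells, , drop = FALSE]
  new("MultiomeExperiment",
      rna = x@rna[, cells, drop = FALSE],
      atac = x@atac[, cells, drop = FALSE],
      colData = x@colData[cells, , drop = FALSE],
      geneData = x@geneData,
      peakRanges = x@peakRanges,
      fragments = fr,
      peakSeqs = x@peakSeqs)
})

#' @rdname accessors
setMethod("trueDE", "MultiomeTruth", function(x) x@de)
#' @rdname accessors
setMethod("trueDA", "MultiomeTruth", function(x) x@da)
#' @rdname accessors
setMethod("trueLinks", "MultiomeTruth", function(x) x@links)
#' @rdname accessors
setMethod("trueTFTargets", "MultiomeTruth", function(x) x@tfTargets)
#' @rdname accessors
setMethod("plantedMotifPositions", "MultiomeTruth", function(x) x@motifPositions)
#' @rdname accessors
setMethod("trueLR", "MultiomeTruth", function(x) x@lr)
#' @rdname accessors
setMethod("sexOfCell", "MultiomeTruth", function(x) x@sexOfCell)
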