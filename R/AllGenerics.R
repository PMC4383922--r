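## Accessors and show methods.  Slot access never appears in user code.

#' @rdname MatureSet-class
#' @param x,object A record-set object.
#' @export
setMethod("length", "MatureSet", function(x) length(x@id))

#' @rdname PrecursorSet-class
#' @export
setMethod("length", "PrecursorSet", function(x) length(x@id))

#' @rdname UtrSet-class
#' @export
setMethod("length", "UtrSet", function(x) length(x@transcriptId))

#' Record-set accessors
#'
#' \code{mirId}, \code{mirName}, \code{mirSpecies}, \code{mirSequence},
#' \code{mirArm}, \code{precursorOf}, \code{matureIdsOf},
#' \code{highConfidenceOf}, \code{transcriptIds}, \code{geneSymbols} extract
#' the corresponding column from a record set.
#'
#' @param x A [MatureSet-class], [PrecursorSet-class] or [UtrSet-class].
#' @return The requested column (character/logical vector or list).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("mirId", function(x) standardGeneric("mirId"))
#' @rdname accessors
#' @export
setGeneric("mirName", function(x) standardGeneric("mirName"))
#' @rdname accessors
#' @export
setGeneric("mirSpecies", function(x) standardGeneric("mirSpecies"))
#' @rdname accessors
#' @export
setGeneric("mirSequence", function(x) standardGeneric("mirSequence"))
#' @rdname accessors
#' @export
setGeneric("mirArm", function(x) standardGeneric("mirArm"))
#' @rdname accessors
#' @export
setGeneric("precursorOf", function(x) standardGeneric("precursorOf"))
#' @rdname accessors
#' @export
setGeneric("matureIdsOf", function(x) standardGeneric("matureIdsOf"))
#' @rdname accessors
#' @export
setGeneric("highConfidenceOf", function(x) standardGeneric("highConfidenceOf"))
#' @rdname accessors
#' @export
setGeneric("transcriptIds", function(x) standardGeneric("transcriptIds"))
#' @rdname accessors
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))

#' @rdname accessors
#' @export
setMethod("mirId", "MatureSet", function(x) x@id)
#' @rdname accessors
#' @export
setMethod("mirId", "PrecursorSet", function(x) x@id)
#' @rdname accessors
#' @export
setMethod("mirName", "MatureSet", function(x) x@name)
#' @rdname accessors
#' @export
setMethod("mirName", "PrecursorSet", function(x) x@name)
#' @rdname accessors
#' @export
setMethod("mirSpecies", "MatureSet", function(x) x@species)
#' @rdname accessors
#' @export
setMethod("mirSpecies", "PrecursorSet", function(x) x@species)
#' @rdname accessors
#' @export
setMethod("mirSpecies", "UtrSet", function(x) x@species)
#' @rdname accessors
#' @export
setMethod("mirSequence", "MatureSet", function(x) {
  stats::setNames(x@sequence, x@id)
})
#' @rdname accessors
#' @export
setMethod("mirSequence", "PrecursorSet", function(x) {
  stats::setNames(x@sequence, x@id)
})
#' @rdname accessors
#' @export
setMethod("mirSequence", "UtrSet", function(x) {
  stats::setNames(x@sequence, x@transcriptId)
})
#' @rdname accessors
#' @export
setMethod("mirArm", "MatureSet", function(x) stats::setNames(x@arm, x@id))
#' @rdname accessors
#' @export
setMethod("precursorOf", "MatureSet", function(x) {
  stats::setNames(x@precursorId, x@id)
})
#' @rdname accessors
#' @export
setMethod("matureIdsOf", "PrecursorSet", function(x) {
  stats::setNames(x@matureIds, x@id)
})
#' @rdname accessors
#' @export
setMethod("highConfidenceOf", "PrecursorSet", function(x) {
  stats::setNames(x@highConfidence, x@id)
})
#' @rdname accessors
#' @export
setMethod("transcriptIds", "UtrSet", function(x) x@transcriptId)
#' @rdname accessors
#' @export
setMethod("geneSymbols", "UtrSet", function(x) {
  stats::setNames(x@geneSymbol, x@transcriptId)
})

#' Subset a record set
#'
#' @param x A record set.
#' @param i Index vector (integer, logical or id/transcript-id character).
#' @param j,...,drop Ignored.
#' @return A record set of the same class.
#' @rdname subset-methods
#' @export
setMethod("[", "MatureSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@id)
  initialize(x, id = x@id[i], name = x@name[i], species = x@species[i],
             sequence = x@sequence[i], precursorId = x@precursorId[i],
             arm = x@arm[i])
})

#' @rdname subset-methods
#' @export
setMethod("[", "PrecursorSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@id)
  initialize(x, id = x@id[i], name = x@name[i],
             historicalNames = x@historicalNames[i], species = x@species[i],
             sequence = x@sequence[i], matureIds = x@matureIds[i],
             highConfidence = x@highConfidence[i])
})

#' @rdname subset-methods
#' @export
setMethod("[", "UtrSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@transcriptId)
  initialize(x, transcriptId = x@transcriptId[i],
             geneSymbol = x@geneSymbol[i], description = x@description[i],
             species = x@species[i], sequence = x@sequence[i])
})

#' Library sizes of an expression table
#'
#' @param x A [MirExpression-class] object.
#' @return Named numeric vector of total mapped reads per experiment.
#' @export
setGeneric("librarySizes", function(x) standardGeneric("librarySizes"))

#' @rdname librarySizes
#' @export
setMethod("librarySizes", "MirExpression", function(x) {
  stats::setNames(SummarizedExperiment::colData(x)$librarySize, colnames(x))
})

#' PubMed record ids associated with a precursor
#'
#' @param x A [PubmedMap-class].
#' @param id Precursor id (or name used as key).
#' @return Sorted integer vector of distinct PubMed ids (empty if unknown).
#' @export
setGeneric("pubmedIds", function(x, id) standardGeneric("pubmedIds"))

#' @rdname pubmedIds
#' @export
setMethod("pubmedIds", "PubmedMap", function(x, id) {
  v <- x@associations[[id]]
  if (is.null(v)) integer() else v
})

#' @rdname pubmedIds
#' @param keys For \code{pubmedKeys}, none; returns all map keys.
#' @export
setGeneric("pubmedKeys", function(x) standardGeneric("pubmedKeys"))

#' @rdname pubmedIds
#' @export
setMethod("pubmedKeys", "PubmedMap", function(x) names(x@associations))

setMethod("show", "MatureSet", function(object) {
  cat(sprintf("MatureSet with %d mature miRNAs across %d species\n",
              length(object), length(unique(object@species))))
  if (length(object))
    cat("  e.g.", object@name[1L], paste0("(", object@sequence[1L], ")"), "\n")
})

setMethod("show", "PrecursorSet", function(object) {
  cat(sprintf("PrecursorSet with %d precursors (%d high-confidence)\n",
              length(object), sum(object@highConfidence)))
})

setMethod("show", "UtrSet", function(object) {
  cat(sprintf("UtrSet with %d 3'-UTR sequences (%d-%d nt)\n", length(object),
              if (length(object)) min(nchar(object@sequence)) else 0L,
              if (length(object)) max(nchar(object@sequence)) else 0L))
})

setMethod("show", "PubmedMap", function(object) {
  cat(sprintf("PubmedMap: %d precursors, %d associations\n",
              length(object@associations),
              sum(lengths(object@associations))))
})
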