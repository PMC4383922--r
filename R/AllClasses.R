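## Central S4 containers.  Record sets are column-parallel (one slot per
## field, all the same length), in file order; MirExpression extends
## SummarizedExperiment so the usual assay/colData machinery applies.

setClassUnion("characterOrNULL", c("character", "NULL"))

#' MatureSet: a set of mature miRNA records
#'
#' Column-parallel container for mature miRNAs parsed from a miRBase-style
#' FASTA file.  Sequences are normalized RNA (17--30 nt); the arm is
#' inferred from a \code{-5p}/\code{-3p} name suffix and is one of
#' \code{"5p"}, \code{"3p"} or \code{"unknown"}.
#'
#' @slot id Stable accession strings (e.g. MIMAT0000074).
#' @slot name Current names (e.g. hsa-miR-19b-3p).
#' @slot species Three-letter species codes (see [supportedSpecies()]).
#' @slot sequence Normalized RNA sequences.
#' @slot precursorId Hosting precursor id, or NA before joining.
#' @slot arm One of "5p", "3p", "unknown".
#' @export
setClass("MatureSet", representation(
  id = "character", name = "character", species = "character",
  sequence = "character", precursorId = "character", arm = "character"))

setValidity("MatureSet", function(object) {
  n <- length(object@id)
  lens <- vapply(list(object@name, object@species, object@sequence,
                      object@precursorId, object@arm), length, 0L)
  if (any(lens != n)) return("all slots must have equal length")
  if (any(!object@species %in% supportedSpecies()))
    return("unknown species code")
  if (any(!object@arm %in% c("5p", "3p", "unknown")))
    return("arm must be '5p', '3p' or 'unknown'")
  sl <- nchar(object@sequence)
  if (n && any(sl < 17L | sl > 30L))
    return(sprintf("mature sequence length outside 17-30 nt: '%s'",
                   object@name[which(sl < 17L | sl > 30L)[1L]]))
  if (n && any(grepl("[^ACGU]", object@sequence)))
    return("sequences must be normalized RNA over {A,C,G,U}")
  TRUE
})

#' Construct a MatureSet
#'
#' @param id,name,sequence Character vectors of equal length.
#' @param species Species codes; inferred from name prefixes when NULL.
#' @param precursorId Hosting precursor ids (NA when not yet joined).
#' @param arm Arm labels; inferred from -5p/-3p name suffixes when NULL.
#' @return A [MatureSet-class] object.
#' @export
#' @examples
#' MatureSet(id = "MIMAT0000074", name = "hsa-miR-19b-3p",
#'           sequence = "UGUGCAAAUCCAUGCAAAACUGA")
MatureSet <- function(id = character(), name = character(),
                      sequence = character(), species = NULL,
                      precursorId = rep(NA_character_, length(id)),
                      arm = NULL) {
  sequence <- normalizeRna(sequence)
  if (is.null(species)) species <- speciesFromName(name)
  if (is.null(arm)) {
    arm <- as.character(ifelse(grepl("-5p$", name), "5p",
                               ifelse(grepl("-3p$", name), "3p", "unknown")))
  }
  new("MatureSet", id = as.character(id), name = as.character(name),
      species = species, sequence = sequence,
      precursorId = as.character(precursorId), arm = arm)
}

#' PrecursorSet: a set of hairpin (precursor) miRNA records
#'
#' @slot id Stable accession strings.
#' @slot name Current names (e.g. hsa-mir-19b-1).
#' @slot historicalNames List of character vectors of former names.
#' @slot species Species codes.
#' @slot sequence Normalized RNA hairpin sequences.
#' @slot matureIds List of character vectors (1--2 mature ids after joining).
#' @slot highConfidence Logical flag per precursor.
#' @export
setClass("PrecursorSet", representation(
  id = "character", name = "character", historicalNames = "list",
  species = "character", sequence = "character", matureIds = "list",
  highConfidence = "logical"))

setValidity("PrecursorSet", function(object) {
  n <- length(object@id)
  lens <- c(length(object@name), length(object@historicalNames),
            length(object@species), length(object@sequence),
            length(object@matureIds), length(object@highConfidence))
  if (any(lens != n)) return("all slots must have equal length")
  if (anyDuplicated(object@id)) return("duplicate precursor id")
  if (anyDuplicated(object@name)) return("duplicate precursor name")
  if (any(!object@species %in% supportedSpecies()))
    return("unknown species code")
  if (n && any(grepl("[^ACGU]", object@sequence)))
    return("sequences must be normalized RNA over {A,C,G,U}")
  nm <- lengths(object@matureIds)
  if (any(nm > 2L)) return("a precursor hosts at most 2 mature arms")
  TRUE
})

#' Construct a PrecursorSet
#'
#' @param id,name,sequence Character vectors of equal length.
#' @param species Species codes; inferred from name prefixes when NULL.
#' @param historicalNames List of character vectors (defaults to empty).
#' @param matureIds List of character vectors (defaults to empty; fill with
#'   [attachMatures()]).
#' @param highConfidence Logical vector (defaults to FALSE).
#' @return A [PrecursorSet-class] object.
#' @export
PrecursorSet <- function(id = character(), name = character(),
                         sequence = character(), species = NULL,
                         historicalNames = rep(list(character()), length(id)),
                         matureIds = rep(list(character()), length(id)),
                         highConfidence = rep(FALSE, length(id))) {
  sequence <- normalizeRna(sequence)
  if (is.null(species)) species <- speciesFromName(name)
  new("PrecursorSet", id = as.character(id), name = as.character(name),
      historicalNames = historicalNames, species = species,
      sequence = sequence, matureIds = matureIds,
      highConfidence = highConfidence)
}

#' UtrSet: 3'-UTR target sequences
#'
#' Sequences are normalized to the RNA alphabet internally (RefSeq-style DNA
#' input is accepted).  Headers follow the
#' \code{transcript_id|gene_symbol|description} convention.
#'
#' @slot transcriptId Unique transcript identifiers.
#' @slot geneSymbol Gene symbols (may be empty strings).
#' @slot description Free-text descriptions.
#' @slot species Species codes.
#' @slot sequence Normalized RNA sequences (nonempty).
#' @export
setClass("UtrSet", representation(
  transcriptId = "character", geneSymbol = "character",
  description = "character", species = "character", sequence = "character"))

setValidity("UtrSet", function(object) {
  n <- length(object@transcriptId)
  lens <- c(length(object@geneSymbol), length(object@description),
            length(object@species), length(object@sequence))
  if (any(lens != n)) return("all slots must have equal length")
  if (anyDuplicated(object@transcriptId))
    return("duplicate transcript_id in UTR set")
  if (n && any(nchar(object@sequence) == 0L))
    return("empty UTR sequence")
  if (any(!object@species %in% supportedSpecies()))
    return("unknown species code")
  TRUE
})

#' Construct a UtrSet
#'
#' @param transcriptId,sequence Character vectors of equal length.
#' @param geneSymbol,description Annotation columns (default empty strings).
#' @param species Species code(s), recycled.
#' @return A [UtrSet-class] object.
#' @export
UtrSet <- function(transcriptId = character(), sequence = character(),
                   geneSymbol = rep("", length(transcriptId)),
                   description = rep("", length(transcriptId)),
                   species = rep("hsa", length(transcriptId))) {
  new("UtrSet", transcriptId = as.character(transcriptId),
      geneSymbol = as.character(geneSymbol),
      description = as.character(description),
      species = rep(species, length.out = length(transcriptId)),
      sequence = normalizeRna(sequence))
}

#' MirExpression: mature-miRNA read counts with library sizes
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose \code{counts} assay
#' holds nonnegative integer read counts (rows = mature ids, columns =
#' experiments) and whose \code{colData} carries a \code{librarySize} column
#' of total mapped reads per experiment.  Every library size must be at
#' least the column sum of counts for that experiment.
#'
#' @export
setClass("MirExpression", contains = "SummarizedExperiment")

setValidity("MirExpression", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  cts <- SummarizedExperiment::assay(object, "counts")
  if (any(cts < 0)) return("negative count")
  if (any(cts != round(cts))) return("non-integer count")
  cd <- SummarizedExperiment::colData(object)
  if (!"librarySize" %in% colnames(cd))
    return("colData column 'librarySize' is required")
  ls <- cd$librarySize
  if (any(ls <= 0)) return("library sizes must be positive")
  if (ncol(cts) && any(ls < colSums(cts)))
    return("library size smaller than column sum of counts")
  TRUE
})

#' Construct a MirExpression table
#'
#' @param counts Integer matrix, rows named by mature id, columns by
#'   experiment id.
#' @param librarySizes Positive totals per experiment, in column order (or
#'   named by experiment).  When NULL, defaults to the column sums with a
#'   warning, which is the natural lower bound.
#' @return A [MirExpression-class] object.
#' @export
#' @examples
#' m <- matrix(c(5L, 0L, 0L, 3L), 2, dimnames = list(c("a", "b"), c("e1", "e2")))
#' MirExpression(m, librarySizes = c(1e6, 2e6))
MirExpression <- function(counts, librarySizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(librarySizes)) {
    warning("library sizes missing; defaulting to per-experiment column sums")
    librarySizes <- pmax(colSums(counts), 1)   # keep sizes positive when empty
  }
  if (!is.null(names(librarySizes)) && !is.null(colnames(counts)))
    librarySizes <- librarySizes[colnames(counts)]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(librarySize = as.numeric(librarySizes),
                                   row.names = colnames(counts)))
  new("MirExpression", se)
}

#' PubmedMap: precursor-to-PubMed associations
#'
#' Set-valued map from precursor id to the distinct positive PubMed record
#' ids associated with it.
#'
#' @slot associations Named list of sorted integer vectors.
#' @export
setClass("PubmedMap", representation(associations = "list"))

setValidity("PubmedMap", function(object) {
  a <- object@associations
  if (length(a) && is.null(names(a))) return("associations must be named")
  for (v in a) {
    if (any(v <= 0)) return("PubMed ids must be positive")
    if (anyDuplicated(v)) return("duplicate PubMed id within a set")
  }
  TRUE
})

#' Construct a PubmedMap
#'
#' @param associations Named list: precursor id -> vector of PubMed ids.
#'   Duplicates are collapsed (set semantics).
#' @return A [PubmedMap-class] object.
#' @export
PubmedMap <- function(associations = list()) {
  associations <- lapply(associations, function(v) sort(unique(as.integer(v))))
  new("PubmedMap", associations = associations)
}
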