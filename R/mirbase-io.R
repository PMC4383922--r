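## Readers and writers for every file-based input and output: miRBase-style
## FASTA (mature, hairpin, 3'-UTR), tab-delimited count tables with library
## sizes, gene2pubmed-style association tables, high-confidence id lists and
## ranked result tables.  Parsing is order-preserving, and write-then-read
## is identity on all of them.

## Minimal structural pre-scan so a malformed FASTA is reported with the
## offending line number before it reaches the Biostrings parser.
checkFastaShape <- function(path) {
  if (!file.exists(path)) mirInputError(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank))
    mirInputError(sprintf("empty FASTA file: %s", path))
  first <- nonblank[[1L]]
  if (!startsWith(lines[[first]], ">"))
    mirInputError(sprintf(
      "malformed FASTA at line %d of %s: expected '>' header, got '%s'",
      first, path, substr(lines[[first]], 1, 30)))
  invisible(TRUE)
}

## Split miRBase-dialect headers "name accession description" into a
## data.frame.  A missing accession falls back to the name.
parseMirbaseHeaders <- function(headers) {
  toks <- strsplit(trimws(headers), "[[:space:]]+")
  data.frame(
    name = vapply(toks, `[`, "", 1L),
    id = vapply(toks, function(t) if (length(t) >= 2L) t[[2L]] else t[[1L]], ""),
    description = vapply(toks, function(t)
      if (length(t) >= 3L) paste(t[-(1:2)], collapse = " ") else "", ""),
    stringsAsFactors = FALSE)
}

#' Read a miRBase-style mature miRNA FASTA file
#'
#' Headers follow the miRBase flat-FASTA dialect \code{>name accession
#' description}.  Sequences are normalized (T to U, uppercase); the arm is
#' inferred from a \code{-5p}/\code{-3p} name suffix; the species code is
#' the name prefix and unknown prefixes are rejected.
#'
#' @param path Path to the FASTA file.
#' @param speciesFilter Optional species code; only matching records are
#'   kept.
#' @return A [MatureSet-class], in file order.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">hsa-miR-19b-3p MIMAT0000074", "UGUGCAAAUCCAUGCAAAACUGA"), f)
#' readMatureFasta(f)
readMatureFasta <- function(path, speciesFilter = NULL) {
  checkFastaShape(path)
  set <- Biostrings::readBStringSet(path)
  hdr <- parseMirbaseHeaders(names(set))
  seqs <- normalizeRna(as.character(set))
  assertRnaAlphabet(seqs, hdr$name)
  keep <- rep(TRUE, nrow(hdr))
  species <- speciesFromName(hdr$name)
  if (!is.null(speciesFilter)) keep <- species == speciesFilter
  MatureSet(id = hdr$id[keep], name = hdr$name[keep],
            sequence = seqs[keep], species = species[keep])
}

#' Read a miRBase-style hairpin (precursor) FASTA file
#'
#' As [readMatureFasta()] but without arm inference; the returned
#' precursors carry empty mature links — use [attachMatures()] to join a
#' [MatureSet-class] onto them by name stem.
#'
#' @param path Path to the FASTA file.
#' @param speciesFilter Optional species code filter.
#' @return A [PrecursorSet-class], in file order.  Duplicate precursor
#'   names are an error.
#' @export
readHairpinFasta <- function(path, speciesFilter = NULL) {
  checkFastaShape(path)
  set <- Biostrings::readBStringSet(path)
  hdr <- parseMirbaseHeaders(names(set))
  seqs <- normalizeRna(as.character(set))
  assertRnaAlphabet(seqs, hdr$name)
  if (anyDuplicated(hdr$name))
    mirInputError(sprintf("duplicate precursor name '%s' in %s",
                          hdr$name[duplicated(hdr$name)][1L], path))
  species <- speciesFromName(hdr$name)
  keep <- if (is.null(speciesFilter)) rep(TRUE, nrow(hdr))
          else species == speciesFilter
  PrecursorSet(id = hdr$id[keep], name = hdr$name[keep],
               sequence = seqs[keep], species = species[keep])
}

#' Join mature miRNAs onto their precursors by name stem
#'
#' The join key is the shared name stem: lowercase name with any
#' \code{-5p}/\code{-3p} suffix removed ("miR" and "mir" are equivalent).
#' A mature also matches a precursor whose name is the stem plus a numeric
#' locus suffix (hsa-miR-19b joins hsa-mir-19b-1).
#'
#' @param precursors A [PrecursorSet-class].
#' @param matures A [MatureSet-class].
#' @return List with elements \code{precursors} (matureIds filled in) and
#'   \code{matures} (precursorId filled in; a mature matching several
#'   precursor loci keeps the first in file order).
#' @export
attachMatures <- function(precursors, matures) {
  pstem <- nameStem(mirName(precursors))
  mstem <- nameStem(mirName(matures))
  pids <- mirId(precursors)
  mids <- mirId(matures)
  matureIds <- rep(list(character()), length(precursors))
  precOfMat <- rep(NA_character_, length(matures))
  for (j in seq_along(matures)) {
    hit <- which(pstem == mstem[j] |
                 grepl(paste0("^", gsub("([.|()\\^{}+$*?\\[\\]\\\\])",
                                        "\\\\\\1", mstem[j]),
                              "-[0-9]+$"), pstem))
    for (i in hit) matureIds[[i]] <- c(matureIds[[i]], mids[j])
    if (length(hit) && is.na(precOfMat[j])) precOfMat[j] <- pids[hit[1L]]
  }
  list(
    precursors = initialize(precursors, matureIds = matureIds),
    matures = initialize(matures, precursorId = precOfMat))
}

#' Read a mature-miRNA read-count table
#'
#' Tab-delimited with a mandatory header row; first column is the mature
#' id, remaining columns are per-experiment read counts.  Library sizes are
#' carried either in a sidecar row whose id field is
#' \code{__library_sizes__} (written by [writeExpressionTable()]) or in a
#' two-column sidecar file \code{experiment<TAB>size}; if both are absent
#' they default to the column sums with a warning.
#'
#' @param path Path to the count table.
#' @param librarySizesPath Optional path to a sidecar library-size file.
#' @return A [MirExpression-class] object.
#' @export
readExpressionTable <- function(path, librarySizesPath = NULL) {
  if (!file.exists(path)) mirInputError(sprintf("file not found: %s", path))
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(tab) < 1L) mirInputError(sprintf("no columns in %s", path))
  expIds <- colnames(tab)[-1L]
  sizes <- NULL
  isSidecar <- tab[[1L]] == "__library_sizes__"
  if (any(isSidecar)) {
    sizes <- as.numeric(tab[which(isSidecar)[1L], -1L, drop = TRUE])
    names(sizes) <- expIds
    tab <- tab[!isSidecar, , drop = FALSE]
  }
  if (!is.null(librarySizesPath)) {
    sc <- utils::read.delim(librarySizesPath, header = FALSE, sep = "\t",
                            colClasses = "character")
    sizes <- stats::setNames(as.numeric(sc[[2L]]), sc[[1L]])[expIds]
  }
  ids <- tab[[1L]]
  counts <- matrix(0L, nrow = nrow(tab), ncol = length(expIds),
                   dimnames = list(ids, expIds))
  for (j in seq_along(expIds)) {
    raw <- tab[[j + 1L]]
    raw[!nzchar(raw)] <- "0"                  # absent pairs are 0
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) | val < 0 | val != round(val))
    if (length(bad))
      mirValidationError(sprintf(
        "invalid count '%s' at row %d (mature '%s'), column '%s' of %s",
        raw[bad[1L]], bad[1L], ids[bad[1L]], expIds[j], path))
    counts[, j] <- as.integer(val)
  }
  if (is.null(sizes)) {
    warning(sprintf("no library sizes for %s; using column sums", path))
    sizes <- pmax(colSums(counts), 1)
  }
  MirExpression(counts, librarySizes = sizes)
}

#' Read a gene2pubmed-style miRNA-to-PubMed association table
#'
#' Tab-delimited \code{precursor_id<TAB>pubmed_id} pairs; duplicates are
#' collapsed to set semantics.  Unknown ids are retained (downstream joins
#' decide relevance).
#'
#' @param path Path to the association table.
#' @return A [PubmedMap-class].
#' @export
readPubmedMap <- function(path) {
  if (!file.exists(path)) mirInputError(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(PubmedMap())
  toks <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(toks)
  pm <- suppressWarnings(
    as.integer(vapply(toks, function(t)
      if (length(t) >= 2L) t[[2L]] else NA_character_, "")))
  bad <- which(nf < 2L | is.na(pm) | pm <= 0L)
  if (length(bad))
    mirInputError(sprintf("malformed association at line %d of %s: '%s'",
                          bad[1L], path, lines[bad[1L]]))
  ids <- vapply(toks, `[[`, "", 1L)
  PubmedMap(split(pm, factor(ids, levels = unique(ids))))
}

#' Read a high-confidence miRNA id list
#'
#' One precursor id per line; blank lines ignored; duplicates collapsed.
#'
#' @param path Path to the list file.
#' @return Character vector of ids (a set).
#' @export
readHighConfList <- function(path) {
  if (!file.exists(path)) mirInputError(sprintf("file not found: %s", path))
  ids <- trimws(readLines(path, warn = FALSE))
  unique(ids[nzchar(ids)])
}

#' Read a 3'-UTR FASTA file
#'
#' Headers follow \code{transcript_id|gene_symbol|description}; a header
#' missing the gene symbol yields an empty symbol with a warning (lenient
#' parse).  Sequences are normalized to the RNA alphabet, so RefSeq-style
#' DNA input is accepted.
#'
#' @param path Path to the UTR FASTA file.
#' @param species Species code recorded on every record (default "hsa").
#' @return A [UtrSet-class], in file order.
#' @export
readUtrFasta <- function(path, species = "hsa") {
  checkFastaShape(path)
  set <- Biostrings::readBStringSet(path)
  headers <- trimws(names(set))
  toks <- strsplit(headers, "|", fixed = TRUE)
  tid <- vapply(toks, `[[`, "", 1L)
  sym <- vapply(toks, function(t) if (length(t) >= 2L) t[[2L]] else "", "")
  des <- vapply(toks, function(t) if (length(t) >= 3L) t[[3L]] else "", "")
  if (any(lengths(toks) < 2L))
    warning(sprintf("%d UTR header(s) missing gene_symbol in %s; stored empty",
                    sum(lengths(toks) < 2L), path))
  seqs <- normalizeRna(as.character(set))
  assertRnaAlphabet(seqs, tid)
  UtrSet(transcriptId = tid, sequence = seqs, geneSymbol = sym,
         description = des, species = species)
}

#' Write a ranked result table as TSV
#'
#' UTF-8, tab-delimited, header row, one row per record, deterministic
#' column order (the data.frame's).  Numeric columns whose values are all
#' integral are rendered as integers.
#'
#' @param rows A data.frame (possibly 0-row).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeResultsTsv <- function(rows, path) {
  rows <- as.data.frame(rows)
  for (j in seq_along(rows)) {
    if (is.numeric(rows[[j]]) && all(rows[[j]] == round(rows[[j]])))
      rows[[j]] <- as.integer(rows[[j]])
  }
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(rows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read back a result table written by [writeResultsTsv()]
#'
#' @param path Path to the TSV.
#' @return A data.frame.
#' @export
readResultsTsv <- function(path) {
  if (!file.exists(path)) mirInputError(sprintf("file not found: %s", path))
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

## ---- writers used by the fixture generator and round-trip tests ----------

writeFasta <- function(headers, seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  names(x) <- headers
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Write record sets in the dialects the readers accept
#'
#' \code{writeMatureFasta} and \code{writeHairpinFasta} emit
#' \code{>name accession} headers; \code{writeUtrFasta} emits
#' \code{transcript_id|gene_symbol|description} headers;
#' \code{writeExpressionTable} emits the count table with a
#' \code{__library_sizes__} sidecar row; \code{writePubmedMap} one
#' id/PMID pair per line; \code{writeHighConfList} one id per line.
#'
#' @param x The record set / table / map to write.
#' @param path Output path.
#' @return Invisibly, the path.
#' @name fixture-writers
NULL

#' @rdname fixture-writers
#' @export
writeMatureFasta <- function(x, path) {
  writeFasta(paste(mirName(x), mirId(x)), unname(mirSequence(x)), path)
}

#' @rdname fixture-writers
#' @export
writeHairpinFasta <- function(x, path) {
  writeFasta(paste(mirName(x), mirId(x)), unname(mirSequence(x)), path)
}

#' @rdname fixture-writers
#' @export
writeUtrFasta <- function(x, path) {
  writeFasta(paste(transcriptIds(x), unname(geneSymbols(x)), x@description,
                   sep = "|"),
             unname(mirSequence(x)), path)
}

#' @rdname fixture-writers
#' @export
writeExpressionTable <- function(x, path) {
  cts <- SummarizedExperiment::assay(x, "counts")
  header <- paste(c("mature_id", colnames(cts)), collapse = "\t")
  sizeRow <- paste(c("__library_sizes__",
                     format(librarySizes(x), scientific = FALSE, trim = TRUE)),
                   collapse = "\t")
  body <- if (nrow(cts)) {
    apply(cbind(rownames(cts), format(cts, scientific = FALSE, trim = TRUE)),
          1L, paste, collapse = "\t")
  } else character()
  writeLines(c(header, sizeRow, body), path)
  invisible(path)
}

#' @rdname fixture-writers
#' @export
writePubmedMap <- function(x, path) {
  keys <- pubmedKeys(x)
  lines <- unlist(lapply(keys, function(k)
    paste(k, pubmedIds(x, k), sep = "\t")), use.names = FALSE)
  writeLines(if (is.null(lines)) character() else lines, path)
  invisible(path)
}

#' @rdname fixture-writers
#' @export
writeHighConfList <- function(x, path) {
  writeLines(as.character(x), path)
  invisible(path)
}
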