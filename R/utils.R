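## Sequence normalization and validation helpers shared by all modules.
## Internal coordinates are 0-based half-open; written reports are 1-based
## inclusive.

#' Supported species codes
#'
#' Three-letter lowercase species prefixes accepted throughout the package:
#' human (hsa), mouse (mmu), rat (rno), dog (cfa) and chicken (gga).  Every
#' miRNA name must start with one of these codes; unknown prefixes are
#' rejected at parse time.
#'
#' @return Character vector of the five supported codes.
#' @export
#' @examples
#' supportedSpecies()
supportedSpecies <- function() c("hsa", "mmu", "rno", "cfa", "gga")

## Condition constructors: validation failures are signalled with a
## dedicated class so the CLI can map them to exit code 3.
mirValidationError <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("mirValidationError", "error")))
}

mirInputError <- function(msg) {
  stop(errorCondition(msg, class = c("mirInputError", "error")))
}

#' Normalize a nucleotide sequence to the RNA alphabet
#'
#' Strips whitespace, folds to uppercase and replaces T with U.  DNA input is
#' therefore accepted everywhere; internally all sequences live in
#' \{A,C,G,U\}.  Normalization is idempotent.
#'
#' @param x Character vector of raw sequences.
#' @return Character vector of normalized RNA sequences.
#' @export
#' @examples
#' normalizeRna("acgT tGca")
normalizeRna <- function(x) {
  x <- gsub("[[:space:]]+", "", x)
  chartr("Tt", "Uu", toupper(chartr("acgut", "ACGUT", x)))
}

## Assert that each (already normalized) sequence is over {A,C,G,U}.
## `labels` names the offending record in the error; the first bad position
## is reported 1-based.
assertRnaAlphabet <- function(seqs, labels = seq_along(seqs)) {
  bad <- regexpr("[^ACGU]", seqs)
  hit <- which(bad > 0L)
  if (length(hit)) {
    i <- hit[[1L]]
    mirValidationError(sprintf(
      "invalid character '%s' at position %d in sequence of record '%s'",
      substr(seqs[i], bad[i], bad[i]), bad[i], labels[i]))
  }
  invisible(TRUE)
}

## Reverse complement of a normalized RNA string (A<->U, C<->G).
rnaRevComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::RNAString(x)))
}

## Species code from a miRNA name prefix ("hsa-miR-19b-3p" -> "hsa").
## Unknown prefixes are a parse error.
speciesFromName <- function(names) {
  code <- sub("-.*$", "", names)
  bad <- !(code %in% supportedSpecies())
  if (any(bad)) {
    mirInputError(sprintf(
      "unknown species prefix '%s' in miRNA name '%s' (supported: %s)",
      code[bad][1L], names[bad][1L],
      paste(supportedSpecies(), collapse = ", ")))
  }
  code
}

## Name stem used to join matures to their precursor: lowercase, arm suffix
## dropped, "mir"/"miR" equivalent.  "hsa-miR-19b-3p" -> "hsa-mir-19b".
nameStem <- function(x) {
  sub("-(5p|3p)$", "", tolower(x))
}

## Format 0-based half-open [start, end) as 1-based inclusive "start-end".
formatSites1Based <- function(start0, end0) {
  paste(start0 + 1L, end0, sep = "-")
}
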