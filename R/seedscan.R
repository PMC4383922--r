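## Custom target-scanning workflow: sequence validation, 7-mer seed
## complementarity screening on the target sense strand, a documented
## monotone surrogate score on the 50-100 presentation scale, and ranked
## result tables for both submission modes (custom miRNA against a UTR set,
## custom target against a species miRNome).

#' Validate and normalize a user-provided miRNA sequence
#'
#' Whitespace is stripped, case folded and T replaced by U; the sequence is
#' accepted iff its length is 17--30 nt and its alphabet is
#' \{A,C,G,U\}.
#'
#' @param raw Raw sequence string.
#' @param params A [ScanParams-class].
#' @return The normalized RNA sequence.
#' @export
#' @examples
#' validateMirnaSeq("uagcuuaucagacugauguuga")
validateMirnaSeq <- function(raw, params = scanParams()) {
  s <- normalizeRna(raw)
  r <- params@mirnaLenRange
  if (nchar(s) < r[1L] || nchar(s) > r[2L])
    mirValidationError(sprintf(
      "miRNA sequence length %d outside accepted range %d-%d nt",
      nchar(s), r[1L], r[2L]))
  assertRnaAlphabet(s, "miRNA query")
  s
}

#' Validate and normalize a user-provided target sequence
#'
#' As [validateMirnaSeq()] but with the target length bounds
#' (100--30 000 nt by default).  Any sequence within bounds is accepted,
#' so coding-region or 5'-UTR segments can be scanned the same way.
#'
#' @param raw Raw sequence string.
#' @param params A [ScanParams-class].
#' @return The normalized RNA sequence.
#' @export
validateTargetSeq <- function(raw, params = scanParams()) {
  s <- normalizeRna(raw)
  r <- params@targetLenRange
  if (nchar(s) < r[1L] || nchar(s) > r[2L])
    mirValidationError(sprintf(
      "target sequence length %d outside accepted range %d-%d nt",
      nchar(s), r[1L], r[2L]))
  assertRnaAlphabet(s, "target query")
  s
}

#' Seed of a mature miRNA
#'
#' The subsequence at miRNA positions 2--8 (1-based, a 7-mer) under the
#' default convention; the positions are configurable.
#'
#' @param mirna Normalized miRNA sequence.
#' @param params A [ScanParams-class].
#' @return The seed string.
#' @export
#' @examples
#' seedOf("UAGCUUAUCAGACUGAUGUUGA")  # "AGCUUAU"
seedOf <- function(mirna, params = scanParams()) {
  substr(mirna, params@seedPositions[1L], params@seedPositions[2L])
}

#' Find seed-complementary sites on a target sequence
#'
#' Screens the target sense strand for every occurrence of the
#' Watson-Crick reverse complement of the miRNA seed.  Overlapping sites
#' are all reported; no wobble pairs.  Coordinates are 0-based half-open
#' on the target.
#'
#' @param mirnaId Identifier attached to the reported sites.
#' @param mirnaSeq Normalized miRNA sequence.
#' @param targetId Target identifier.
#' @param targetSeq Normalized target sequence.
#' @param params A [ScanParams-class].
#' @return data.frame with columns target_id, start, end, matched_7mer,
#'   mirna_id, sorted by start; every row satisfies
#'   \code{substr(target, start+1, end) == revcomp(seed)}.
#' @export
findSeedSites <- function(mirnaId, mirnaSeq, targetId, targetSeq,
                          params = scanParams()) {
  seed <- seedOf(mirnaSeq, params)
  site <- rnaRevComp(seed)
  m <- Biostrings::matchPattern(site, Biostrings::RNAString(targetSeq))
  st <- BiocGenerics::start(m) - 1L             # to 0-based half-open
  data.frame(target_id = rep(targetId, length(st)), start = st,
             end = st + nchar(site),
             matched_7mer = rep(site, length(st)),
             mirna_id = rep(mirnaId, length(st)),
             stringsAsFactors = FALSE)[order(st), , drop = FALSE]
}

#' Surrogate prediction score for a scanned target
#'
#' An explicit, documented monotone map from the seed-site count and site
#' density onto the 50--100 integer presentation scale:
#' \deqn{score = 50 + round(50 (1 - e^{-x/4})), \quad
#'       x = n (1 + 1000 / L)}
#' with \eqn{n} the number of seed sites and \eqn{L} the target length.
#' More sites never score lower at equal length, and the score is clamped
#' to the scale by construction.  This is a transparent ranking surrogate,
#' not a trained target-prediction model.
#'
#' @param sites data.frame of sites from [findSeedSites()] (at least one
#'   row; targets with no sites are not reported).
#' @param targetLen Target sequence length in nt.
#' @param params A [ScanParams-class] (provides the scale).
#' @return Integer score in 50--100.
#' @export
siteScore <- function(sites, targetLen, params = scanParams()) {
  n <- if (is.data.frame(sites)) nrow(sites) else as.integer(sites)
  if (n < 1L) mirValidationError("siteScore requires at least one seed site")
  lo <- params@scoreRange[1L]
  hi <- params@scoreRange[2L]
  x <- n * (1 + 1000 / targetLen)
  as.integer(round(lo + (hi - lo) * (1 - exp(-x / 4))))
}

rankRows <- function(rows, tieCol) {
  if (!nrow(rows)) {
    rows$rank <- integer()
    return(rows[, c("rank", setdiff(names(rows), "rank")), drop = FALSE])
  }
  ord <- order(-rows$surrogate_score, rows[[tieCol]])
  rows <- rows[ord, , drop = FALSE]
  rows$rank <- seq_len(nrow(rows))
  rownames(rows) <- NULL
  rows[, c("rank", setdiff(names(rows), "rank")), drop = FALSE]
}

scanOnePair <- function(mirnaName, mirnaSeq, targetId, geneSymbol,
                        targetSeq, params) {
  sites <- findSeedSites(mirnaName, mirnaSeq, targetId, targetSeq, params)
  if (!nrow(sites)) return(NULL)
  data.frame(
    surrogate_score = siteScore(sites, nchar(targetSeq), params),
    mirna_name = mirnaName, target_id = targetId,
    gene_symbol = geneSymbol, n_sites = nrow(sites),
    site_positions = paste(formatSites1Based(sites$start, sites$end),
                           collapse = ";"),
    matched_7mers = paste(sites$matched_7mer, collapse = ";"),
    stringsAsFactors = FALSE)
}

#' Scan a custom miRNA against a 3'-UTR set
#'
#' Screens every UTR for seed-complementary sites of the submitted miRNA;
#' targets with at least one site are scored and returned in descending
#' score order (ties broken by ascending target id), carrying their gene
#' annotations and 1-based inclusive seed-match locations.
#'
#' @param mirnaSeq Raw miRNA sequence (validated internally).
#' @param utrs A [UtrSet-class].
#' @param params A [ScanParams-class].
#' @param mirnaName Display name for the query (default "query").
#' @return data.frame with columns rank, surrogate_score, mirna_name,
#'   target_id, gene_symbol, n_sites, site_positions, matched_7mers.
#' @export
scanCustomMirna <- function(mirnaSeq, utrs, params = scanParams(),
                            mirnaName = "query") {
  s <- validateMirnaSeq(mirnaSeq, params)
  seqs <- unname(mirSequence(utrs))
  syms <- unname(geneSymbols(utrs))
  tids <- transcriptIds(utrs)
  rows <- do.call(rbind, lapply(seq_along(utrs), function(i)
    scanOnePair(mirnaName, s, tids[i], syms[i], seqs[i], params)))
  if (is.null(rows))
    rows <- data.frame(surrogate_score = integer(), mirna_name = character(),
                       target_id = character(), gene_symbol = character(),
                       n_sites = integer(), site_positions = character(),
                       matched_7mers = character(), stringsAsFactors = FALSE)
  rankRows(rows, "target_id")
}

#' Scan a custom target against a species miRNome
#'
#' Screens the submitted target for seed-complementary sites of every
#' mature miRNA in the set; miRNAs with at least one site are scored and
#' ranked (ties broken by ascending miRNA name).
#'
#' @param targetSeq Raw target sequence (validated internally).
#' @param mirnome A [MatureSet-class].
#' @param params A [ScanParams-class].
#' @param targetId Display id for the target (default "target").
#' @return data.frame as in [scanCustomMirna()].
#' @export
scanCustomTarget <- function(targetSeq, mirnome, params = scanParams(),
                             targetId = "target") {
  s <- validateTargetSeq(targetSeq, params)
  nms <- mirName(mirnome)
  seqs <- unname(mirSequence(mirnome))
  rows <- do.call(rbind, lapply(seq_along(mirnome), function(i)
    scanOnePair(nms[i], seqs[i], targetId, "", s, params)))
  if (is.null(rows))
    rows <- data.frame(surrogate_score = integer(), mirna_name = character(),
                       target_id = character(), gene_symbol = character(),
                       n_sites = integer(), site_positions = character(),
                       matched_7mers = character(), stringsAsFactors = FALSE)
  rankRows(rows, "mirna_name")
}
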