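## Functional-miRNA identification: four integer criterion scores (PubMed
## literature support, cross-species conservation, pooled RPM expression,
## curated high-confidence status), their composite, the functional call at
## a fixed threshold, dominant/secondary mature-arm selection, and the
## criterion-removal contribution analysis.

#' PubMed literature criterion score
#'
#' Number of distinct associated PubMed records mapped to an integer score:
#' 0 for fewer than two records, 1 for two, 2 for three, 3 for four or
#' more.  False discoveries tend to be ignored by the literature while true
#' ones are repeatedly validated, so repeated independent description is
#' evidence of function.
#'
#' @param n Nonnegative integer vector of distinct PubMed record counts.
#' @param params A [ScoringParams-class].
#' @return Integer score(s) in 0--3.
#' @export
#' @examples
#' pubmedScore(c(0, 1, 2, 3, 4, 17))
pubmedScore <- function(n, params = scoringParams()) {
  if (any(n < 0)) mirValidationError("negative PubMed record count")
  b <- params@pubmedBrackets
  as.integer(rowSums(outer(n, b, `>=`)))
}

#' Conservation criterion score
#'
#' Number of other species carrying an ortholog mapped to an integer score:
#' 0 for none, 1 for one, 2 for two or more.
#'
#' @param n Nonnegative integer vector: other-species ortholog counts.
#' @param params A [ScoringParams-class].
#' @return Integer score(s) in 0--2.
#' @export
#' @examples
#' conservationScore(c(0, 1, 3))
conservationScore <- function(n, params = scoringParams()) {
  if (any(n < 0)) mirValidationError("negative ortholog-species count")
  b <- params@conservationBrackets
  as.integer(rowSums(outer(n, b, `>=`)))
}

#' Expression criterion score
#'
#' Pooled abundance in reads per million mapped to an integer score: 0
#' below 1 RPM, 1 for 1--10 RPM inclusive, 2 strictly above 10 RPM.
#'
#' @param rpm Nonnegative numeric vector of reads-per-million values.
#' @param params A [ScoringParams-class].
#' @return Integer score(s) in 0--2.
#' @export
#' @examples
#' expressionScore(c(0.2, 1, 10, 15))
expressionScore <- function(rpm, params = scoringParams()) {
  if (any(rpm < 0)) mirValidationError("negative RPM")
  b <- params@expressionBracketsRpm
  as.integer((rpm >= b[1L]) + (rpm > b[2L]))
}

#' Curated-status criterion score
#'
#' 1 if the miRNA carries the curated high-confidence flag, else 0.
#'
#' @param highConfidence Logical vector.
#' @return Integer score(s) in 0--1.
#' @export
mirbaseScore <- function(highConfidence) {
  as.integer(as.logical(highConfidence))
}

#' Find the species carrying an ortholog of a mature miRNA
#'
#' Orthology is perfect identity of the 5'-end prefix: because the 3' end
#' of a mature miRNA is often post-transcriptionally modified and more
#' variable, only the first 19 nt must match (for matures shorter than
#' 19 nt the comparison length degrades to the shorter sequence, keeping
#' the relation symmetric).  The query's own species is never included.
#'
#' @param sequence Normalized RNA sequence of the query mature.
#' @param species Species code of the query.
#' @param matures A [MatureSet-class] of candidate matures (any species;
#'   same-species entries are ignored).
#' @param params A [ScoringParams-class].
#' @return Character vector of other species codes with an ortholog.
#' @export
findOrthologs <- function(sequence, species, matures,
                          params = scoringParams()) {
  sequence <- normalizeRna(sequence)
  if (!nzchar(sequence)) mirValidationError("empty query sequence")
  k <- params@orthologPrefixLen
  cand <- mirSpecies(matures) != species
  if (!any(cand)) return(character())
  seqs <- unname(mirSequence(matures))[cand]
  sp <- mirSpecies(matures)[cand]
  L <- pmin(k, nchar(sequence), nchar(seqs))
  hit <- substring(seqs, 1L, L) == substring(sequence, 1L, L)
  sort(unique(sp[hit]))
}

#' Ortholog species sets for a whole mature set
#'
#' @param matures A [MatureSet-class].
#' @param params A [ScoringParams-class].
#' @return Named list (by mature id) of other-species code vectors.
#' @export
orthologSpecies <- function(matures, params = scoringParams()) {
  out <- lapply(seq_along(matures), function(i)
    findOrthologs(mirSequence(matures)[[i]], mirSpecies(matures)[[i]],
                  matures, params))
  stats::setNames(out, mirId(matures))
}

#' Pooled reads-per-million abundance of mature miRNAs
#'
#' Under the default \code{"pooled"} aggregation, counts are summed across
#' all experiments and scaled by the summed library sizes:
#' \eqn{10^6 \sum_e c_e / \sum_e N_e}.  \code{"mean"} instead averages the
#' per-experiment RPM values.  Matures absent from the table have 0 RPM.
#'
#' @param x A [MirExpression-class].
#' @param matureIds Character vector of mature ids.
#' @param params A [ScoringParams-class] (its \code{rpmAggregation} field
#'   selects the aggregation).
#' @return Named numeric vector of RPM values.
#' @export
pooledRpm <- function(x, matureIds, params = scoringParams()) {
  sizes <- librarySizes(x)
  if (sum(sizes) <= 0) mirValidationError("total library size is zero")
  cts <- SummarizedExperiment::assay(x, "counts")
  idx <- match(matureIds, rownames(cts))
  rpm <- vapply(idx, function(i) {
    if (is.na(i)) return(0)
    row <- cts[i, ]
    if (params@rpmAggregation == "pooled") 1e6 * sum(row) / sum(sizes)
    else mean(1e6 * row / sizes)
  }, 0)
  stats::setNames(rpm, matureIds)
}

#' Score precursors on all four criteria
#'
#' PubMed counts and the high-confidence flag are precursor-granular; the
#' conservation and expression criteria are evaluated per mature arm and
#' the precursor takes the maximum over its arms.  The composite is the sum
#' of the four criterion scores (0--8).
#'
#' @param precursors A [PrecursorSet-class] with mature links attached
#'   (see [attachMatures()]); a precursor with no mature arms is an error.
#' @param matures The [MatureSet-class] the links point into.
#' @param expression A [MirExpression-class].
#' @param pubmed A [PubmedMap-class] keyed by precursor id (name keys also
#'   honoured).
#' @param highConf Character vector of high-confidence precursor ids or
#'   names.
#' @param params A [ScoringParams-class].
#' @param orthology Optional precomputed [orthologSpecies()] result.
#' @return data.frame with columns precursor_id, pubmed, conservation,
#'   expression, mirbase, composite, one row per precursor in input order.
#' @export
scorePrecursors <- function(precursors, matures, expression, pubmed,
                            highConf = character(),
                            params = scoringParams(), orthology = NULL) {
  if (is.null(orthology)) orthology <- orthologSpecies(matures, params)
  mids <- matureIdsOf(precursors)
  if (any(lengths(mids) == 0L))
    mirValidationError(sprintf(
      "precursor '%s' has no mature arms; join matures first",
      mirName(precursors)[lengths(mids) == 0L][1L]))
  rpm <- pooledRpm(expression, mirId(matures), params)
  ids <- mirId(precursors)
  nms <- mirName(precursors)
  nPm <- vapply(seq_along(precursors), function(i) {
    v <- pubmedIds(pubmed, ids[i])
    if (!length(v)) v <- pubmedIds(pubmed, nms[i])
    length(v)
  }, 0L)
  cons <- vapply(mids, function(m)
    max(conservationScore(lengths(orthology[m]), params)), 0L)
  expr <- vapply(mids, function(m)
    max(expressionScore(rpm[m], params)), 0L)
  hc <- ids %in% highConf | nms %in% highConf
  pm <- pubmedScore(nPm, params)
  mb <- mirbaseScore(hc)
  data.frame(precursor_id = ids, pubmed = pm, conservation = cons,
             expression = expr, mirbase = mb,
             composite = pm + cons + expr + mb,
             stringsAsFactors = FALSE)
}

#' Functional classification from the composite score
#'
#' A precursor is functional when its composite score reaches the
#' threshold (default: 3 or higher).
#'
#' @param scores Numeric composite vector, or a data.frame with a
#'   \code{composite} column as returned by [scorePrecursors()].
#' @param params A [ScoringParams-class].
#' @return Logical vector.
#' @export
#' @examples
#' classifyFunctional(c(0, 2, 3, 8))
classifyFunctional <- function(scores, params = scoringParams()) {
  comp <- if (is.data.frame(scores)) scores$composite else scores
  comp >= params@functionalThreshold
}

#' Select the dominant (and possibly a secondary) mature arm
#'
#' The dominant arm is the one with the highest pooled RPM (ties prefer
#' the 5p arm, then the lexicographically smaller name).  A second arm is
#' also selected iff its expression is no less than 10% of the dominant
#' arm's AND no less than 5 reads per million (both inclusive, both
#' configurable).
#'
#' @param rpm Named numeric vector of pooled RPM, one entry per mature arm
#'   of one precursor (names are mature ids).
#' @param arm Optional character vector ("5p"/"3p"/"unknown") parallel to
#'   \code{rpm}, used for tie-breaking.
#' @param name Optional display names parallel to \code{rpm} (defaults to
#'   the ids), used for the final tie-break.
#' @param params A [ScoringParams-class].
#' @return List with elements \code{dominant} (mature id) and
#'   \code{secondary} (mature id or NA).
#' @export
#' @examples
#' selectFunctionalMatures(c(a = 100, b = 10))   # both arms
#' selectFunctionalMatures(c(a = 100, b = 4))    # dominant only
selectFunctionalMatures <- function(rpm, arm = NULL, name = names(rpm),
                                    params = scoringParams()) {
  if (!length(rpm)) mirValidationError("precursor has no mature arms")
  if (is.null(arm)) arm <- rep("unknown", length(rpm))
  ord <- order(-rpm, arm != "5p", name)
  dominant <- names(rpm)[ord[1L]]
  secondary <- NA_character_
  if (length(rpm) >= 2L) {
    cand <- ord[2L]
    if (rpm[cand] >= params@secondaryFraction * rpm[ord[1L]] &&
        rpm[cand] >= params@secondaryMinRpm)
      secondary <- names(rpm)[cand]
  }
  list(dominant = dominant, secondary = secondary)
}

#' Criteria required for a functional call (criterion-removal analysis)
#'
#' The contribution of each criterion is evaluated by removing its score
#' from the composite: criterion c is required iff the precursor is
#' functional but would drop below the threshold without c.  Precursors
#' below the threshold return the empty set by convention.
#'
#' @param scores Named numeric vector with elements pubmed, conservation,
#'   expression, mirbase (a one-row data.frame also works).
#' @param params A [ScoringParams-class].
#' @return Character vector, a subset of
#'   \code{c("pubmed", "conservation", "expression", "mirbase")}.
#' @export
#' @examples
#' requiredCriteria(c(pubmed = 3, conservation = 0, expression = 0, mirbase = 0))
requiredCriteria <- function(scores, params = scoringParams()) {
  crit <- c("pubmed", "conservation", "expression", "mirbase")
  s <- vapply(crit, function(k) as.numeric(scores[[k]]), 0)
  comp <- sum(s)
  if (comp < params@functionalThreshold) return(character())
  crit[comp - s < params@functionalThreshold]
}

#' Number of criteria supporting a precursor
#'
#' @param scores As in [requiredCriteria()].
#' @return Integer count of strictly positive criterion scores (0--4).
#' @export
nSupportingCriteria <- function(scores) {
  crit <- c("pubmed", "conservation", "expression", "mirbase")
  sum(vapply(crit, function(k) as.numeric(scores[[k]]), 0) > 0)
}

#' Full functional-annotation pipeline
#'
#' Scores every precursor on the four criteria, classifies it against the
#' composite threshold, selects its dominant (and, when functional and
#' supported, secondary) mature arm, and reports the criterion-removal
#' contribution set.
#'
#' @param precursors A [PrecursorSet-class] (mature links attached
#'   automatically when absent).
#' @param matures A [MatureSet-class].
#' @param expression A [MirExpression-class].
#' @param pubmed A [PubmedMap-class].
#' @param highConf Character vector of high-confidence ids/names.
#' @param params A [ScoringParams-class].
#' @return data.frame with one row per precursor (input order) and columns
#'   precursor_id, name, species, pubmed_score, conservation_score,
#'   expression_score, mirbase_score, composite, is_functional,
#'   dominant_mature, secondary_mature, n_supporting_criteria,
#'   required_criteria (semicolon-joined).
#' @export
annotateFunctional <- function(precursors, matures, expression, pubmed,
                               highConf = character(),
                               params = scoringParams()) {
  if (all(lengths(matureIdsOf(precursors)) == 0L) && length(precursors)) {
    joined <- attachMatures(precursors, matures)
    precursors <- joined$precursors
    matures <- joined$matures
  }
  sc <- scorePrecursors(precursors, matures, expression, pubmed,
                        highConf, params)
  fun <- classifyFunctional(sc, params)
  rpm <- pooledRpm(expression, mirId(matures), params)
  armOf <- mirArm(matures)
  nameOf <- stats::setNames(mirName(matures), mirId(matures))
  mids <- matureIdsOf(precursors)
  dom <- character(length(precursors))
  sec <- rep(NA_character_, length(precursors))
  for (i in seq_along(precursors)) {
    pick <- selectFunctionalMatures(rpm[mids[[i]]], armOf[mids[[i]]],
                                    nameOf[mids[[i]]], params)
    dom[i] <- pick$dominant
    if (fun[i]) sec[i] <- pick$secondary
  }
  req <- vapply(seq_len(nrow(sc)), function(i)
    paste(requiredCriteria(sc[i, ], params), collapse = ";"), "")
  nsup <- vapply(seq_len(nrow(sc)), function(i)
    nSupportingCriteria(sc[i, ]), 0L)
  data.frame(
    precursor_id = sc$precursor_id, name = mirName(precursors),
    species = mirSpecies(precursors), pubmed_score = sc$pubmed,
    conservation_score = sc$conservation, expression_score = sc$expression,
    mirbase_score = sc$mirbase, composite = sc$composite,
    is_functional = fun, dominant_mature = dom, secondary_mature = sec,
    n_supporting_criteria = nsup, required_criteria = req,
    stringsAsFactors = FALSE)
}
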