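## Parameter objects.  Defaults are the published thresholds; every field is
## overridable so bracket boundaries can be probed in tests and from the CLI.

#' ScoringParams: thresholds of the functional-miRNA composite score
#'
#' @slot pubmedBrackets Ascending PubMed-record thresholds mapped to scores
#'   1, 2, 3 (default \code{c(2, 3, 4)}: 1 point for two records, 2 for
#'   three, 3 for four or more).
#' @slot conservationBrackets Ascending ortholog-species thresholds mapped
#'   to scores 1, 2 (default \code{c(1, 2)}).
#' @slot expressionBracketsRpm Expression brackets in reads per million:
#'   score 1 for \code{[b1, b2]} inclusive, 2 for strictly above \code{b2}
#'   (default \code{c(1, 10)}).
#' @slot functionalThreshold Composite score at or above which a precursor
#'   is called functional (default 3).
#' @slot orthologPrefixLen Length of the 5'-end perfect-identity prefix
#'   defining orthology (default 19 nt; the 3' end of a mature miRNA is
#'   often post-transcriptionally modified and more variable).
#' @slot secondaryFraction Minimum expression of a secondary mature arm as a
#'   fraction of the dominant arm (default 0.10, inclusive).
#' @slot secondaryMinRpm Minimum pooled expression of a secondary arm in
#'   reads per million (default 5, inclusive).
#' @slot rpmAggregation \code{"pooled"} (total counts over total library
#'   size, the default) or \code{"mean"} (mean of per-experiment RPMs).
#' @export
setClass("ScoringParams", representation(
  pubmedBrackets = "numeric", conservationBrackets = "numeric",
  expressionBracketsRpm = "numeric", functionalThreshold = "numeric",
  orthologPrefixLen = "integer", secondaryFraction = "numeric",
  secondaryMinRpm = "numeric", rpmAggregation = "character"))

setValidity("ScoringParams", function(object) {
  chkAsc <- function(v) length(v) >= 1 && all(diff(v) > 0) && all(v > 0)
  if (!chkAsc(object@pubmedBrackets) || length(object@pubmedBrackets) != 3L)
    return("pubmedBrackets must be 3 strictly ascending positive values")
  if (!chkAsc(object@conservationBrackets) ||
      length(object@conservationBrackets) != 2L)
    return("conservationBrackets must be 2 strictly ascending positive values")
  if (!chkAsc(object@expressionBracketsRpm) ||
      length(object@expressionBracketsRpm) != 2L)
    return("expressionBracketsRpm must be 2 strictly ascending positive values")
  if (object@functionalThreshold <= 0) return("functionalThreshold must be > 0")
  if (object@orthologPrefixLen <= 0L) return("orthologPrefixLen must be > 0")
  if (object@secondaryFraction < 0 || object@secondaryFraction > 1)
    return("secondaryFraction must lie in [0, 1]")
  if (object@secondaryMinRpm < 0) return("secondaryMinRpm must be >= 0")
  if (!object@rpmAggregation %in% c("pooled", "mean"))
    return("rpmAggregation must be 'pooled' or 'mean'")
  TRUE
})

#' Construct ScoringParams
#'
#' @param pubmedBrackets,conservationBrackets,expressionBracketsRpm,
#'   functionalThreshold,orthologPrefixLen,secondaryFraction,
#'   secondaryMinRpm,rpmAggregation See [ScoringParams-class].
#' @return A validated [ScoringParams-class] object.
#' @export
#' @examples
#' scoringParams()
scoringParams <- function(pubmedBrackets = c(2, 3, 4),
                          conservationBrackets = c(1, 2),
                          expressionBracketsRpm = c(1, 10),
                          functionalThreshold = 3,
                          orthologPrefixLen = 19L,
                          secondaryFraction = 0.10,
                          secondaryMinRpm = 5,
                          rpmAggregation = "pooled") {
  new("ScoringParams", pubmedBrackets = pubmedBrackets,
      conservationBrackets = conservationBrackets,
      expressionBracketsRpm = expressionBracketsRpm,
      functionalThreshold = functionalThreshold,
      orthologPrefixLen = as.integer(orthologPrefixLen),
      secondaryFraction = secondaryFraction,
      secondaryMinRpm = secondaryMinRpm,
      rpmAggregation = rpmAggregation)
}

#' ScanParams: limits and conventions of the target-scanning workflow
#'
#' @slot mirnaLenRange Accepted miRNA sequence lengths, inclusive
#'   (default \code{c(17, 30)} nt).
#' @slot targetLenRange Accepted target sequence lengths, inclusive
#'   (default \code{c(100, 30000)} nt).
#' @slot seedPositions First and last miRNA position (1-based, inclusive) of
#'   the seed (default \code{c(2, 8)}: a 7-mer).
#' @slot scoreRange Presentation score scale (default \code{c(50, 100)}).
#' @export
setClass("ScanParams", representation(
  mirnaLenRange = "integer", targetLenRange = "integer",
  seedPositions = "integer", scoreRange = "numeric"))

setValidity("ScanParams", function(object) {
  rng <- function(v) length(v) == 2L && v[1L] <= v[2L] && all(v > 0)
  if (!rng(object@mirnaLenRange)) return("bad mirnaLenRange")
  if (!rng(object@targetLenRange)) return("bad targetLenRange")
  if (!rng(object@seedPositions)) return("bad seedPositions")
  if (!rng(object@scoreRange)) return("bad scoreRange")
  if (object@seedPositions[2L] > object@mirnaLenRange[1L])
    return("seed must fit inside the shortest accepted miRNA")
  TRUE
})

#' Construct ScanParams
#'
#' @param mirnaLenRange,targetLenRange,seedPositions,scoreRange See
#'   [ScanParams-class].
#' @return A validated [ScanParams-class] object.
#' @export
#' @examples
#' scanParams()
scanParams <- function(mirnaLenRange = c(17L, 30L),
                       targetLenRange = c(100L, 30000L),
                       seedPositions = c(2L, 8L),
                       scoreRange = c(50, 100)) {
  new("ScanParams", mirnaLenRange = as.integer(mirnaLenRange),
      targetLenRange = as.integer(targetLenRange),
      seedPositions = as.integer(seedPositions), scoreRange = scoreRange)
}

#' Seed span length of a ScanParams object
#' @param params A [ScanParams-class].
#' @return Integer seed length (7 under defaults).
#' @export
seedLength <- function(params) {
  params@seedPositions[2L] - params@seedPositions[1L] + 1L
}

#' Apply a named list of overrides (e.g. parsed from a YAML config file) to
#' a parameter constructor.
#'
#' @param constructor One of [scoringParams], [scanParams], [fixtureSpec].
#' @param overrides Named list; unknown names are an error.
#' @return The constructed parameter object.
#' @export
paramsFromList <- function(constructor, overrides = list()) {
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(formals(constructor)))
    if (length(bad))
      mirInputError(sprintf("unknown parameter override '%s'", bad[1L]))
  }
  do.call(constructor, overrides)
}
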