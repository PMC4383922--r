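# Independent brute-force oracles used by the tests.  These deliberately
# share no code with the package: reverse complement via chartr, site
# finding by comparing every window of the target against the pattern.

naiveRevComp <- function(x) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", x), "")[[1]]), collapse = "")
}

# 1-based start positions of every (possibly overlapping) occurrence of
# `site` in `target`, by all-window substring comparison.
naiveSiteStarts <- function(target, site) {
  L <- nchar(target); w <- nchar(site)
  if (L < w) return(integer())
  which(substring(target, 1:(L - w + 1L), w:L) == site)
}

randomRna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# A small hand-built evidence bundle around one two-arm precursor, used by
# several scoring tests.
makeTinyBundle <- function(nPmids = 4L, nOrthoSpecies = 2L, rpm5p = 15,
                           rpm3p = 0.5, highConf = TRUE) {
  otherSp <- setdiff(supportedSpecies(), "hsa")[seq_len(nOrthoSpecies)]
  seq5 <- "UAGCUUAUCAGACUGAUGUUGA"      # 22 nt
  seq3 <- "ACUGCAUUAUGAGCACUUAAAG"
  ids <- c("MIMATX5", "MIMATX3")
  orthIds <- if (length(otherSp)) paste0("MIMATO", seq_along(otherSp))
             else character(0)
  matures <- MatureSet(
    id = c(ids, orthIds),
    name = c("hsa-miR-900-5p", "hsa-miR-900-3p",
             sprintf("%s-miR-900-5p", otherSp)),
    sequence = c(seq5, seq3,
                 rep(paste0(substr(seq5, 1, 19), "CCC"), length(otherSp))))
  precursors <- PrecursorSet(
    id = "MIX900", name = "hsa-mir-900",
    sequence = paste0("ACGUACGU", seq5, "GUGUGUGUGU", seq3, "ACGUACGU"),
    matureIds = list(ids))
  ## library of 2e6 reads so RPM values in steps of 0.5 are exact
  counts <- matrix(0L, nrow = 2 + length(orthIds), ncol = 1,
                   dimnames = list(c(ids, orthIds), "e1"))
  counts["MIMATX5", 1] <- as.integer(round(rpm5p * 2))
  counts["MIMATX3", 1] <- as.integer(round(rpm3p * 2))
  expr <- MirExpression(counts, librarySizes = c(e1 = 2e6))
  pubmed <- PubmedMap(if (nPmids > 0)
    stats::setNames(list(seq_len(nPmids) + 100L), "MIX900") else list())
  highconf <- if (highConf) "MIX900" else character()
  list(precursors = precursors, matures = matures, expr = expr,
       pubmed = pubmed, highconf = highconf)
}
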