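## Seeded synthetic-fixture generator.  Emulates every input the pipeline
## consumes -- multi-species miRNomes with planted orthologous families
## (shared 5' 19-mers, divergent 3' ends), overdispersed count matrices with
## known library sizes, sparse PubMed association counts, a high-confidence
## list, and UTR sequences with planted seed-complementary sites -- and
## exports ground truth computed by an independent straight-line oracle.

#' FixtureSpec: parameters of the synthetic-fixture generator
#'
#' @slot rngSeed Integer seed fixing all downstream randomness.
#' @slot nFamilies Number of miRNA families (each contributes a precursor
#'   with a 5p and a 3p arm per member species).
#' @slot species Species codes to emulate.
#' @slot orthologFraction Probability that a family is shared across two or
#'   more species (members share the 5'-end 19-mer of each arm and diverge
#'   after nt 19).
#' @slot rpmRange Per-arm true abundance drawn log-uniformly from this
#'   reads-per-million range.
#' @slot nbDispersion Negative-binomial size parameter of the count model
#'   (small-RNA-seq counts are overdispersed).
#' @slot nExperiments Number of sequencing experiments in the count table.
#' @slot libSizeRange Uniform range of per-experiment library sizes.
#' @slot pubmedZeroProb Zero-inflation probability of the PubMed-count
#'   model.
#' @slot pubmedLambda Poisson mean of the non-zero PubMed-count component.
#' @slot highconfFraction Probability a precursor is on the
#'   high-confidence list.
#' @slot utrCount Number of 3'-UTR sequences.
#' @slot utrLenRange UTR length range in nt.
#' @slot plantedSitesPerUtr Seed-complementary sites planted per UTR at
#'   recorded coordinates.
#' @export
setClass("FixtureSpec", representation(
  rngSeed = "integer", nFamilies = "integer", species = "character",
  orthologFraction = "numeric", rpmRange = "numeric",
  nbDispersion = "numeric", nExperiments = "integer",
  libSizeRange = "numeric", pubmedZeroProb = "numeric",
  pubmedLambda = "numeric", highconfFraction = "numeric",
  utrCount = "integer", utrLenRange = "integer",
  plantedSitesPerUtr = "integer"))

setValidity("FixtureSpec", function(object) {
  inUnit <- function(p) p >= 0 && p <= 1
  if (!inUnit(object@orthologFraction)) return("orthologFraction not in [0,1]")
  if (!inUnit(object@pubmedZeroProb)) return("pubmedZeroProb not in [0,1]")
  if (!inUnit(object@highconfFraction)) return("highconfFraction not in [0,1]")
  if (object@nFamilies < 1L) return("nFamilies must be >= 1")
  if (length(object@species) < 1L ||
      any(!object@species %in% supportedSpecies()))
    return("species must be a nonempty subset of the supported codes")
  if (object@rpmRange[1L] <= 0 || diff(object@rpmRange) < 0)
    return("bad rpmRange")
  if (object@nbDispersion <= 0) return("nbDispersion must be > 0")
  if (object@nExperiments < 1L) return("nExperiments must be >= 1")
  if (object@utrLenRange[1L] > object@utrLenRange[2L])
    return("bad utrLenRange")
  if (object@plantedSitesPerUtr > 0L && object@utrLenRange[1L] < 100L)
    return("planted sites require UTRs of at least 100 nt")
  if (object@plantedSitesPerUtr * 14L > object@utrLenRange[1L])
    return("too many planted sites for the shortest UTR")
  TRUE
})

#' Construct a FixtureSpec
#'
#' Defaults emulate the study conditions: five species, 81 sequencing
#' experiments, a mix of species-specific and conserved families, and
#' overdispersed counts spanning the expression brackets.
#'
#' @param rngSeed,nFamilies,species,orthologFraction,rpmRange,nbDispersion,
#'   nExperiments,libSizeRange,pubmedZeroProb,pubmedLambda,
#'   highconfFraction,utrCount,utrLenRange,plantedSitesPerUtr
#'   See [FixtureSpec-class].
#' @return A validated [FixtureSpec-class] object.
#' @export
#' @examples
#' fixtureSpec(rngSeed = 1, nFamilies = 5)
fixtureSpec <- function(rngSeed = 1L, nFamilies = 30L,
                        species = supportedSpecies(),
                        orthologFraction = 0.5,
                        rpmRange = c(0.05, 100), nbDispersion = 2,
                        nExperiments = 81L, libSizeRange = c(2e5, 2e6),
                        pubmedZeroProb = 0.4, pubmedLambda = 3,
                        highconfFraction = 0.3, utrCount = 25L,
                        utrLenRange = c(300L, 3000L),
                        plantedSitesPerUtr = 2L) {
  new("FixtureSpec", rngSeed = as.integer(rngSeed),
      nFamilies = as.integer(nFamilies), species = species,
      orthologFraction = orthologFraction, rpmRange = rpmRange,
      nbDispersion = nbDispersion, nExperiments = as.integer(nExperiments),
      libSizeRange = libSizeRange, pubmedZeroProb = pubmedZeroProb,
      pubmedLambda = pubmedLambda, highconfFraction = highconfFraction,
      utrCount = as.integer(utrCount),
      utrLenRange = as.integer(utrLenRange),
      plantedSitesPerUtr = as.integer(plantedSitesPerUtr))
}

randRna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

#' Generate a complete synthetic fixture set
#'
#' Writes, under \code{outdir}: \code{mature.fa} and \code{hairpin.fa}
#' (miRBase dialect; orthologous family members share each arm's 5' 19-mer
#' and diverge after nt 19), \code{counts.tsv} (negative-binomial counts
#' over the stated experiments with a \code{__library_sizes__} row),
#' \code{pubmed.tsv}, \code{highconf.txt}, \code{utr.fa} (RefSeq-style DNA
#' with planted seed-complementary sites at recorded coordinates), and the
#' ground-truth tables \code{truth_scores.tsv} (computed by
#' [oracleScores()], an independent straight-line restatement of the
#' scoring rules) and \code{truth_sites.tsv} (planted site coordinates,
#' 1-based inclusive).  The same seed yields a byte-identical file set.
#'
#' @param spec A [FixtureSpec-class].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with \code{paths} (named file paths) and
#'   \code{truth} (the two ground-truth data.frames).
#' @export
generateFixtures <- function(spec = fixtureSpec(), outdir) {
  methods::validObject(spec)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec@rngSeed)
  sp <- spec@species

  ## miRNome: per family, a 5p and a 3p arm archetype; members share the
  ## first 19 nt of each arm and re-draw nt 20-22 independently.
  mat <- list(); pre <- list()
  for (f in seq_len(spec@nFamilies)) {
    shared <- length(sp) > 1L && stats::runif(1) < spec@orthologFraction
    members <- if (shared) {
      sort(sample(sp, sample(2:length(sp), 1L)))
    } else sample(sp, 1L)
    arch5 <- randRna(19L); arch3 <- randRna(19L)
    for (s in members) {
      si <- match(s, supportedSpecies())
      seq5 <- paste0(arch5, randRna(3L))
      seq3 <- paste0(arch3, randRna(3L))
      id5 <- sprintf("MIMAT%03d%d5", f, si)
      id3 <- sprintf("MIMAT%03d%d3", f, si)
      mat[[length(mat) + 1L]] <- data.frame(
        id = c(id5, id3),
        name = sprintf("%s-miR-%d-%s", s, f, c("5p", "3p")),
        sequence = c(seq5, seq3), stringsAsFactors = FALSE)
      pre[[length(pre) + 1L]] <- data.frame(
        id = sprintf("MI%03d%d", f, si),
        name = sprintf("%s-mir-%d", s, f),
        sequence = paste0(randRna(8L), seq5, randRna(10L), seq3,
                          randRna(8L)),
        stringsAsFactors = FALSE)
    }
  }
  mat <- do.call(rbind, mat)
  pre <- do.call(rbind, pre)
  matures <- MatureSet(id = mat$id, name = mat$name, sequence = mat$sequence)
  precursors <- PrecursorSet(id = pre$id, name = pre$name,
                             sequence = pre$sequence)

  ## Overdispersed counts: per-arm true RPM log-uniform over rpmRange.
  nm <- nrow(mat)
  trueRpm <- exp(stats::runif(nm, log(spec@rpmRange[1L]),
                              log(spec@rpmRange[2L])))
  libs <- round(stats::runif(spec@nExperiments, spec@libSizeRange[1L],
                             spec@libSizeRange[2L]))
  expIds <- sprintf("exp%02d", seq_len(spec@nExperiments))
  counts <- matrix(0L, nm, spec@nExperiments,
                   dimnames = list(mat$id, expIds))
  for (e in seq_len(spec@nExperiments)) {
    counts[, e] <- stats::rnbinom(nm, size = spec@nbDispersion,
                                  mu = trueRpm * libs[e] / 1e6)
  }
  libs <- pmax(libs, colSums(counts))      # library size bounds column sum
  expression <- MirExpression(counts,
                              librarySizes = stats::setNames(libs, expIds))

  ## Sparse PubMed associations (zero-inflated Poisson record counts).
  np <- nrow(pre)
  nPm <- ifelse(stats::runif(np) < spec@pubmedZeroProb, 0L,
                stats::rpois(np, spec@pubmedLambda))
  pmPool <- sample(1000000:9999999, sum(nPm))
  assoc <- split(pmPool, rep(seq_len(np), nPm))
  names(assoc) <- pre$id[as.integer(names(assoc))]
  pubmed <- PubmedMap(assoc)
  highconf <- pre$id[stats::runif(np) < spec@highconfFraction]

  ## UTRs with planted seed-complementary sites at disjoint positions.
  utrRows <- list(); siteRows <- list()
  for (u in seq_len(spec@utrCount)) {
    len <- sample(spec@utrLenRange[1L]:spec@utrLenRange[2L], 1L)
    s <- strsplit(randRna(len), "")[[1L]]
    taken <- integer()
    if (spec@plantedSitesPerUtr > 0L) {
      for (k in seq_len(spec@plantedSitesPerUtr)) {
        mi <- sample(nm, 1L)
        site <- strsplit(rnaRevComp(substr(mat$sequence[mi], 2L, 8L)),
                         "")[[1L]]
        for (try in 1:50) {
          pos <- sample(len - 6L, 1L)            # 1-based start
          if (!any((pos:(pos + 6L)) %in% taken)) break
        }
        if (any((pos:(pos + 6L)) %in% taken)) next
        taken <- c(taken, pos:(pos + 6L))
        s[pos:(pos + 6L)] <- site
        siteRows[[length(siteRows) + 1L]] <- data.frame(
          transcript_id = sprintf("NM_%06d", u),
          mirna_id = mat$id[mi], start = pos, end = pos + 6L,
          matched_7mer = paste(site, collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
    utrRows[[u]] <- data.frame(
      transcript_id = sprintf("NM_%06d", u),
      gene_symbol = sprintf("GENE%d", u),
      description = sprintf("synthetic 3'UTR %d", u),
      sequence = paste(s, collapse = ""), stringsAsFactors = FALSE)
  }
  utr <- do.call(rbind, utrRows)
  truthSites <- if (length(siteRows)) do.call(rbind, siteRows) else
    data.frame(transcript_id = character(), mirna_id = character(),
               start = integer(), end = integer(),
               matched_7mer = character(), stringsAsFactors = FALSE)

  paths <- c(mature = file.path(outdir, "mature.fa"),
             hairpin = file.path(outdir, "hairpin.fa"),
             counts = file.path(outdir, "counts.tsv"),
             pubmed = file.path(outdir, "pubmed.tsv"),
             highconf = file.path(outdir, "highconf.txt"),
             utr = file.path(outdir, "utr.fa"),
             truthScores = file.path(outdir, "truth_scores.tsv"),
             truthSites = file.path(outdir, "truth_sites.tsv"))
  writeMatureFasta(matures, paths[["mature"]])
  writeHairpinFasta(precursors, paths[["hairpin"]])
  writeExpressionTable(expression, paths[["counts"]])
  writePubmedMap(pubmed, paths[["pubmed"]])
  writeHighConfList(highconf, paths[["highconf"]])
  ## RefSeq-style DNA on disk; readers normalize back to RNA.
  writeFasta(paste(utr$transcript_id, utr$gene_symbol, utr$description,
                   sep = "|"),
             chartr("U", "T", utr$sequence), paths[["utr"]])

  truthScores <- oracleScores(outdir)
  writeResultsTsv(truthScores, paths[["truthScores"]])
  writeResultsTsv(truthSites, paths[["truthSites"]])
  invisible(list(paths = paths,
                 truth = list(scores = truthScores, sites = truthSites)))
}

#' Independent ground-truth oracle for the scoring rules
#'
#' Recomputes every criterion score, the composite, the functional call
#' and the mature-arm selection for a fixture directory by direct literal
#' application of the published bracket rules, in deliberately plain
#' straight-line code that shares nothing with the scoring implementation:
#' orthology is a character-by-character double loop over 5' prefixes,
#' abundance is total counts over total library size times one million,
#' and each bracket is a literal if/else chain with hard-coded constants.
#'
#' @param dir Directory holding mature.fa, hairpin.fa, counts.tsv,
#'   pubmed.tsv and highconf.txt.
#' @return data.frame with one row per precursor: precursor_id, pubmed,
#'   conservation, expression, mirbase, composite, is_functional,
#'   dominant_mature, secondary_mature.
#' @export
oracleScores <- function(dir) {
  matures <- readMatureFasta(file.path(dir, "mature.fa"))
  precursors <- readHairpinFasta(file.path(dir, "hairpin.fa"))
  expr <- readExpressionTable(file.path(dir, "counts.tsv"))
  pubmed <- readPubmedMap(file.path(dir, "pubmed.tsv"))
  highconf <- readHighConfList(file.path(dir, "highconf.txt"))
  joined <- attachMatures(precursors, matures)
  precursors <- joined$precursors

  mseq <- unname(mirSequence(matures))
  msp <- mirSpecies(matures)
  mid <- mirId(matures)
  marm <- unname(mirArm(matures))
  mname <- mirName(matures)
  cts <- SummarizedExperiment::assay(expr, "counts")
  totalLib <- sum(librarySizes(expr))

  rpmOf <- function(id) {
    i <- match(id, rownames(cts))
    if (is.na(i)) return(0)
    1e6 * sum(cts[i, ]) / totalLib
  }
  orthoCount <- function(j) {
    found <- character()
    for (k in seq_along(mseq)) {
      if (msp[k] == msp[j]) next
      L <- min(19L, nchar(mseq[j]), nchar(mseq[k]))
      same <- TRUE
      for (p in seq_len(L)) {
        if (substr(mseq[j], p, p) != substr(mseq[k], p, p)) {
          same <- FALSE; break
        }
      }
      if (same) found <- union(found, msp[k])
    }
    length(found)
  }

  rows <- vector("list", length(precursors))
  pids <- mirId(precursors)
  mlinks <- matureIdsOf(precursors)
  for (i in seq_along(precursors)) {
    arms <- mlinks[[i]]
    n <- length(pubmedIds(pubmed, pids[i]))
    if (n >= 4) pm <- 3 else if (n == 3) pm <- 2 else
      if (n == 2) pm <- 1 else pm <- 0
    cons <- 0; ex <- 0
    armRpm <- numeric(0)
    for (a in arms) {
      j <- match(a, mid)
      k <- orthoCount(j)
      if (k >= 2) cs <- 2 else if (k == 1) cs <- 1 else cs <- 0
      if (cs > cons) cons <- cs
      r <- rpmOf(a)
      armRpm[a] <- r
      if (r > 10) es <- 2 else if (r >= 1) es <- 1 else es <- 0
      if (es > ex) ex <- es
    }
    mb <- if (pids[i] %in% highconf) 1 else 0
    comp <- pm + cons + ex + mb
    fun <- comp >= 3
    ## dominant arm: highest RPM; ties prefer 5p, then smaller name
    best <- 1L
    for (a in seq_along(arms)) {
      ra <- armRpm[arms[a]]; rb <- armRpm[arms[best]]
      aj <- match(arms[a], mid); bj <- match(arms[best], mid)
      if (ra > rb) best <- a
      else if (ra == rb && a != best) {
        if (marm[aj] == "5p" && marm[bj] != "5p") best <- a
        else if (marm[aj] == marm[bj] && mname[aj] < mname[bj]) best <- a
      }
    }
    dom <- arms[best]
    sec <- NA_character_
    if (fun && length(arms) == 2L) {
      other <- arms[-best]
      if (armRpm[other] >= 0.10 * armRpm[dom] && armRpm[other] >= 5)
        sec <- other
    }
    rows[[i]] <- data.frame(
      precursor_id = pids[i], pubmed = pm, conservation = cons,
      expression = ex, mirbase = mb, composite = comp,
      is_functional = fun, dominant_mature = dom, secondary_mature = sec,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
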