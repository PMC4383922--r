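# Target-scanning workflow: sequence validation, seed extraction, 7-mer
# complementarity site finding against a naive all-window oracle, the
# surrogate score and both scan modes.

test_that("miRNA sequence validation enforces the 17-30 nt bounds", {
  ok <- validateMirnaSeq(" uagcuuauca gacugauguuga ")
  expect_equal(ok, "UAGCUUAUCAGACUGAUGUUGA")
  expect_equal(nchar(validateMirnaSeq(randomRna(17))), 17L)
  expect_equal(nchar(validateMirnaSeq(randomRna(30))), 30L)
  expect_error(validateMirnaSeq(randomRna(16)), "17-30")
  expect_error(validateMirnaSeq(randomRna(31)), "17-30")
  expect_error(validateMirnaSeq(paste0(randomRna(10), "N", randomRna(10))),
               "position 11")
})

test_that("target sequence validation enforces the 100-30000 nt bounds", {
  expect_error(validateTargetSeq(randomRna(99)), "100-30000")
  expect_equal(nchar(validateTargetSeq(randomRna(100))), 100L)
  expect_error(validateTargetSeq(paste(rep("A", 30001), collapse = "")),
               "100-30000")
  expect_equal(nchar(validateTargetSeq(chartr("U", "T", randomRna(150)))),
               150L)
})

test_that("the seed is miRNA positions 2-8 and always 7 nt", {
  expect_equal(seedOf("UAGCUUAUCAGACUGAUGUUGA"), "AGCUUAU")
  set.seed(1)
  for (i in 1:20) expect_equal(nchar(seedOf(randomRna(17))), 7L)
  a <- randomRna(22)
  b <- paste0(substr(a, 1, 8), randomRna(14))
  expect_equal(seedOf(a), seedOf(b))
  ## configurable positions
  expect_equal(seedOf("UAGCUUAUCAGACUGAUGUUGA",
                      scanParams(seedPositions = c(1L, 7L))), "UAGCUUA")
})

test_that("seed sites are exactly the reverse-complement occurrences", {
  mir <- "UAGCUUAUCAGACUGAUGUUGA"        # seed AGCUUAU, revcomp AUAAGCU
  rc <- naiveRevComp(seedOf(mir))
  expect_equal(rc, "AUAAGCU")

  none <- paste(rep("C", 120), collapse = "")
  expect_equal(nrow(findSeedSites("m", mir, "t", none)), 0L)

  ## planted between G runs (site has no G; G background cannot alias it)
  flank <- paste(rep("G", 50), collapse = "")
  target <- paste0(flank, rc, flank)
  hit <- findSeedSites("m", mir, "t", target)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 50L)
  expect_equal(hit$end, 57L)
  expect_equal(hit$matched_7mer, rc)
  expect_equal(substr(target, hit$start + 1, hit$end), rc)

  ## overlapping tandem occurrences are all reported
  polyC <- "CCCCCCC"                     # revcomp of seed GGGGGGG
  mirG <- paste0("A", "GGGGGGG", randomRna(14))
  expect_equal(findSeedSites("m", mirG, "t",
                             paste(rep("C", 10), collapse = ""))$start,
               0:3)
})

test_that("site finding agrees with the naive all-window oracle", {
  set.seed(99)
  for (i in 1:200) {
    mir <- randomRna(sample(17:30, 1))
    target <- randomRna(sample(30:200, 1))
    got <- findSeedSites("m", mir, "t", target)$start
    want <- naiveSiteStarts(target, naiveRevComp(seedOf(mir))) - 1L
    expect_identical(got, as.integer(want))
  }
})

test_that("adding flanking sequence never removes a site", {
  set.seed(5)
  for (i in 1:20) {
    mir <- randomRna(22)
    target <- randomRna(150)
    before <- findSeedSites("m", mir, "t", target)
    shifted <- findSeedSites("m", mir, "t", paste0(randomRna(10), target,
                                                   randomRna(10)))
    expect_true(all((before$start + 10L) %in% shifted$start))
  }
})

test_that("the surrogate score is clamped to 50-100 and monotone in sites", {
  one <- data.frame(start = 0L)
  expect_error(siteScore(one[0, , drop = FALSE], 2000), "at least one")
  set.seed(3)
  for (L in c(100, 500, 2000, 30000)) {
    scores <- vapply(1:12, function(n) siteScore(n, L), 0L)
    expect_true(all(scores >= 50L & scores <= 100L))
    expect_true(all(diff(scores) >= 0))
  }
  expect_equal(siteScore(1000, 100), 100L)
})

test_that("custom-miRNA scans rank targets by descending score", {
  mir <- "UAGCUUAUCAGACUGAUGUUGA"
  rc <- naiveRevComp(seedOf(mir))
  bgC <- function(n) paste(rep("C", n), collapse = "")
  utrs <- UtrSet(
    transcriptId = c("NM_3", "NM_1", "NM_2"),
    geneSymbol = c("GC", "GA", "GB"),
    sequence = c(bgC(300),                                # no site
                 paste0(bgC(100), rc, bgC(100)),          # one site
                 paste0(bgC(50), rc, bgC(50), rc, bgC(50))))  # two sites
  res <- scanCustomMirna(mir, utrs)
  expect_equal(nrow(res), 2L)
  expect_equal(res$rank, 1:2)
  expect_equal(res$target_id, c("NM_2", "NM_1"))          # 2 sites first
  expect_equal(res$n_sites, c(2L, 1L))
  expect_equal(res$site_positions[2], "101-107")
  expect_true(all(diff(res$surrogate_score) <= 0))

  expect_equal(nrow(scanCustomMirna(mir, UtrSet("NM_9", bgC(200)))), 0L)
})

test_that("equal-score rows break ties by ascending id, stably", {
  mir <- "UAGCUUAUCAGACUGAUGUUGA"
  rc <- naiveRevComp(seedOf(mir))
  bgC <- function(n) paste(rep("C", n), collapse = "")
  same <- paste0(bgC(100), rc, bgC(100))
  utrs <- UtrSet(transcriptId = c("NM_B", "NM_A"), sequence = c(same, same))
  res <- scanCustomMirna(mir, utrs)
  expect_equal(res$target_id, c("NM_A", "NM_B"))
  ## permutation invariance of input order
  res2 <- scanCustomMirna(mir, utrs[2:1])
  expect_equal(res, res2)
})

test_that("custom-target scans report each miRNA with sites in the target", {
  seeds <- c("AGCUUAU", "CGAUCGA")
  mirs <- vapply(seeds, function(s) paste0("U", s, randomRna(14)), "")
  set.seed(11)
  decoys <- replicate(3, paste0("U", "GGGGGGG", randomRna(14)))
  mirnome <- MatureSet(
    id = sprintf("M%d", 1:5),
    name = sprintf("hsa-miR-%d-5p", c(11, 22, 33, 44, 55)),
    sequence = c(mirs, decoys))
  bgG <- function(n) paste(rep("G", n), collapse = "")
  target <- paste0(bgG(60), naiveRevComp(seeds[1]), bgG(60),
                   naiveRevComp(seeds[2]), bgG(60))
  res <- scanCustomTarget(target, mirnome)
  expect_equal(nrow(res), 2L)
  expect_setequal(res$mirna_name, c("hsa-miR-11-5p", "hsa-miR-22-5p"))

  expect_error(scanCustomTarget(randomRna(99), mirnome), "100-30000")

  ## identical sequences under two names score identically, adjacent rows
  dup <- MatureSet(id = c("Ma", "Mb"),
                   name = c("hsa-miR-91-5p", "hsa-miR-92-5p"),
                   sequence = rep(mirs[1], 2))
  rdup <- scanCustomTarget(target, dup)
  expect_equal(rdup$surrogate_score[1], rdup$surrogate_score[2])
  expect_equal(rdup$mirna_name, c("hsa-miR-91-5p", "hsa-miR-92-5p"))
})

test_that("every reported site satisfies its own revcomp invariant", {
  set.seed(21)
  for (i in 1:30) {
    mir <- randomRna(20)
    ## plant one guaranteed occurrence so the invariant is always exercised
    target <- paste0(randomRna(150), naiveRevComp(seedOf(mir)),
                     randomRna(150))
    sites <- findSeedSites("m", mir, "t", target)
    expect_gte(nrow(sites), 1L)
    expect_true(all(substring(target, sites$start + 1, sites$end) ==
                      sites$matched_7mer))
    expect_true(all(sites$matched_7mer == naiveRevComp(seedOf(mir))))
  }
})
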