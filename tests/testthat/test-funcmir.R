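# The four criterion scores, the composite, the functional call, the
# mature-arm selection and the criterion-removal contribution analysis.

test_that("PubMed scoring follows the published brackets", {
  expect_equal(pubmedScore(2), 1L)
  expect_equal(pubmedScore(3), 2L)
  expect_equal(pubmedScore(c(4, 17)), c(3L, 3L))
  expect_equal(pubmedScore(c(0, 1)), c(0L, 0L))
  expect_error(pubmedScore(-1), "negative")
})

test_that("conservation scoring follows the published brackets", {
  expect_equal(conservationScore(0), 0L)
  expect_equal(conservationScore(1), 1L)
  expect_equal(conservationScore(c(2, 3)), c(2L, 2L))
})

test_that("expression scoring is inclusive on 1-10 and strict above 10", {
  expect_equal(expressionScore(0.2), 0L)
  expect_equal(expressionScore(c(1, 10)), c(1L, 1L))
  expect_equal(expressionScore(15), 2L)
  expect_equal(expressionScore(10.0001), 2L)
  expect_equal(expressionScore(0.9999), 0L)
})

test_that("curated-status scoring is the 0/1 indicator", {
  expect_equal(mirbaseScore(TRUE), 1L)
  expect_equal(mirbaseScore(FALSE), 0L)
  expect_equal(mirbaseScore(c(TRUE, TRUE)), c(1L, 1L))
})

test_that("orthology requires perfect 5'-end 19-nt prefix identity", {
  q <- "UAGCUUAUCAGACUGAUGUUGA"          # 22 nt hsa query
  full <- MatureSet(id = "m1", name = "mmu-miR-1-5p", sequence = q)
  expect_equal(findOrthologs(q, "hsa", full), "mmu")

  diverged <- MatureSet(id = "r1", name = "rno-miR-1-5p",
                        sequence = paste0(substr(q, 1, 19), "CCC"))
  expect_equal(findOrthologs(q, "hsa", diverged), "rno")

  mismatch5 <- paste0(substr(q, 1, 4), "G", substr(q, 6, 22))
  other <- MatureSet(id = "c1", name = "cfa-miR-1-5p", sequence = mismatch5)
  expect_equal(findOrthologs(q, "hsa", other), character())

  ## own species never counts, even on identity
  self <- MatureSet(id = "h1", name = "hsa-miR-1-5p", sequence = q)
  expect_equal(findOrthologs(q, "hsa", self), character())
  expect_error(findOrthologs("", "hsa", self), "empty")
})

test_that("sub-19-nt matures compare over the shorter length, symmetrically", {
  short <- paste(rep("ACGU", 5), collapse = "")          # 20 nt
  q17 <- substr(short, 1, 17)
  a <- MatureSet(id = "a", name = "hsa-miR-2-5p", sequence = short)
  b <- MatureSet(id = "b", name = "mmu-miR-2-5p", sequence = q17)
  expect_equal(findOrthologs(q17, "mmu", a), "hsa")
  expect_equal(findOrthologs(short, "hsa", b), "mmu")
})

test_that("orthology prefix relation is symmetric on random pairs", {
  set.seed(42)
  for (i in 1:50) {
    la <- sample(17:25, 1); lb <- sample(17:25, 1)
    shared <- randomRna(19)
    sa <- if (runif(1) < 0.5) paste0(shared, randomRna(max(0, la - 19)))
          else randomRna(la)
    sb <- if (runif(1) < 0.5) paste0(shared, randomRna(max(0, lb - 19)))
          else randomRna(lb)
    sa <- substr(sa, 1, la); sb <- substr(sb, 1, lb)
    A <- MatureSet(id = "a", name = "hsa-miR-3-5p", sequence = sa)
    B <- MatureSet(id = "b", name = "mmu-miR-3-5p", sequence = sb)
    expect_equal(length(findOrthologs(sa, "hsa", B)) > 0,
                 length(findOrthologs(sb, "mmu", A)) > 0)
  }
})

test_that("pooled RPM is total counts over total library size", {
  x1 <- MirExpression(matrix(10L, 1, 1, dimnames = list("m", "e1")),
                      librarySizes = c(e1 = 1e6))
  expect_equal(unname(pooledRpm(x1, "m")), 10)

  x2 <- MirExpression(matrix(c(5L, 5L), 1, 2,
                             dimnames = list("m", c("e1", "e2"))),
                      librarySizes = c(e1 = 5e5, e2 = 15e5))
  expect_equal(unname(pooledRpm(x2, "m")), 5)          # 1e6 * 10 / 2e6
  expect_equal(unname(pooledRpm(x2, "absent")), 0)

  ## the mean-of-RPMs alternative is selectable and differs here
  pMean <- scoringParams(rpmAggregation = "mean")
  expect_equal(unname(pooledRpm(x2, "m", pMean)), mean(c(10, 10 / 3)))
})

test_that("precursor scoring combines the four criteria (max over arms)", {
  b <- makeTinyBundle(nPmids = 4, nOrthoSpecies = 2, rpm5p = 15,
                      rpm3p = 0.5, highConf = TRUE)
  sc <- scorePrecursors(b$precursors, b$matures, b$expr, b$pubmed,
                        b$highconf)
  expect_equal(sc$pubmed, 3L)
  expect_equal(sc$conservation, 2L)
  expect_equal(sc$expression, 2L)
  expect_equal(sc$mirbase, 1L)
  expect_equal(sc$composite, 8L)

  z <- makeTinyBundle(nPmids = 0, nOrthoSpecies = 0, rpm5p = 0,
                      rpm3p = 0, highConf = FALSE)
  scz <- scorePrecursors(z$precursors, z$matures, z$expr, z$pubmed,
                         z$highconf)
  expect_equal(scz$composite, 0L)
  expect_equal(unlist(scz[, c("pubmed", "conservation", "expression",
                              "mirbase")], use.names = FALSE),
               rep(0L, 4))

  lo <- makeTinyBundle(nPmids = 2, nOrthoSpecies = 1, rpm5p = 0.5,
                       rpm3p = 0, highConf = FALSE)
  scl <- scorePrecursors(lo$precursors, lo$matures, lo$expr, lo$pubmed,
                         lo$highconf)
  expect_equal(unlist(scl[, c("pubmed", "conservation", "expression",
                              "mirbase")], use.names = FALSE),
               c(1L, 1L, 0L, 0L))
  expect_equal(scl$composite, 2L)
})

test_that("a precursor without mature arms cannot be scored", {
  b <- makeTinyBundle()
  p <- PrecursorSet(id = "MIX1", name = "hsa-mir-901",
                    sequence = "ACGUACGUACGUACGUACGUACGUACGU")
  expect_error(scorePrecursors(p, b$matures, b$expr, b$pubmed, b$highconf),
               "no mature arms")
})

test_that("functional classification is composite >= 3 and monotone", {
  expect_true(classifyFunctional(3))
  expect_false(classifyFunctional(2))
  expect_true(classifyFunctional(8))
  comp <- 0:8
  cls <- classifyFunctional(comp)
  expect_true(all(diff(cls) >= 0))       # monotone in composite
})

test_that("mature-arm selection applies the 10% and 5-RPM rules inclusively", {
  both <- selectFunctionalMatures(c(a = 100, b = 10))
  expect_equal(both, list(dominant = "a", secondary = "b"))

  floor5 <- selectFunctionalMatures(c(a = 100, b = 4))
  expect_equal(floor5$secondary, NA_character_)

  frac <- selectFunctionalMatures(c(a = 90, b = 9))
  expect_equal(frac$secondary, "b")       # 9 >= 10% of 90 and >= 5
  atBoundary <- selectFunctionalMatures(c(a = 50, b = 5))
  expect_equal(atBoundary$secondary, "b") # both boundaries inclusive

  under <- selectFunctionalMatures(c(a = 60, b = 5.9))
  expect_equal(under$secondary, NA_character_)  # 5.9 < 10% of 60

  single <- selectFunctionalMatures(c(a = 7))
  expect_equal(single, list(dominant = "a", secondary = NA_character_))

  ## ties prefer the 5p arm, then the lexicographically smaller name
  tie <- selectFunctionalMatures(c(x3 = 20, x5 = 20),
                                 arm = c("3p", "5p"),
                                 name = c("hsa-miR-7-3p", "hsa-miR-7-5p"))
  expect_equal(tie$dominant, "x5")
  tieNm <- selectFunctionalMatures(c(b = 20, a = 20),
                                   arm = c("3p", "3p"), name = c("b", "a"))
  expect_equal(tieNm$dominant, "a")
  expect_error(selectFunctionalMatures(numeric()), "no mature arms")
})

test_that("criterion-removal analysis finds the required criteria", {
  expect_equal(requiredCriteria(c(pubmed = 3, conservation = 0,
                                  expression = 0, mirbase = 0)), "pubmed")
  expect_equal(requiredCriteria(c(pubmed = 3, conservation = 2,
                                  expression = 2, mirbase = 1)),
               character())
  expect_equal(requiredCriteria(c(pubmed = 1, conservation = 1,
                                  expression = 0, mirbase = 0)),
               character())     # composite 2: below threshold
  expect_equal(requiredCriteria(c(pubmed = 0, conservation = 2,
                                  expression = 2, mirbase = 0)),
               c("conservation", "expression"))
  expect_equal(requiredCriteria(c(pubmed = 1, conservation = 2,
                                  expression = 1, mirbase = 0)),
               "conservation")   # only its removal drops 4 below 3
  ## required criteria always have nonzero scores
  set.seed(7)
  for (i in 1:40) {
    s <- c(pubmed = sample(0:3, 1), conservation = sample(0:2, 1),
           expression = sample(0:2, 1), mirbase = sample(0:1, 1))
    req <- requiredCriteria(s)
    expect_true(all(s[req] > 0))
  }
})

test_that("supporting-criterion counts are the number of nonzero scores", {
  expect_equal(nSupportingCriteria(c(pubmed = 3, conservation = 2,
                                     expression = 2, mirbase = 1)), 4L)
  expect_equal(nSupportingCriteria(c(pubmed = 0, conservation = 0,
                                     expression = 0, mirbase = 0)), 0L)
  expect_equal(nSupportingCriteria(c(pubmed = 1, conservation = 0,
                                     expression = 2, mirbase = 0)), 2L)
})

test_that("each criterion score is monotone in its raw input", {
  ns <- 0:20
  expect_true(all(diff(pubmedScore(ns)) >= 0))
  expect_true(all(diff(conservationScore(ns)) >= 0))
  rpms <- seq(0, 25, by = 0.25)
  expect_true(all(diff(expressionScore(rpms)) >= 0))
})

test_that("annotateFunctional emits the documented per-precursor table", {
  b <- makeTinyBundle(nPmids = 3, nOrthoSpecies = 1, rpm5p = 80,
                      rpm3p = 12, highConf = FALSE)
  ann <- annotateFunctional(b$precursors, b$matures, b$expr, b$pubmed,
                            b$highconf)
  expect_equal(names(ann),
               c("precursor_id", "name", "species", "pubmed_score",
                 "conservation_score", "expression_score", "mirbase_score",
                 "composite", "is_functional", "dominant_mature",
                 "secondary_mature", "n_supporting_criteria",
                 "required_criteria"))
  expect_equal(ann$composite, 2L + 1L + 2L + 0L)
  expect_true(ann$is_functional)
  expect_equal(ann$dominant_mature, "MIMATX5")
  expect_equal(ann$secondary_mature, "MIMATX3")   # 12 >= 8 and >= 5
  expect_equal(ann$n_supporting_criteria, 3L)
})
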