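test_that("template aligns to itself without gaps", {
  a <- defaultTemplateAnchor()
  aln <- alignToTemplate(a@template, a)
  expect_true(attr(aln, "alignable"))
  expect_identical(paste(aln[1, ], collapse = ""), a@template)
  expect_identical(unname(aln[1, a@helixColumns]), c("R", "D", "E", "R"))
})

test_that("short fingers gain gap columns; unalignable rows are flagged", {
  a <- defaultTemplateAnchor()
  ## 23-residue C-X2-C variant of the template: 2 residues fewer in the
  ## first inter-Cys spacer
  f23 <- "YACESCDRRFSRSDELTRHIRIH"
  aln <- alignToTemplate(f23, a)
  expect_true(attr(aln, "alignable"))
  expect_equal(sum(aln[1, ] == "-"), 2L)
  expect_identical(unname(aln[1, a@helixColumns]), c("R", "D", "E", "R"))

  bad <- alignToTemplate(strrep("A", 25), a)
  expect_false(attr(bad, "alignable"))
  expect_true(all(bad[1, ] == "-"))

  ## rows preserve input order
  both <- alignToTemplate(c(x = strrep("A", 25), y = a@template), a)
  expect_identical(attr(both, "alignable"), c(FALSE, TRUE))
})

test_that("extra Cys/His do not divert the scaffold anchoring", {
  a <- defaultTemplateAnchor()
  ## His inserted in the spacer between Cys2 and the recognition helix
  tpl <- strsplit(a@template, "")[[1]]
  tpl[12] <- "H"
  aln <- alignToTemplate(paste(tpl, collapse = ""), a)
  expect_true(attr(aln, "alignable"))
  expect_identical(unname(aln[1, a@helixColumns]), c("R", "D", "E", "R"))
})

test_that("propensities reproduce exact counts and normalize", {
  a <- defaultTemplateAnchor()
  aln4 <- alignToTemplate(rep(a@template, 4), a)
  tab <- computePropensities(aln4, pseudocount = 0, anchor = a)
  tpl <- strsplit(a@template, "")[[1]]
  for (j in c(1, 5, 14, 20))
    expect_equal(tab@prob[tpl[j], j], 1)

  ## 5 rows with {R,R,R,A,K} at the -1 column
  seqs <- vapply(c("R", "R", "R", "A", "K"), function(r) {
    x <- tpl; x[14] <- r; paste(x, collapse = "")
  }, character(1))
  tab5 <- computePropensities(alignToTemplate(seqs, a), pseudocount = 0,
                              anchor = a)
  expect_equal(tab5@prob["R", 14], 0.6)
  expect_equal(tab5@prob["A", 14], 0.2)
  expect_equal(tab5@prob["K", 14], 0.2)
  expect_equal(tab5@pMax[["-1"]], 0.6)
  expect_equal(tab5@pMaxResidue[["-1"]], "R")

  ## columns sum to 1 for a random alignment with pseudocounts
  set.seed(201)
  gen <- generateCohort(CohortParams(nProteins = 10, seed = 3))
  co <- cohortFromGenerated(gen)
  alnR <- alignToTemplate(domains(co)$sequence, a)
  tabR <- computePropensities(alnR, pseudocount = 0.5, anchor = a)
  expect_true(all(abs(colSums(tabR@prob) - 1) < 1e-9))

  expect_error(computePropensities(alignToTemplate(a@template, a),
                                   anchor = a), "at least 2")
})

test_that("specificity score honours its contract in both orientations", {
  ## maximal residues in every column give exactly 1
  tabM <- mkToyTable(p = c(0.3, 0.6, 0.2, 0.3), pmax = c(0.3, 0.6, 0.2, 0.3))
  resM <- specificityScore(c("A", "A", "A", "A"), tabM)
  expect_equal(resM$score, 1)
  expect_equal(specificityScore(c("A", "A", "A", "A"), tabM,
                                orientation = "as_printed")$score, 1)

  ## hand-evaluated toy: per-position (P, Pmax) =
  ## (0.1,0.3), (0.6,0.6), (0.2,0.2), (0.1,0.3)
  tab <- mkToyTable(p = c(0.1, 0.6, 0.2, 0.1), pmax = c(0.3, 0.6, 0.2, 0.3))
  res <- specificityScore(c("A", "A", "A", "A"), tab)
  expect_equal(res$score, log(0.3 * 0.6 * 0.2 * 0.3) /
                 log(0.1 * 0.6 * 0.2 * 0.1))
  expect_equal(res$score, 0.6732962, tolerance = 1e-6)
  ## the as-printed orientation is the reciprocal
  resP <- specificityScore(c("A", "A", "A", "A"), tab,
                           orientation = "as_printed")
  expect_equal(resP$score, 1 / res$score)

  expect_error(specificityScore(c("A", "A", "A", "-"), tab), "alphabet")
  expect_error(specificityScore(c("A", "A"), tab), "4 recognition")
})

test_that("consistent scores decrease as any residue gets rarer", {
  pmax <- c(0.3, 0.6, 0.2, 0.3)
  grid <- c(0.25, 0.15, 0.08, 0.03, 0.01)
  for (pos in 1:4) {
    last <- Inf
    for (g in grid) {
      p <- pmin(c(0.2, 0.5, 0.15, 0.2), pmax)
      p[pos] <- min(g, pmax[pos])
      s <- specificityScore(c("A", "A", "A", "A"),
                            mkToyTable(p, pmax))$score
      expect_lt(s, last)
      last <- s
    }
  }
})

test_that("score orientations bracket 1 on random tables", {
  set.seed(202)
  a <- defaultTemplateAnchor()
  gen <- generateCohort(CohortParams(nProteins = 15, seed = 9))
  co <- cohortFromGenerated(gen)
  aln <- alignToTemplate(domains(co)$sequence, a)
  tab <- computePropensities(aln, anchor = a)
  for (k in 1:100) {
    res4 <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 4,
                   replace = TRUE)
    sc <- specificityScore(res4, tab)$score
    sp <- specificityScore(res4, tab, orientation = "as_printed")$score
    expect_gt(sc, 0); expect_lte(sc, 1)
    expect_gte(sp, 1)
  }
})

test_that("cohort specificity annotation scores alignable domains", {
  set.seed(203)
  co <- curateCohort(cohortFromGenerated(
    generateCohort(CohortParams(nProteins = 15, seed = 4))))$kept
  co <- annotateSpecificity(co)
  d <- domains(co)
  expect_false(anyNA(d$specificity_score))
  expect_true(all(d$specificity_score > 0 & d$specificity_score <= 1))
  ## deterministic on rescoring
  co2 <- annotateSpecificity(co)
  expect_identical(domains(co2)$specificity_score, d$specificity_score)

  ## a cohort built entirely from column-maximal residues scores 1.0
  coMax <- curateCohort(cohortFromGenerated(generateCohort(
    CohortParams(nProteins = 10, seed = 5, specMaxFraction = 1))))$kept
  coMax <- annotateSpecificity(coMax)
  expect_true(all(domains(coMax)$specificity_score == 1))
})

test_that("position composition equals raw frequency counting", {
  a <- defaultTemplateAnchor()
  aln1 <- alignToTemplate(a@template, a)
  pc1 <- positionComposition(aln1)
  tpl <- strsplit(a@template, "")[[1]]
  for (j in seq_along(tpl))
    expect_equal(pc1[tpl[j], j], 100)

  set.seed(204)
  gen <- generateCohort(CohortParams(nProteins = 5, seed = 6))
  aln <- alignToTemplate(domains(cohortFromGenerated(gen))$sequence, a)
  pc <- positionComposition(aln)
  expect_true(all(abs(colSums(pc) - 100) < 1e-9))
  ## agrees with pseudocount-0 propensities
  tab0 <- computePropensities(aln, pseudocount = 0, anchor = a)
  expect_equal(unname(pc / 100), unname(tab0@prob), tolerance = 1e-12)
  expect_true(all(pc["-", ] >= 0))
})
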