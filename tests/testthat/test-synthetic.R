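test_that("generated domains meet their charge targets exactly", {
  set.seed(501)
  a <- defaultTemplateAnchor()
  for (k in 1:50) {
    nPos <- sample(2:10, 1)   # >= 2 scaffold His
    nNeg <- sample(0:4, 1)
    s <- generateDomainSequence(nPos, nNeg, recResidues = NEUTRAL_REC)
    expect_equal(nchar(s), 25L)
    chars <- strsplit(s, "")[[1]]
    expect_equal(sum(chars %in% c("K", "R", "H")), nPos)
    expect_equal(sum(chars %in% c("D", "E")), nNeg)
    expect_equal(netCharge(s), nPos - nNeg)
    ## scaffold ligands in place and alignable
    expect_identical(chars[a@scaffoldColumns], c("C", "C", "H", "H"))
    expect_true(attr(alignToTemplate(s, a), "alignable"))
  }
  ## recognition residues are reported and placed
  s <- generateDomainSequence(6, 1, recResidues = c("R", "S", "N", "R"))
  expect_identical(unname(attr(s, "recognition")), c("R", "S", "N", "R"))
  expect_identical(strsplit(s, "")[[1]][a@helixColumns],
                   c("R", "S", "N", "R"))

  ## His-neutral convention: scaffold His are uncharged, so (0, 0) works
  convHN <- ChargeConvention(hisPositive = FALSE)
  s0 <- generateDomainSequence(0, 0, conv = convHN,
                               recResidues = NEUTRAL_REC)
  expect_equal(netCharge(s0, convHN), 0L)

  expect_error(generateDomainSequence(1, 0, recResidues = NEUTRAL_REC),
               "below the scaffold")
  expect_error(generateDomainSequence(15, 8, recResidues = NEUTRAL_REC),
               "exceed")
  expect_error(generateDomainSequence(-1, 0), ">= 0")
})

test_that("cohort generation is bit-identical for identical seeds", {
  g1 <- generateCohort(CohortParams(nProteins = 8, seed = 42))
  g2 <- generateCohort(CohortParams(nProteins = 8, seed = 42))
  expect_identical(g1$sequences, g2$sequences)
  expect_identical(g1$domainTable, g2$domainTable)
  expect_identical(g1$truth, g2$truth)
  g3 <- generateCohort(CohortParams(nProteins = 8, seed = 43))
  expect_false(identical(g1$sequences, g3$sequences))
})

test_that("generated cohorts obey their structural parameters", {
  gen <- generateCohort(CohortParams(nProteins = 60, seed = 7))
  expect_length(gen$sequences, 60L)
  expect_true(all(gen$truth$n_domains >= 3 & gen$truth$n_domains <= 15))
  expect_equal(gen$truth$n_domains,
               as.vector(table(factor(gen$domainTable$protein_id,
                                      levels = gen$truth$protein_id))))
  ## linkers have the configured length at both ends and between domains
  dt <- gen$domainTable
  first <- dt[!duplicated(dt$protein_id), ]
  expect_true(all(first$start == 6L))
  ## every domain is 25 residues
  expect_true(all(dt$end - dt$start + 1L == 25L))
  ## truth abundance is echoed in the abundance vector
  expect_identical(unname(gen$abundance), gen$truth$abundance)
  expect_true(all(gen$truth$pct_asym_true %in% c(0, 100)))
  expect_identical(gen$truth$injected_asym, gen$truth$pct_asym_true == 100)
  ## empty cohort is valid
  g0 <- generateCohort(CohortParams(nProteins = 0, seed = 1))
  expect_length(g0$sequences, 0L)
  expect_equal(nrow(g0$domainTable), 0L)
})

test_that("background charge draws match their configured means", {
  ## pAsymProtein = 0: all domains from the background model
  gen <- generateCohort(CohortParams(nProteins = 150, seed = 11,
                                     pAsymProtein = 0))
  co <- annotateCharges(cohortFromGenerated(gen))
  st <- cohortChargeStats(co)
  n <- st$n_domains
  ## means within 4 standard errors of the generation targets (clipping
  ## perturbs them only slightly)
  expect_lt(abs(st$pos_mean - 6.5), 4 * 1.4 / sqrt(n))
  expect_lt(abs(st$neg_mean - 1.6), 4 * 1.0 / sqrt(n))
})

test_that("injected proteins alternate high and low net charge", {
  gen <- generateCohort(CohortParams(nProteins = 80, seed = 13,
                                     pAsymProtein = 1))
  expect_true(all(gen$truth$injected_asym))
  co <- annotateCharges(cohortFromGenerated(gen))
  d <- as.data.frame(domains(co))
  odd <- d$net_charge[d$index %% 2L == 1L]
  evn <- d$net_charge[d$index %% 2L == 0L]
  ## targets 7 and 1; the low target is floored by scaffold His and any
  ## Arg recognition residues, so its realized mean sits between 1 and 3
  expect_gt(mean(odd), 6.5)
  expect_lt(mean(evn), 3)
  expect_gt(mean(odd) - mean(evn), 4)
  ## nearly all adjacent pairs are electrostatically asymmetric
  co <- annotateAsymmetry(co)
  expect_gt(mean(proteins(co)$pct_asym_nonspec), 75)
})

test_that("abundance follows the configured log-linear coupling", {
  gen <- generateCohort(CohortParams(nProteins = 400, seed = 17,
                                     abundanceBeta = 1))
  tr <- gen$truth
  lo <- log(tr$abundance)
  ## E[log ab] = log(2) - beta * pct/100; difference of group means ~ beta
  d_mean <- mean(lo[tr$pct_asym_true == 0]) -
    mean(lo[tr$pct_asym_true == 100])
  expect_lt(abs(d_mean - 1), 0.25)
  ## beta = 0 removes the coupling
  gen0 <- generateCohort(CohortParams(nProteins = 400, seed = 17,
                                      abundanceBeta = 0))
  tr0 <- gen0$truth
  d0 <- mean(log(tr0$abundance[tr0$pct_asym_true == 0])) -
    mean(log(tr0$abundance[tr0$pct_asym_true == 100]))
  expect_lt(abs(d0), 0.25)
})

test_that("simulated cohorts round-trip through the input readers", {
  dir <- withr::local_tempdir()
  params <- CohortParams(nProteins = 12, seed = 19)
  paths <- simulateCohort(params, dir)
  expect_true(all(file.exists(unlist(paths))))
  gen <- generateCohort(params)
  seqs <- readProteinFasta(paths$fasta)
  expect_identical(unname(as.character(seqs)), unname(gen$sequences))
  dt <- readDomainTable(paths$domains)
  expect_equal(dt$start, gen$domainTable$start)
  ab <- readAbundance(paths$abundance)
  expect_equal(unname(ab[gen$truth$protein_id]),
               unname(gen$abundance), tolerance = 1e-12)
  ## assembled cohorts from disk and from memory are equal
  coD <- assembleCohort(seqs, dt, ab)
  coM <- cohortFromGenerated(gen)
  expect_equal(as.data.frame(domains(coD)), as.data.frame(domains(coM)))
  meta <- jsonlite::read_json(paths$metadata)
  expect_equal(meta$seed, 19L)
  expect_equal(meta$n_proteins, 12L)
})

test_that("coupling recovery finds the injected association", {
  gen <- generateCohort(CohortParams(nProteins = 100, seed = 23))
  rec <- recoverCoupling(gen, stages = "nonspec")
  expect_false(rec$nonspec$underpowered)
  expect_lt(rec$nonspec$pearson_r, 0)
  expect_gt(rec$nonspec$mean_symmetric, rec$nonspec$mean_asymmetric)
  ## truth travels with the result
  expect_equal(nrow(rec$truth), 100L)
  ## from-disk run agrees with the in-memory run
  dir <- withr::local_tempdir()
  simulateCohort(gen, dir)
  recD <- recoverCoupling(dir, stages = "nonspec")
  expect_equal(recD$nonspec$pearson_r, rec$nonspec$pearson_r,
               tolerance = 1e-9)
  ## failures carry the stage name
  expect_error(recoverCoupling(withr::local_tempdir()),
               "stage 'io_curation'")
})
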