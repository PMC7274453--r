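test_that("non-specific pair rule matches worked examples", {
  ## both conditions fire
  r <- classifyPairNonspec(-4.5, 4.5)
  expect_true(r$asymmetric); expect_true(r$cond_neg); expect_true(r$cond_diff)
  ## difference large but neither member below -2e: symmetric under "and"
  r2 <- classifyPairNonspec(-1, 4)
  expect_false(r2$asymmetric)
  expect_false(r2$cond_neg); expect_true(r2$cond_diff)
  expect_true(classifyPairNonspec(-1, 4,
    AsymmetryConfig(pairRuleNonspec = "or"))$asymmetric)
  expect_true(classifyPairNonspec(-1, 4,
    AsymmetryConfig(pairRuleNonspec = "diff_only"))$asymmetric)
  ## member below -2e but difference small: symmetric under "and"
  r3 <- classifyPairNonspec(-3, -2)
  expect_false(r3$asymmetric)
  expect_true(r3$cond_neg); expect_false(r3$cond_diff)
  ## boundary: |diff| exactly sigma counts (>=), charge exactly at the
  ## threshold does not (<)
  expect_true(classifyPairNonspec(-2.5, 0.5)$asymmetric)
  expect_false(classifyPairNonspec(-2, 1)$asymmetric)
  expect_error(classifyPairNonspec(NA, 1), "missing")
})

test_that("specific pair rule matches worked examples", {
  ## difference 0.25 >= 0.2
  expect_true(classifyPairSpec(0.9, 0.65)$asymmetric)
  ## low score alone suffices under "either_or_both"
  r <- classifyPairSpec(0.55, 0.7)
  expect_true(r$asymmetric)
  expect_true(r$cond_low); expect_false(r$cond_diff)
  expect_false(classifyPairSpec(0.9, 0.9)$asymmetric)
  ## contrast_only: exactly one member below the threshold
  cfgC <- AsymmetryConfig(pairRuleSpec = "contrast_only")
  expect_true(classifyPairSpec(0.55, 0.7, cfgC)$asymmetric)
  expect_false(classifyPairSpec(0.5, 0.55, cfgC)$asymmetric)  # both low
  cfgD <- AsymmetryConfig(pairRuleSpec = "diff_only")
  expect_false(classifyPairSpec(0.55, 0.7, cfgD)$asymmetric)
  ## boundaries: score exactly 0.6 is not low; diff exactly 0.2 counts
  expect_false(classifyPairSpec(0.6, 0.79)$asymmetric)
  expect_true(classifyPairSpec(0.6, 0.8)$asymmetric)
  expect_error(classifyPairSpec(0.9, NA), "missing")
})

test_that("percent asymmetry counts pairs with NA-shrunken denominator", {
  ## q = (2,2,8) -> normalized (-3,-3,6): pair 1 symmetric, pair 2 asymmetric
  expect_equal(percentAsymmetric(normalizeCharges(c(2, 2, 8)), "nonspec"),
               50)
  ## q = (2,2,2,10) -> one asymmetric pair out of 3
  expect_equal(percentAsymmetric(normalizeCharges(c(2, 2, 2, 10)),
                                 "nonspec"), 100 / 3)
  ## all symmetric / all asymmetric extremes
  expect_equal(percentAsymmetric(c(0, 0, 0), "nonspec"), 0)
  expect_equal(percentAsymmetric(c(-4, 4, -4), "nonspec"), 100)
  ## NA member removes the pair from the denominator
  expect_equal(percentAsymmetric(c(-4, 4, NA), "nonspec"), 100)
  expect_true(is.na(percentAsymmetric(c(NA, 4, NA), "nonspec")))
  expect_equal(percentAsymmetric(c(0.9, 0.65, 0.64), "spec"), 50)
  expect_error(percentAsymmetric(1, "nonspec"), "at least 2")
})

test_that("cohort asymmetry annotation agrees with per-array computation", {
  set.seed(301)
  co <- annotatedCohort(nProteins = 25, seed = 7)
  p <- proteins(co)
  d <- domains(co)
  expect_true(all(p$pct_asym_nonspec >= 0 & p$pct_asym_nonspec <= 100))
  expect_true(all(p$pct_asym_spec >= 0 & p$pct_asym_spec <= 100))
  for (pid in p$protein_id[1:5]) {
    ii <- which(d$protein_id == pid)
    expect_equal(p$pct_asym_nonspec[p$protein_id == pid],
                 percentAsymmetric(as.numeric(d$normalized_charge[ii]),
                                   "nonspec"))
    expect_equal(p$pct_asym_spec[p$protein_id == pid],
                 percentAsymmetric(d$specificity_score[ii], "spec"))
  }
  ## config is echoed into metadata for provenance
  expect_equal(S4Vectors::metadata(co)$asymmetry_config$sigma_nonspec, 3)
  expect_error(annotateAsymmetry(mkChargeCohort(list(A = c(4, 4, 4)))),
               "not charge-annotated")
})

test_that("raw-charge configuration reproduces the N/(N-1) rescaling", {
  set.seed(302)
  ## with raw charges the same pairs differ by a factor (N-1)/N, so a
  ## borderline pair can flip: q = (2,2,7) has raw diff 5, normalized 7.5
  co <- annotateCharges(mkChargeCohort(list(A = c(2, 2, 7))))
  co1 <- annotateAsymmetry(co)
  expect_equal(proteins(co1)$pct_asym_nonspec, 50)
  co2 <- annotateAsymmetry(co, AsymmetryConfig(useNormalized = FALSE))
  ## raw charges never go below -2e here -> no pair fires under "and"
  expect_equal(proteins(co2)$pct_asym_nonspec, 0)
})

test_that("pair classification table covers every adjacent pair", {
  set.seed(303)
  co <- annotatedCohort(nProteins = 20, seed = 11)
  pc <- pairClassifications(co)
  p <- proteins(co)
  expect_equal(nrow(pc), sum(p$n_domains - 1L))
  ## per-protein aggregation of the table reproduces the annotation
  agg <- tapply(pc$asym_nonspec, pc$protein_id, function(x)
    100 * mean(x, na.rm = TRUE))
  expect_equal(as.numeric(agg[p$protein_id]), p$pct_asym_nonspec)
})

test_that("percent asymmetry is non-increasing along a sigma sweep", {
  set.seed(304)
  co <- annotatedCohort(nProteins = 30, seed = 13)
  sw <- sweepCutoffs(co, "nonspec", sigmas = c(2, 3, 4, 6, 8))
  expect_equal(dim(sw), c(nProteins(co), 5L))
  expect_equal(unname(sw[, "3"]), proteins(co)$pct_asym_nonspec)
  for (i in seq_len(nrow(sw)))
    expect_true(all(diff(sw[i, ]) <= 1e-9))
  swS <- sweepCutoffs(co, "spec", sigmas = c(0.1, 0.2, 0.4))
  expect_equal(unname(swS[, "0.2"]), proteins(co)$pct_asym_spec)
  expect_error(sweepCutoffs(co, "nonspec", sigmas = c(0, 3)), "> 0")
})

test_that("asymmetry table rounds to one decimal and writes per protein", {
  set.seed(305)
  co <- annotatedCohort(nProteins = 10, seed = 17)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  out <- writeAsymmetryTable(co, tsv)
  back <- read.delim(tsv)
  expect_equal(nrow(back), nProteins(co))
  expect_equal(back$pct_asym_nonspec,
               round(proteins(co)$pct_asym_nonspec, 1))
  expect_equal(out$pct_asym_spec, round(proteins(co)$pct_asym_spec, 1))
})
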