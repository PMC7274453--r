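## Fixture builders: small cohorts constructed in code.

NEUTRAL_REC <- c("S", "S", "N", "Q")   # uncharged recognition residues

## One domain sequence with a prescribed net charge under the default
## His-positive convention (the 2 scaffold His floor the positive count).
toyDomainSeq <- function(net) {
  if (net >= 2) generateDomainSequence(net, 0, recResidues = NEUTRAL_REC)
  else generateDomainSequence(2, 2 - net, recResidues = NEUTRAL_REC)
}

## Cohort of proteins with prescribed per-domain net charges.
## chargeList: named list of integer vectors, one per protein.
mkChargeCohort <- function(chargeList, abundance = NULL, linker = 5L) {
  stopifnot(!is.null(names(chargeList)))
  seqs <- character(0)
  doms <- list()
  for (pid in names(chargeList)) {
    q <- chargeList[[pid]]
    dseqs <- vapply(q, toyDomainSeq, character(1))
    L <- 25L
    lk <- strrep("G", linker)
    full <- paste0(lk, paste(dseqs, collapse = lk), lk)
    starts <- linker + (seq_along(q) - 1L) * (L + linker) + 1L
    seqs[pid] <- full
    doms[[pid]] <- data.frame(protein_id = pid, index = seq_along(q),
                              start = starts, end = starts + L - 1L)
  }
  assembleCohort(seqs, do.call(rbind, doms), abundance)
}

## Handcrafted propensity table with prescribed (P, Pmax) per helix column.
## Query residue "A" carries P; residue "R" carries Pmax (unless A itself is
## maximal); remaining mass sits on the gap category.
mkToyTable <- function(p, pmax) {
  anchor <- defaultTemplateAnchor()
  hc <- anchor@helixColumns
  L <- nchar(anchor@template)
  cats <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")
  prob <- matrix(0, nrow = 21, ncol = L, dimnames = list(cats, NULL))
  prob["-", ] <- 1
  for (k in seq_along(hc)) {
    j <- hc[k]
    prob[, j] <- 0
    prob["A", j] <- p[k]
    if (pmax[k] > p[k]) prob["R", j] <- pmax[k]
    prob["-", j] <- 1 - sum(prob[c("A", "R"), j])
  }
  new("PropensityTable", prob = prob, helixColumns = hc,
      pMax = stats::setNames(pmax, names(hc)),
      pMaxResidue = stats::setNames(rep("R", 4), names(hc)),
      nSequences = 10L, pseudocount = 0)
}

## Random amino-acid string over the 20 standard residues.
randomAA <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

## Cohort annotated end-to-end (charges + specificity + asymmetry) from the
## synthetic generator, curated with defaults.
annotatedCohort <- function(nProteins = 30, seed = 1, ...) {
  gen <- generateCohort(CohortParams(nProteins = nProteins, seed = seed,
                                     ...))
  co <- curateCohort(cohortFromGenerated(gen))$kept
  co <- annotateCharges(co)
  co <- annotateSpecificity(co)
  annotateAsymmetry(co)
}
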