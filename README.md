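# zfasym

Asymmetry of electrostatic charge and binding specificity in tandem C2H2
zinc-finger proteins, and its linkage to cellular abundance.

## Background

Tandem C2H2 zinc-finger proteins read DNA with a chain of ~25-residue
domains. Each finger contributes two separable affinities: a
**non-specific**, electrostatic pull on the DNA backbone (proxied by the
finger's net charge: `#[K,R,H] − #[D,E]`) and a **specific** preference for
particular bases set by the four recognition-helix residues at positions
−1, +2, +3 and +6. If these affinities are distributed *asymmetrically*
along the array — one finger clamping while its neighbour dangles — the
protein can move between DNA sites by intersegment transfer (the
"monkey-bar" mechanism) instead of staying uniformly glued, with
consequences for target search and, at cohort scale, for how abundant the
cell needs to keep each protein.

`zfasym` implements that analysis end to end:

* **I/O and curation** — read protein FASTA, domain coordinate tables and
  abundance tables; keep canonical tandem arrays (linkers ≤ 8 residues,
  3–15 domains), reporting every exclusion with its reason.
* **Electrostatics** — per-domain net charge under a switchable His
  convention, and within-protein normalized charges
  `q̄ᵢ = qᵢ − mean(q₋ᵢ)` (they sum to zero in every protein).
* **Specificity** — deterministic template-anchored alignment of fingers
  to a canonical C2H2 scaffold, per-column residue propensity tables, and
  a per-finger specificity score in (0, 1] that equals 1 exactly for the
  column-maximal finger.
* **Asymmetry** — classification of adjacent finger pairs in both modes
  (charge rule: neighbour below −2e *and* difference ≥ 3e on normalized
  charges; score rule: either score < 0.6 *or* difference ≥ 0.2), with
  the documented rule variants, and percent asymmetry per protein.
* **Linkage** — symmetric/asymmetric group comparison (t-test),
  correlation with abundance, 4×4 binned count/mean-abundance matrices,
  and length-stratified reports with underpowered-stratum suppression.
* **Synthetic cohorts** — a fully seeded generator emulating curated
  zinc-finger datasets, plus a parameter-recovery harness
  (`recoverCoupling()`) for the abundance–asymmetry coupling.
* **Pipeline** — `runPipeline()` executes every stage and writes all
  tables plus JSON summaries and re-runnable metadata; a thin CLI lives in
  `inst/scripts/zfasym.R`.

See the vignette (`vignettes/zinc-finger-asymmetry-methods.Rmd`) for the
full methods description and every default's rationale.

## Worked example

```r
library(zfasym)

netCharge("YACPVESCDRRFSRSDELTRHIRIH")
#> [1] 3
normalizeCharges(c(5, 2, 8))
#> [1]  0.0 -4.5  4.5

## a seeded synthetic cohort, written in the pipeline's input formats
dir <- tempfile()
simulateCohort(CohortParams(nProteins = 100, seed = 1), dir)

res <- runPipeline(list(input_fasta     = file.path(dir, "cohort.fasta"),
                        input_domains   = file.path(dir, "domains.tsv"),
                        input_abundance = file.path(dir, "abundance.tsv")),
                   outDir = file.path(dir, "out"))

res$cohort
#> ZFCohort with 100 proteins and 617 zinc-finger domains
#>   domains per protein: 3 - 15
#>   abundance set for 100 proteins
#>   annotations: charges, specificity, asymmetry

head(as.data.frame(proteins(res$cohort))[, c("protein_id", "n_domains",
     "abundance", "pct_asym_nonspec", "pct_asym_spec")], 5)
#>   protein_id n_domains abundance pct_asym_nonspec pct_asym_spec
#> 1    SZF0001         4 1.6256761                0      33.33333
#> 2    SZF0002         5 1.8439502              100     100.00000
#> 3    SZF0003         5 1.7761422                0      75.00000
#> 4    SZF0004         3 0.7027632              100     100.00000
#> 5    SZF0005        13 2.4704746               25      75.00000

full <- res$linkage[["3-15"]]$nonspec
cat(sprintf("r = %.3f (p = %.2g); mean abundance symmetric %.2f vs asymmetric %.2f (p = %.2g)\n",
    full$pearson_r, full$correlation_p,
    full$mean_symmetric, full$mean_asymmetric, full$p_value))
#> r = -0.593 (p = 7.7e-11); mean abundance symmetric 2.35 vs asymmetric 1.07 (p = 1.2e-08)

res$bins$counts
#>           spec
#> nonspec    [0,25) [25,50) [50,75) [75,100]
#>   [0,25)        0       1       7       23
#>   [25,50)       1       2       6       14
#>   [50,75)       0       1       4       10
#>   [75,100]      1       3       4       23
```

The generated cohort was built with a negative abundance–asymmetry
coupling (β = 1), and the pipeline recovers it: asymmetric proteins are
markedly less abundant. The output directory additionally contains
`curation.tsv`, `charges.tsv`, `propensities.tsv`, `specificity.tsv`,
`asymmetry.tsv`, `pairs.tsv`, the bin matrices, `linkage-summary.json` and
`run-metadata.json` (every cutoff echoed, so a run is re-executable from
its metadata alone).

Command-line equivalent:

```sh
Rscript inst/scripts/zfasym.R simulate --out /tmp/sim --n 100 --seed 1
Rscript inst/scripts/zfasym.R run --fasta /tmp/sim/cohort.fasta \
    --domains /tmp/sim/domains.tsv --abundance /tmp/sim/abundance.tsv \
    --out /tmp/sim/out
```

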