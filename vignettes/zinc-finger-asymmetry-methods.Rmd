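---
title: "Methods: charge and specificity asymmetry in tandem zinc-finger arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: charge and specificity asymmetry in tandem zinc-finger arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfasym)
```

# Scope

Tandem C2H2 zinc-finger proteins bind DNA through a chain of ~25-residue
domains. Two per-domain properties shape how such an array engages DNA:

* **non-specific affinity**, dominated by electrostatics and proxied here by
  the domain's net charge, and
* **specific affinity**, determined by the four recognition-helix residues
  (positions −1, +2, +3, +6) that contact DNA bases.

`zfasym` measures how unevenly these two properties are distributed along
each array ("asymmetry"), and relates per-protein percent asymmetry to
cellular abundance. This vignette documents every modelling and numerical
choice so a run can be interpreted, and reproduced, from its outputs alone.

# Electrostatics

Net charge is counted from sequence: `+1` for Lys, Arg and His, `-1` for
Asp and Glu, `0` otherwise. Histidine's protonation state near DNA is
ambiguous at physiological pH, so the convention is explicit and switchable
(`ChargeConvention(hisPositive = FALSE)` treats His as neutral); both
conventions are carried through the whole pipeline.

Within a protein of $N$ domains the *normalized* charge of domain $i$ is

$$\bar q_i = q_i - \frac{1}{N-1}\sum_{j \ne i} q_j ,$$

i.e. each domain is measured against the mean of its *other* array members.
Two identities follow and are property-tested: $\sum_i \bar q_i = 0$, and
any pairwise difference is the raw difference rescaled by $N/(N-1)$:

```{r}
normalizeCharges(c(5, 2, 8))
```

Normalization removes protein-level charge offsets so that arrays are
compared by internal contrast, not overall charge. The asymmetry rules
below default to normalized charges (`useNormalized = TRUE`); raw charges
remain available for sensitivity analysis.

# Template-anchored alignment and specificity scores

Recognition residues can only be read off once all fingers are placed on a
common coordinate system. The anchor is a canonical 25-column C2H2 template
(an Egr-1-style finger) with fixed scaffold columns for the two Cys and two
His zinc ligands and helix columns 14, 16, 17, 20 for positions −1, +2,
+3, +6. Alignment is deterministic and combinatorial rather than
score-based: all candidate Cys/Cys/His/His ligand quadruples in a finger
are enumerated (spacers capped at 4, 12 and 3 residues beyond the
template's), and the quadruple whose spacer lengths deviate least from the
template (ties broken lexicographically) anchors the finger. Segments
between anchors are right-justified, terminal overhangs truncated, and
fingers with no feasible quadruple are flagged unalignable (all-gap row)
rather than force-fitted. Determinism here is a design requirement: the
alignment feeds a frozen-oracle test suite, and heuristic aligners with
tie-dependent output would make the propensity table irreproducible.

Per-column residue propensities are estimated over a 21-category alphabet
(20 residues + gap) with a pseudocount (default 0.5):

$$P(a, j) = \frac{n_{a,j} + c}{n + 21c} .$$

The column maximum $P^{max}_j$ is taken over the 20 residues only, so gaps
can never be "the preferred residue".

A finger with recognition residues $r_{-1}, r_{+2}, r_{+3}, r_{+6}$ is
scored against the table by comparing its propensity product to the
column-maximal product. Two orientations are provided:

* `"consistent"` (default): $S = \ln\prod_j P^{max}_j \,/\, \ln\prod_j
  P(r_j, j)$, which lies in $(0, 1]$ and equals 1 exactly for the
  column-maximal finger — a bounded, monotone score.
* `"as_printed"`: the reciprocal ratio $\ln\prod_j P(r_j,j) \,/\,
  \ln\prod_j P^{max}_j$, which is provably $\ge 1$ (both logs are negative
  and the numerator is more negative). It is retained verbatim because the
  downstream thresholds (low-specificity cutoff 0.6, difference cutoff
  0.2) are only coherent for a score in $(0,1]$; the package defaults to
  the consistent orientation and records the choice in the run metadata.

# Asymmetry classification

Adjacent finger pairs are classified per mode; a protein's percent
asymmetry is $100 \times$ (asymmetric pairs)/(countable pairs). Pairs with
a missing value shrink the denominator instead of counting as symmetric,
and a protein with no countable pair gets `NA`.

**Non-specific (charge) rule**, default `"and"`: a pair is asymmetric iff
$\min(\bar q_i, \bar q_j) < -2e$ **and** $|\bar q_i - \bar q_j| \ge
\sigma^{nonspec} = 3e$. The conjunction targets arrays in which one finger
is actively repelled by DNA while its neighbour is not; `"or"` and
`"diff_only"` variants are provided because descriptions of such rules in
the literature differ in exactly this connective, and the sensitivity of
cohort-level results to the connective is itself of interest
(`pairClassifications()` exposes the fired sub-conditions per pair).

**Specific (score) rule**, default `"either_or_both"`: asymmetric iff
either score is below 0.6 **or** the scores differ by at least 0.2;
`"contrast_only"` (exactly one member low) and `"diff_only"` are the
alternatives. Thresholds are calibrated for the consistent orientation.

Cutoff sensitivity is audited with `sweepCutoffs()`, which recomputes
percent asymmetry along a $\sigma$ grid and verifies the built-in
monotonicity invariant (raising a difference cutoff can only demote pairs).

# Linkage to abundance

Per-protein percent asymmetry is related to abundance three ways, all on
the same usable subset (proteins with both quantities):

1. **Group comparison**: proteins split at 50% (the boundary is
   asymmetric); two-sided unpaired t-test, equal-variance by default with
   Welch optional. Degenerate zero-variance groups yield the analytic
   limits ($t = 0, p = 1$ for equal means) instead of an error.
2. **Correlation**: Pearson by default, Spearman optional; degenerate
   inputs are flagged rather than failing.
3. **Binned view**: a 4×4 grid over (non-specific %, specific %) with bins
   `[0,25)`, `[25,50)`, `[50,75)`, `[75,100]`, tabulating counts and mean
   abundance per cell (`binMatrix()`, `plotBinMatrix()`).

Because short arrays quantize percent asymmetry coarsely (a 3-finger
protein can only score 0, 50 or 100%), `lengthStratifiedReport()` repeats
the analysis within domain-count strata ({3}, {4}, {3–6}, {3–15}); strata
with fewer than 4 usable proteins are flagged underpowered and their
statistics suppressed rather than reported.

# Curation

Input arrays are filtered to canonical tandem arrays before analysis:
linkers (gap between consecutive annotated domains) at most 8 residues and
3–15 domains per protein. The default drops violating proteins whole;
`clusterMode = "largest_cluster"` instead retains the longest run of
domains connected by short linkers, then re-applies the domain-count rule.
Every exclusion is written to `curation.tsv` with its reason.

# Synthetic cohort generator

Real cohorts derive from annotation and abundance databases that cannot be
bundled, so the generator emulates their statistical structure. All
parameters live in `CohortParams()` and are echoed into
`cohort-metadata.json`:

* domain counts 3–15 with probabilities skewed toward short arrays
  (mode at 3–4 domains);
* per-domain positive-residue counts from round(N(6.5, 1.4)) and negative
  from round(N(1.6, 1.0)), clipped to each domain's feasible range. Under
  the His-positive convention these targets give a mean net charge near
  4.9; with `hisFraction = 0.2` of extra positives drawn as His, the
  His-neutral convention yields a mean near 2.3;
* a fraction `pAsymProtein = 0.4` of proteins carries injected
  high/low net-charge alternation (targets 7 and 1) along the array;
* recognition residues from a generation propensity model
  (column-maximal residue with probability `specMaxFraction = 0.8`,
  otherwise a neutral polar alternative);
* abundance from $\exp(\ln 2 - \beta \cdot \mathrm{pct}/100 +
  \mathcal N(0, 0.5))$ where pct is the protein's true injected asymmetry
  (100 or 0) and $\beta$ (default 1) is the coupling to recover. The noise
  standard deviation is a free parameter of the generator, not an
  empirical estimate.

Each protein draws from a substream seeded deterministically from the
cohort seed, so cohorts are bit-identical across runs and platforms for
identical parameters.

**Scope and caveats.** The generator is a *qualitative* emulator: it
reproduces the targeted charge means, the short-array length skew and a
recoverable negative abundance–asymmetry coupling, and that is all it is
used for. Known departures from real cohorts: (i) the injected alternation
makes the within-array charge contrast cleaner than observed arrays, and
clipping by scaffold His and recognition Arg floors the low-charge target
near 2 rather than 1, so injected proteins average slightly below 100%
measured asymmetry; (ii) the two-component recognition model (maximal
residue vs. neutral alternative) yields a more bimodal specificity-score
distribution, and therefore higher specific-asymmetry percentages, than
natural finger repertoires; (iii) abundance dispersion is assumed
log-normal with an arbitrary sd. Conclusions about real data should come
from real inputs via `runPipeline()`; the generator's role is pipeline
verification and power/type-I analysis (`recoverCoupling()`).

# Numerical choices

* Scores are compared in log space; the score is snapped to exactly 1 when
  $|\ln\prod P - \ln\prod P^{max}| < 10^{-12}$ to avoid
  floating-point-only deviations from the analytic value.
* Monotonicity of the cutoff sweep is asserted at $10^{-9}$ slack.
* Seeds are kept below $2^{31}$; per-protein substreams use a fixed
  integer hash of (cohort seed, protein index).
* Written tables round for readability (charges 2 decimals, percentages
  1 decimal); all statistics are computed on unrounded values.

# Problem sizes

Verification uses cohorts of 10–150 proteins for unit and property tests,
900 proteins (≈5,600 domains) for the charge-accounting check, 50 seeded
cohorts of 100 proteins for coupling recovery, and 1,000 replicates of 100
proteins for the type-I-error check of the group t-test at $\beta = 0$.

# End-to-end example

```{r, eval = FALSE}
dir <- tempfile()
simulateCohort(CohortParams(nProteins = 100, seed = 1), dir)
res <- runPipeline(list(input_fasta = file.path(dir, "cohort.fasta"),
                        input_domains = file.path(dir, "domains.tsv"),
                        input_abundance = file.path(dir, "abundance.tsv")),
                   outDir = file.path(dir, "out"))
res$linkage[["3-15"]]$nonspec$pearson_r
```
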