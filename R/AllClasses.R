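#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

## 20 standard one-letter amino-acid codes; "-" is the gap category used in
## alignment columns and propensity tables.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
GAP_CHAR <- "-"

#' Charge-counting convention for zinc-finger domains
#'
#' Net charge of a finger is counted from sequence as (number of positively
#' charged residues) minus (number of negatively charged residues). The
#' default convention counts Lys, Arg and His as positive and Asp, Glu as
#' negative; His can be treated as neutral to obtain the His-neutral variant
#' of all charge statistics.
#'
#' @slot positive character vector of positively charged one-letter codes.
#' @slot negative character vector of negatively charged one-letter codes.
#' @export
setClass("ChargeConvention",
         representation(positive = "character", negative = "character"),
         prototype(positive = c("K", "R", "H"), negative = c("D", "E")))

setValidity("ChargeConvention", function(object) {
  msg <- NULL
  if (length(intersect(object@positive, object@negative)) > 0L)
    msg <- c(msg, "positive and negative residue sets must be disjoint")
  bad <- setdiff(c(object@positive, object@negative), AA20)
  if (length(bad) > 0L)
    msg <- c(msg, paste0("non-standard residues in charge sets: ",
                         paste(bad, collapse = ", ")))
  if (is.null(msg)) TRUE else msg
})

#' @param hisPositive logical; count His as +1 (default) or as neutral.
#' @param positive,negative residue sets; defaults are Lys/Arg/His and
#'   Asp/Glu, with His removed from the positive set when
#'   \code{hisPositive = FALSE}.
#' @return A \code{ChargeConvention} object.
#' @examples
#' ChargeConvention()
#' ChargeConvention(hisPositive = FALSE)
#' @rdname ChargeConvention-class
#' @export
ChargeConvention <- function(hisPositive = TRUE,
                             positive = c("K", "R", "H"),
                             negative = c("D", "E")) {
  if (!hisPositive)
    positive <- setdiff(positive, "H")
  new("ChargeConvention", positive = positive, negative = negative)
}

#' Template anchor for recognition-helix alignment
#'
#' Holds the 25-residue C2H2 template finger used to anchor all domain
#' alignments, the template columns of the four specificity-determining
#' recognition-helix positions (-1, +2, +3, +6) and the columns of the four
#' zinc-coordinating scaffold ligands (Cys, Cys, His, His).
#'
#' @slot template single amino-acid string.
#' @slot helixColumns named integer vector, names "-1", "+2", "+3", "+6".
#' @slot scaffoldColumns integer vector of 4 columns: Cys1, Cys2, His1, His2.
#' @export
setClass("TemplateAnchor",
         representation(template = "character",
                        helixColumns = "integer",
                        scaffoldColumns = "integer"))

setValidity("TemplateAnchor", function(object) {
  msg <- NULL
  if (length(object@template) != 1L || nchar(object@template) < 12L)
    msg <- c(msg, "template must be a single sequence of reasonable length")
  tpl <- strsplit(object@template, "")[[1]]
  sc <- object@scaffoldColumns
  if (length(sc) != 4L || any(sc < 1L) || any(sc > length(tpl)) ||
      is.unsorted(sc, strictly = TRUE)) {
    msg <- c(msg, "scaffoldColumns must be 4 increasing in-range columns")
  } else {
    if (!all(tpl[sc[1:2]] == "C"))
      msg <- c(msg, "first two scaffold columns must hold Cys")
    if (!all(tpl[sc[3:4]] == "H"))
      msg <- c(msg, "last two scaffold columns must hold His")
  }
  hc <- object@helixColumns
  if (length(hc) != 4L || !identical(names(hc), c("-1", "+2", "+3", "+6")))
    msg <- c(msg, 'helixColumns must be named "-1", "+2", "+3", "+6"')
  else if (anyDuplicated(hc) > 0L)
    msg <- c(msg, "helix columns must be distinct")
  else if (length(sc) == 4L && (any(hc <= sc[2]) || any(hc >= sc[4])))
    msg <- c(msg, "helix columns must lie between the second Cys and last His")
  if (is.null(msg)) TRUE else msg
})

#' Per-column residue propensity table
#'
#' Probabilities of each of the 20 residues plus the gap category at each
#' aligned template column, estimated from an alignment of zinc-finger
#' domains with an additive pseudocount. For the four recognition-helix
#' columns the maximal residue propensity (over the 20 residues, gap
#' excluded) is recorded; these maxima normalize the specificity score.
#'
#' @slot prob 21 x L matrix (rows: 20 residues + gap), columns sum to 1.
#' @slot helixColumns named integer vector (labels "-1","+2","+3","+6").
#' @slot pMax named numeric, maximal residue propensity per helix column.
#' @slot pMaxResidue named character, the residue attaining each maximum.
#' @slot nSequences number of aligned rows used.
#' @slot pseudocount additive pseudocount per category.
#' @export
setClass("PropensityTable",
         representation(prob = "matrix",
                        helixColumns = "integer",
                        pMax = "numeric",
                        pMaxResidue = "character",
                        nSequences = "integer",
                        pseudocount = "numeric"))

setValidity("PropensityTable", function(object) {
  msg <- NULL
  if (!identical(rownames(object@prob), c(AA20, GAP_CHAR)))
    msg <- c(msg, "prob rows must be the 20 residues plus the gap category")
  cs <- colSums(object@prob)
  if (any(abs(cs - 1) > 1e-9))
    msg <- c(msg, "propensity columns must each sum to 1")
  if (any(object@pMax <= 0) || any(object@pMax > 1))
    msg <- c(msg, "helix-column maxima must lie in (0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' Cutoffs and pair rules for asymmetry classification
#'
#' All cutoffs used to classify adjacent zinc-finger pairs as asymmetric.
#' Non-specific (electrostatic) asymmetry is evaluated on normalized net
#' charges by default: under the default \code{"and"} rule a pair is
#' asymmetric when one member's normalized charge falls below
#' \code{negChargeThreshold} (default -2e) and the pair's charge difference
#' is at least \code{sigmaNonspec} (default 3e). Alternative published
#' wordings of the rule are selectable (\code{"or"}, \code{"diff_only"}).
#' Specific-binding asymmetry uses the specificity score: under the default
#' \code{"either_or_both"} rule a pair is asymmetric when either score is
#' low (< \code{lowSpecThreshold}, default 0.6) or the score difference is
#' at least \code{sigmaSpec} (default 0.2).
#'
#' @slot sigmaNonspec charge-difference cutoff, units e; > 0.
#' @slot negChargeThreshold negative-charge condition threshold (e).
#' @slot pairRuleNonspec one of "and", "or", "diff_only".
#' @slot sigmaSpec specificity-difference cutoff; > 0.
#' @slot lowSpecThreshold low-specificity condition threshold, in (0, 1).
#' @slot pairRuleSpec one of "either_or_both", "contrast_only", "diff_only".
#' @slot useNormalized evaluate charge conditions on normalized charges.
#' @export
setClass("AsymmetryConfig",
         representation(sigmaNonspec = "numeric",
                        negChargeThreshold = "numeric",
                        pairRuleNonspec = "character",
                        sigmaSpec = "numeric",
                        lowSpecThreshold = "numeric",
                        pairRuleSpec = "character",
                        useNormalized = "logical"),
         prototype(sigmaNonspec = 3, negChargeThreshold = -2,
                   pairRuleNonspec = "and", sigmaSpec = 0.2,
                   lowSpecThreshold = 0.6, pairRuleSpec = "either_or_both",
                   useNormalized = TRUE))

setValidity("AsymmetryConfig", function(object) {
  msg <- NULL
  if (object@sigmaNonspec <= 0) msg <- c(msg, "sigmaNonspec must be > 0")
  if (object@sigmaSpec <= 0) msg <- c(msg, "sigmaSpec must be > 0")
  if (object@lowSpecThreshold <= 0 || object@lowSpecThreshold >= 1)
    msg <- c(msg, "lowSpecThreshold must lie in (0, 1)")
  if (!object@pairRuleNonspec %in% c("and", "or", "diff_only"))
    msg <- c(msg, 'pairRuleNonspec must be "and", "or" or "diff_only"')
  if (!object@pairRuleSpec %in% c("either_or_both", "contrast_only",
                                  "diff_only"))
    msg <- c(msg, paste0('pairRuleSpec must be "either_or_both", ',
                         '"contrast_only" or "diff_only"'))
  if (is.null(msg)) TRUE else msg
})

#' @param sigmaNonspec,negChargeThreshold,pairRuleNonspec,sigmaSpec
#'   non-specific rule parameters; see slot documentation.
#' @param lowSpecThreshold,pairRuleSpec,useNormalized specific rule
#'   parameters; see slot documentation.
#' @return An \code{AsymmetryConfig} object.
#' @examples
#' AsymmetryConfig()
#' AsymmetryConfig(sigmaNonspec = 4, pairRuleNonspec = "diff_only")
#' @rdname AsymmetryConfig-class
#' @export
AsymmetryConfig <- function(sigmaNonspec = 3, negChargeThreshold = -2,
                            pairRuleNonspec = c("and", "or", "diff_only"),
                            sigmaSpec = 0.2, lowSpecThreshold = 0.6,
                            pairRuleSpec = c("either_or_both",
                                             "contrast_only", "diff_only"),
                            useNormalized = TRUE) {
  new("AsymmetryConfig",
      sigmaNonspec = sigmaNonspec,
      negChargeThreshold = negChargeThreshold,
      pairRuleNonspec = match.arg(pairRuleNonspec),
      sigmaSpec = sigmaSpec,
      lowSpecThreshold = lowSpecThreshold,
      pairRuleSpec = match.arg(pairRuleSpec),
      useNormalized = useNormalized)
}

#' Cohort of tandem zinc-finger proteins
#'
#' Central container for a cohort: one protein-level table (id, name, domain
#' count, abundance, per-protein percent asymmetry) and one domain-level
#' table (id, index along the array, coordinates, sequence, charge and
#' specificity annotations). Slots are filled progressively by the pipeline
#' stages; unset annotation columns hold \code{NA}.
#'
#' @slot proteins \code{DataFrame} with columns \code{protein_id},
#'   \code{name}, \code{n_domains}, \code{abundance},
#'   \code{pct_asym_nonspec}, \code{pct_asym_spec}.
#' @slot domains \code{DataFrame} with columns \code{protein_id},
#'   \code{index}, \code{start}, \code{end}, \code{sequence} and, once
#'   annotated, \code{n_pos}, \code{n_neg}, \code{net_charge},
#'   \code{normalized_charge}, \code{res_m1}, \code{res_p2}, \code{res_p3},
#'   \code{res_p6}, \code{specificity_score}.
#' @export
setClass("ZFCohort",
         contains = "Annotated",
         representation(proteins = "DataFrame", domains = "DataFrame"))

setValidity("ZFCohort", function(object) {
  p <- object@proteins
  d <- object@domains
  msg <- NULL
  need_p <- c("protein_id", "name", "n_domains", "abundance",
              "pct_asym_nonspec", "pct_asym_spec")
  need_d <- c("protein_id", "index", "start", "end", "sequence")
  if (!all(need_p %in% colnames(p)))
    return(paste0("proteins table lacks columns: ",
                  paste(setdiff(need_p, colnames(p)), collapse = ", ")))
  if (!all(need_d %in% colnames(d)))
    return(paste0("domains table lacks columns: ",
                  paste(setdiff(need_d, colnames(d)), collapse = ", ")))
  if (anyDuplicated(p$protein_id) > 0L)
    msg <- c(msg, "duplicated protein_id in proteins table")
  if (nrow(d) > 0L) {
    if (!all(d$protein_id %in% p$protein_id))
      msg <- c(msg, "domains reference unknown protein ids")
    if (any(d$start < 1L) || any(d$end < d$start))
      msg <- c(msg, "domain coordinates must satisfy 1 <= start <= end")
    if (any(nchar(d$sequence) != d$end - d$start + 1L))
      msg <- c(msg, "sequence length must equal end - start + 1")
    f <- match(d$protein_id, p$protein_id)
    ord <- order(f, d$start)
    if (!identical(ord, seq_len(nrow(d))))
      msg <- c(msg, "domains must be grouped by protein and sorted by start")
    cnt <- tabulate(f, nbins = nrow(p))
    if (!identical(as.integer(d$index), sequence(cnt[cnt > 0L])))
      msg <- c(msg, "domain index must equal 1-based position in the array")
    if (nrow(d) > 1L) {
      same <- f[-1] == f[-nrow(d)]
      if (any(same & d$start[-1] <= d$end[-nrow(d)]))
        msg <- c(msg, "domains of one protein must not overlap")
    }
    if (!all(cnt == p$n_domains))
      msg <- c(msg, "n_domains must match the number of domain rows")
  } else if (nrow(p) > 0L && any(p$n_domains != 0L)) {
    msg <- c(msg, "n_domains must match the number of domain rows")
  }
  if (is.null(msg)) TRUE else msg[1]
})

#' Parameters of the synthetic zinc-finger cohort generator
#'
#' Defines the statistical structure of a generated cohort: the distribution
#' of domain counts per protein (3-15, skewed toward short arrays), the
#' per-domain counts of positively and negatively charged residues (normal
#' draws, rounded and clipped to feasible ranges; defaults 6.5 +/- 1.4 and
#' 1.6 +/- 1.0), the fraction of proteins carrying an injected high/low
#' charge alternation, the propensity model for recognition-helix residues,
#' and a log-linear abundance model
#' \code{abundance = exp(alpha - beta * pctAsym/100 + noise)} coupling
#' abundance negatively to true percent asymmetry when \code{beta > 0}.
#'
#' @slot nProteins number of proteins to generate.
#' @slot domainCountProbs named probability vector over domain counts 3..15.
#' @slot posCountMean,posCountSd per-domain positive residue count model.
#' @slot negCountMean,negCountSd per-domain negative residue count model.
#' @slot pAsymProtein probability a protein carries charge alternation.
#' @slot highChargeMean,lowChargeMean alternating net-charge targets (e).
#' @slot specMaxFraction probability a recognition residue is drawn as the
#'   column-maximal residue of the generation propensity model.
#' @slot hisFraction probability an extra positive residue is His (vs Lys/Arg).
#' @slot abundanceAlpha,abundanceBeta,abundanceNoiseSd log-abundance model.
#' @slot linkerLength residues between consecutive domains.
#' @slot seed integer seed of the cohort's random stream.
#' @export
setClass("CohortParams",
         representation(nProteins = "integer",
                        domainCountProbs = "numeric",
                        posCountMean = "numeric", posCountSd = "numeric",
                        negCountMean = "numeric", negCountSd = "numeric",
                        pAsymProtein = "numeric",
                        highChargeMean = "numeric",
                        lowChargeMean = "numeric",
                        specMaxFraction = "numeric",
                        hisFraction = "numeric",
                        abundanceAlpha = "numeric",
                        abundanceBeta = "numeric",
                        abundanceNoiseSd = "numeric",
                        linkerLength = "integer",
                        seed = "integer"))

setValidity("CohortParams", function(object) {
  msg <- NULL
  p <- object@domainCountProbs
  if (!identical(names(p), as.character(3:15)))
    msg <- c(msg, "domainCountProbs must be named over 3..15")
  else if (abs(sum(p) - 1) > 1e-9 || any(p < 0))
    msg <- c(msg, "domainCountProbs must be a probability vector summing to 1")
  if (object@nProteins < 0L) msg <- c(msg, "nProteins must be >= 0")
  if (any(c(object@posCountSd, object@negCountSd,
            object@abundanceNoiseSd) < 0))
    msg <- c(msg, "standard deviations must be >= 0")
  probs <- c(object@pAsymProtein, object@specMaxFraction, object@hisFraction)
  if (any(probs < 0) || any(probs > 1))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (object@linkerLength < 0L) msg <- c(msg, "linkerLength must be >= 0")
  if (is.null(msg)) TRUE else msg
})
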