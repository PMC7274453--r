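## Vectorized pair rules. vi, vj are the two members' values (normalized
## charges for the non-specific rule, specificity scores for the specific
## rule); NA in either member yields NA (pair excluded from denominators).

.nonspecPair <- function(vi, vj, cfg) {
  cond_neg <- pmin(vi, vj) < cfg@negChargeThreshold
  cond_diff <- abs(vi - vj) >= cfg@sigmaNonspec
  asym <- switch(cfg@pairRuleNonspec,
                 and = cond_neg & cond_diff,
                 or = cond_neg | cond_diff,
                 diff_only = cond_diff)
  list(asymmetric = asym, cond_neg = cond_neg, cond_diff = cond_diff)
}

.specPair <- function(vi, vj, cfg) {
  cond_low <- pmin(vi, vj) < cfg@lowSpecThreshold
  cond_contrast <- (vi < cfg@lowSpecThreshold) != (vj < cfg@lowSpecThreshold)
  cond_diff <- abs(vi - vj) >= cfg@sigmaSpec
  asym <- switch(cfg@pairRuleSpec,
                 either_or_both = cond_low | cond_diff,
                 contrast_only = cond_contrast,
                 diff_only = cond_diff)
  list(asymmetric = asym, cond_low = cond_low,
       cond_contrast = cond_contrast, cond_diff = cond_diff)
}

#' Classify one adjacent pair for non-specific (electrostatic) asymmetry
#'
#' Applies the configured electrostatic pair rule to the charges of two
#' neighbouring fingers. Under the default \code{"and"} rule the pair is
#' asymmetric iff one member's (normalized) charge is below the
#' negative-charge threshold (default -2e) and the charge difference is at
#' least \code{sigmaNonspec} (default 3e). \code{"or"} requires either
#' condition, \code{"diff_only"} the difference condition alone.
#'
#' @param qi,qj charges of the two adjacent fingers (normalized charges
#'   under the default configuration).
#' @param cfg an \code{\link{AsymmetryConfig}}.
#' @return A list: \code{asymmetric} (logical), \code{cond_neg},
#'   \code{cond_diff}.
#' @examples
#' classifyPairNonspec(-4.5, 4.5)   # asymmetric: both conditions hold
#' classifyPairNonspec(-1, 4)       # symmetric under the default "and" rule
#' @export
classifyPairNonspec <- function(qi, qj, cfg = AsymmetryConfig()) {
  if (anyNA(c(qi, qj)))
    stop("both charges must be set; pairs with missing values are excluded")
  .nonspecPair(qi, qj, cfg)
}

#' Classify one adjacent pair for specific-binding asymmetry
#'
#' Applies the configured specificity pair rule to the scores of two
#' neighbouring fingers. Under the default \code{"either_or_both"} rule the
#' pair is asymmetric iff either score is low (below
#' \code{lowSpecThreshold}, default 0.6) or the score difference is at least
#' \code{sigmaSpec} (default 0.2). \code{"contrast_only"} requires exactly
#' one member below the threshold; \code{"diff_only"} the difference alone.
#'
#' @param si,sj specificity scores of the two adjacent fingers.
#' @param cfg an \code{\link{AsymmetryConfig}}.
#' @return A list: \code{asymmetric}, \code{cond_low}, \code{cond_contrast},
#'   \code{cond_diff}.
#' @examples
#' classifyPairSpec(0.9, 0.65)  # asymmetric: difference 0.25 >= 0.2
#' classifyPairSpec(0.9, 0.9)   # symmetric
#' @export
classifyPairSpec <- function(si, sj, cfg = AsymmetryConfig()) {
  if (anyNA(c(si, sj)))
    stop("both scores must be set; pairs with missing values are excluded")
  .specPair(si, sj, cfg)
}

#' Percent of asymmetric adjacent pairs in one array
#'
#' For an N-finger array the N - 1 adjacent pairs are classified and the
#' percentage of asymmetric pairs is returned. Pairs in which either value
#' is missing are excluded from the denominator (rather than counted as
#' symmetric); if no pair is countable the result is \code{NA}.
#'
#' @param values per-domain values in array order: normalized charges
#'   (\code{mode = "nonspec"}) or specificity scores (\code{mode = "spec"}).
#' @param mode "nonspec" or "spec".
#' @param cfg an \code{\link{AsymmetryConfig}}.
#' @return Percentage in [0, 100], or \code{NA} if no countable pair.
#' @examples
#' ## 3-domain protein with exactly one asymmetric pair -> 50
#' percentAsymmetric(normalizeCharges(c(2, 2, 8)), "nonspec")
#' @export
percentAsymmetric <- function(values, mode = c("nonspec", "spec"),
                              cfg = AsymmetryConfig()) {
  mode <- match.arg(mode)
  n <- length(values)
  if (n < 2L)
    stop("an array of at least 2 domains is required")
  vi <- values[-n]
  vj <- values[-1]
  asym <- if (mode == "nonspec") .nonspecPair(vi, vj, cfg)$asymmetric
          else .specPair(vi, vj, cfg)$asymmetric
  countable <- sum(!is.na(asym))
  if (countable == 0L) return(NA_real_)
  100 * sum(asym, na.rm = TRUE) / countable
}

#' Annotate per-protein percent asymmetry
#'
#' Computes, for every protein, the percentage of asymmetric adjacent pairs
#' in the non-specific (charge) and, where specificity scores are available,
#' the specific mode, and stores them in the protein table.
#'
#' @param cohort a charge-annotated (and optionally specificity-annotated)
#'   \code{ZFCohort}.
#' @param cfg an \code{\link{AsymmetryConfig}}.
#' @return The annotated \code{ZFCohort}.
#' @export
annotateAsymmetry <- function(cohort, cfg = AsymmetryConfig()) {
  d <- domains(cohort)
  p <- proteins(cohort)
  if (nrow(d) == 0L) return(cohort)
  qcol <- if (cfg@useNormalized) d$normalized_charge else d$net_charge
  if (all(is.na(qcol)))
    stop("cohort is not charge-annotated; run annotateCharges() first")
  f <- factor(d$protein_id, levels = p$protein_id)
  p$pct_asym_nonspec <- unname(vapply(split(as.numeric(qcol), f),
                                      percentAsymmetric, numeric(1),
                                      mode = "nonspec", cfg = cfg))
  if (any(!is.na(d$specificity_score))) {
    p$pct_asym_spec <- unname(vapply(split(d$specificity_score, f),
                                     percentAsymmetric, numeric(1),
                                     mode = "spec", cfg = cfg))
  }
  proteins(cohort) <- p
  metadata(cohort)$asymmetry_config <- list(
    sigma_nonspec = cfg@sigmaNonspec,
    neg_charge_threshold = cfg@negChargeThreshold,
    pair_rule_nonspec = cfg@pairRuleNonspec,
    sigma_spec = cfg@sigmaSpec,
    low_spec_threshold = cfg@lowSpecThreshold,
    pair_rule_spec = cfg@pairRuleSpec,
    use_normalized = cfg@useNormalized)
  cohort
}

#' Per-pair classification table
#'
#' One row per adjacent domain pair with the fired sub-conditions in both
#' modes, for audit output.
#'
#' @param cohort an annotated \code{ZFCohort}.
#' @param cfg an \code{\link{AsymmetryConfig}}.
#' @return A data.frame with one row per adjacent pair.
#' @export
pairClassifications <- function(cohort, cfg = AsymmetryConfig()) {
  d <- as.data.frame(domains(cohort))
  out <- do.call(rbind, lapply(split(d, factor(d$protein_id,
                                               levels = unique(d$protein_id))),
                               function(dd) {
    n <- nrow(dd)
    if (n < 2L) return(NULL)
    q <- if (cfg@useNormalized) dd$normalized_charge else dd$net_charge
    ns <- .nonspecPair(q[-n], q[-1], cfg)
    sp <- .specPair(dd$specificity_score[-n], dd$specificity_score[-1], cfg)
    data.frame(protein_id = dd$protein_id[1], pair = seq_len(n - 1L),
               asym_nonspec = ns$asymmetric,
               nonspec_cond_neg = ns$cond_neg,
               nonspec_cond_diff = ns$cond_diff,
               asym_spec = sp$asymmetric,
               spec_cond_low = sp$cond_low,
               spec_cond_diff = sp$cond_diff)
  }))
  rownames(out) <- NULL
  out
}

#' Sweep the asymmetry difference cutoff
#'
#' Recomputes per-protein percent asymmetry over a grid of difference
#' cutoffs (sigma). Raising sigma can only demote pairs from asymmetric to
#' symmetric, so each protein's percentage is non-increasing along the grid;
#' this is verified before returning.
#'
#' @param cohort an annotated \code{ZFCohort}.
#' @param mode "nonspec" or "spec".
#' @param sigmas numeric grid of cutoffs (all > 0).
#' @param cfg base \code{\link{AsymmetryConfig}}; its sigma is replaced.
#' @return A matrix (proteins x sigmas) of percentages.
#' @export
sweepCutoffs <- function(cohort, mode = c("nonspec", "spec"),
                         sigmas = c(3, 4, 5, 6), cfg = AsymmetryConfig()) {
  mode <- match.arg(mode)
  if (any(sigmas <= 0)) stop("sigma values must be > 0")
  d <- domains(cohort)
  p <- proteins(cohort)
  vals <- if (mode == "nonspec") {
    if (cfg@useNormalized) as.numeric(d$normalized_charge)
    else as.numeric(d$net_charge)
  } else d$specificity_score
  f <- factor(d$protein_id, levels = p$protein_id)
  out <- vapply(sigmas, function(s) {
    cfg2 <- cfg
    if (mode == "nonspec") cfg2@sigmaNonspec <- s else cfg2@sigmaSpec <- s
    vapply(split(vals, f), percentAsymmetric, numeric(1),
           mode = mode, cfg = cfg2)
  }, numeric(nrow(p)))
  out <- matrix(out, nrow = nrow(p),
                dimnames = list(p$protein_id, as.character(sigmas)))
  mono <- apply(out, 1L, function(r) {
    r <- r[!is.na(r)]
    length(r) < 2L || all(diff(r) <= 1e-9)
  })
  if (!all(mono))
    stop("internal error: percent asymmetry increased along the sigma grid")
  out
}

#' Write the per-protein asymmetry table
#'
#' @param cohort an asymmetry-annotated \code{ZFCohort}.
#' @param path output TSV path.
#' @return Invisibly, the written data.frame.
#' @export
writeAsymmetryTable <- function(cohort, path) {
  p <- as.data.frame(proteins(cohort))
  out <- p[, c("protein_id", "n_domains", "pct_asym_nonspec",
               "pct_asym_spec")]
  out$pct_asym_nonspec <- round(out$pct_asym_nonspec, 1)
  out$pct_asym_spec <- round(out$pct_asym_spec, 1)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}
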