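## Extract the (pct asymmetry, abundance) working table for one mode,
## dropping proteins lacking either value and counting the exclusions.
.linkageTable <- function(cohort, mode = c("nonspec", "spec")) {
  mode <- match.arg(mode)
  p <- as.data.frame(proteins(cohort))
  pct <- if (mode == "nonspec") p$pct_asym_nonspec else p$pct_asym_spec
  usable <- !is.na(pct) & !is.na(p$abundance)
  list(tab = data.frame(protein_id = p$protein_id[usable],
                        n_domains = p$n_domains[usable],
                        pct = pct[usable],
                        abundance = p$abundance[usable],
                        stringsAsFactors = FALSE),
       n_excluded = sum(!usable))
}

#' Split a cohort into symmetric and asymmetric groups
#'
#' Proteins with percent asymmetry below \code{threshold} form the symmetric
#' group; those at or above it the asymmetric group (the boundary belongs to
#' the asymmetric group). Proteins lacking either the asymmetry percentage
#' or an abundance value are excluded, with the exclusion count reported.
#'
#' @param cohort an annotated \code{ZFCohort}.
#' @param threshold percent threshold (default 50).
#' @param mode "nonspec" or "spec".
#' @return A list: \code{symmetric} and \code{asymmetric} data.frames
#'   (protein_id, n_domains, pct, abundance) and \code{n_excluded}.
#' @export
splitGroups <- function(cohort, threshold = 50, mode = c("nonspec", "spec")) {
  lt <- .linkageTable(cohort, mode)
  if (nrow(lt$tab) == 0L)
    stop("no protein has both percent asymmetry and abundance set")
  sym <- lt$tab[lt$tab$pct < threshold, , drop = FALSE]
  asym <- lt$tab[lt$tab$pct >= threshold, , drop = FALSE]
  list(symmetric = sym, asymmetric = asym, n_excluded = lt$n_excluded,
       threshold = threshold, mode = mode)
}

#' Compare group abundances with an unpaired t-test
#'
#' Two-sided unpaired t-test of the abundance of the symmetric versus the
#' asymmetric group; equal-variance (pooled) by default, Welch optional. The
#' degenerate case of zero variance in both groups is handled directly:
#' identical means give t = 0, p = 1, separated means give p = 0.
#'
#' @param symmetric,asymmetric numeric abundance vectors, each of length
#'   >= 2.
#' @param welch use the Welch (unequal-variance) test.
#' @return A list: \code{n_symmetric}, \code{n_asymmetric},
#'   \code{mean_symmetric}, \code{mean_asymmetric}, \code{t_statistic},
#'   \code{p_value}, \code{method}.
#' @export
compareGroups <- function(symmetric, asymmetric, welch = FALSE) {
  if (length(symmetric) < 2L)
    stop("symmetric group has fewer than 2 proteins")
  if (length(asymmetric) < 2L)
    stop("asymmetric group has fewer than 2 proteins")
  if (stats::var(symmetric) == 0 && stats::var(asymmetric) == 0) {
    same <- mean(symmetric) == mean(asymmetric)
    tt <- list(statistic = if (same) 0 else
                 sign(mean(symmetric) - mean(asymmetric)) * Inf,
               p.value = if (same) 1 else 0)
  } else {
    ht <- stats::t.test(symmetric, asymmetric, var.equal = !welch)
    tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
  }
  list(n_symmetric = length(symmetric), n_asymmetric = length(asymmetric),
       mean_symmetric = mean(symmetric), mean_asymmetric = mean(asymmetric),
       t_statistic = tt$statistic, p_value = tt$p.value,
       method = if (welch) "welch" else "pooled")
}

#' Correlation between percent asymmetry and abundance
#'
#' Pearson product-moment correlation by default; Spearman optional. Zero
#' variance in either vector yields a missing, flagged estimate rather than
#' an error.
#'
#' @param pct percent-asymmetry values.
#' @param abundance matching abundance values.
#' @param method "pearson" (default) or "spearman".
#' @return A list: \code{r}, \code{p_value}, \code{n}, \code{method},
#'   \code{flagged} (TRUE when degenerate).
#' @export
correlateAsymmetry <- function(pct, abundance,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(pct) != length(abundance))
    stop("vectors must have equal length")
  ok <- !is.na(pct) & !is.na(abundance)
  pct <- pct[ok]; abundance <- abundance[ok]
  if (length(pct) < 3L)
    stop("at least 3 complete pairs required")
  if (stats::var(pct) == 0 || stats::var(abundance) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = length(pct),
                method = method, flagged = TRUE))
  ct <- stats::cor.test(pct, abundance, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(pct),
       method = method, flagged = FALSE)
}

#' Bin proteins on both asymmetry axes
#'
#' Places every protein with both asymmetry percentages and an abundance
#' value into a 4 x 4 grid over (percent non-specific asymmetry x percent
#' specific asymmetry) with bins [0,25), [25,50), [50,75), [75,100], and
#' tabulates per-cell protein counts and mean abundances.
#'
#' @param cohort an annotated \code{ZFCohort}.
#' @param edges bin edges (default 0, 25, 50, 75, 100; top bin closed).
#' @return A list: \code{counts} and \code{mean_abundance} matrices (rows:
#'   non-specific bins, columns: specific bins), \code{edges}, \code{n}.
#' @export
binMatrix <- function(cohort, edges = c(0, 25, 50, 75, 100)) {
  if (length(edges) < 3L || is.unsorted(edges, strictly = TRUE))
    stop("edges must be strictly increasing with at least 3 values")
  p <- as.data.frame(proteins(cohort))
  usable <- !is.na(p$pct_asym_nonspec) & !is.na(p$pct_asym_spec) &
    !is.na(p$abundance)
  p <- p[usable, , drop = FALSE]
  nb <- length(edges) - 1L
  cut_bin <- function(x) pmin(findInterval(x, edges[-1]) + 1L, nb)
  bx <- cut_bin(p$pct_asym_nonspec)
  by <- cut_bin(p$pct_asym_spec)
  labs <- paste0("[", edges[-length(edges)], ",", edges[-1],
                 c(rep(")", nb - 1L), "]"))
  counts <- matrix(0L, nb, nb, dimnames = list(nonspec = labs, spec = labs))
  means <- matrix(NA_real_, nb, nb, dimnames = dimnames(counts))
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    sel <- bx == i & by == j
    counts[i, j] <- sum(sel)
    if (any(sel)) means[i, j] <- mean(p$abundance[sel])
  }
  list(counts = counts, mean_abundance = means, edges = edges,
       n = nrow(p))
}

.linkageSummary <- function(cohort, mode, threshold = 50, welch = FALSE,
                            corMethod = "pearson", minUsable = 4L) {
  lt <- .linkageTable(cohort, mode)
  base <- list(mode = mode, group_threshold = threshold,
               n_usable = nrow(lt$tab), n_excluded = lt$n_excluded)
  if (nrow(lt$tab) < minUsable)
    return(c(base, list(underpowered = TRUE)))
  gr <- splitGroups(cohort, threshold = threshold, mode = mode)
  cmp <- if (nrow(gr$symmetric) >= 2L && nrow(gr$asymmetric) >= 2L)
    compareGroups(gr$symmetric$abundance, gr$asymmetric$abundance,
                  welch = welch)
  else list(n_symmetric = nrow(gr$symmetric),
            n_asymmetric = nrow(gr$asymmetric),
            mean_symmetric = if (nrow(gr$symmetric)) mean(gr$symmetric$abundance) else NA_real_,
            mean_asymmetric = if (nrow(gr$asymmetric)) mean(gr$asymmetric$abundance) else NA_real_,
            t_statistic = NA_real_, p_value = NA_real_,
            method = "suppressed")
  corr <- correlateAsymmetry(lt$tab$pct, lt$tab$abundance,
                             method = corMethod)
  c(base, cmp, list(pearson_r = corr$r, correlation_p = corr$p_value,
                    correlation_method = corr$method,
                    underpowered = FALSE))
}

#' Length-stratified linkage summaries
#'
#' Computes the abundance-asymmetry linkage summary (group means, t-test,
#' correlation) separately per domain-count stratum and per mode. Strata
#' with fewer than \code{minUsable} usable proteins are flagged underpowered
#' and their statistics suppressed.
#'
#' @param cohort an annotated \code{ZFCohort}.
#' @param strata list of domain-count vectors; default strata are arrays of
#'   3, of 4, of 3-6 and of 3-15 domains.
#' @param threshold group split threshold (percent).
#' @param welch use the Welch test.
#' @param corMethod "pearson" or "spearman".
#' @param minUsable minimal usable proteins per stratum (default 4).
#' @return A list (one element per stratum) of lists (one per mode) of
#'   linkage summaries.
#' @export
lengthStratifiedReport <- function(cohort,
                                   strata = list("3" = 3L, "4" = 4L,
                                                 "3-6" = 3:6,
                                                 "3-15" = 3:15),
                                   threshold = 50, welch = FALSE,
                                   corMethod = "pearson", minUsable = 4L) {
  p <- proteins(cohort)
  d <- domains(cohort)
  out <- lapply(strata, function(lens) {
    keep <- p$protein_id[p$n_domains %in% lens]
    sub <- new("ZFCohort",
               proteins = p[p$protein_id %in% keep, , drop = FALSE],
               domains = d[d$protein_id %in% keep, , drop = FALSE],
               metadata = metadata(cohort))
    list(n_proteins = length(keep),
         nonspec = .linkageSummary(sub, "nonspec", threshold, welch,
                                   corMethod, minUsable),
         spec = .linkageSummary(sub, "spec", threshold, welch,
                                corMethod, minUsable))
  })
  names(out) <- names(strata)
  out
}

#' Heatmap of a binned asymmetry-abundance matrix
#'
#' Mirrors the two-panel binned view: protein counts or mean abundance on
#' the (non-specific x specific) percent-asymmetry grid. Requires ggplot2.
#'
#' @param bm result of \code{\link{binMatrix}}.
#' @param what "counts" or "mean_abundance".
#' @return A ggplot object.
#' @export
plotBinMatrix <- function(bm, what = c("counts", "mean_abundance")) {
  what <- match.arg(what)
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  m <- bm[[what]]
  df <- data.frame(nonspec = factor(rep(rownames(m), ncol(m)),
                                    levels = rownames(m)),
                   spec = factor(rep(colnames(m), each = nrow(m)),
                                 levels = colnames(m)),
                   value = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nonspec, y = .data$spec,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "% non-specific asymmetry",
                  y = "% specific asymmetry",
                  fill = if (what == "counts") "proteins"
                         else "mean abundance") +
    ggplot2::theme_minimal()
}
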