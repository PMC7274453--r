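#' Net charge of a zinc-finger domain from its sequence
#'
#' Counts (number of positively charged residues) minus (number of
#' negatively charged residues) under a \code{\link{ChargeConvention}}. This
#' integer net charge, in units of the elementary charge e, is the proxy for
#' the strength of a finger's non-specific electrostatic attraction to DNA.
#'
#' @param sequence amino-acid string (one domain).
#' @param conv a \code{ChargeConvention}; default counts His as positive.
#' @param strict reject non-standard residues (default); when \code{FALSE}
#'   unknown residues are treated as uncharged.
#' @return Integer net charge (e).
#' @examples
#' netCharge("KKRHDE")                                # +2
#' netCharge("KKRHDE", ChargeConvention(hisPositive = FALSE))  # +1
#' @export
netCharge <- function(sequence, conv = ChargeConvention(), strict = TRUE) {
  if (length(sequence) != 1L || is.na(sequence) || nchar(sequence) == 0L)
    stop("sequence must be a single non-empty string")
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (strict) {
    bad <- which(!chars %in% AA20)
    if (length(bad) > 0L)
      stop("non-standard residue '", chars[bad[1]], "' at position ",
           bad[1])
  }
  as.integer(sum(chars %in% conv@positive) - sum(chars %in% conv@negative))
}

#' Normalize per-domain net charges within a protein
#'
#' For an array of N >= 2 fingers with net charges q_i, the normalized
#' charge of finger i is q_i minus the mean net charge of the other N - 1
#' fingers of the same protein:
#' \deqn{\bar q_i = q_i - \frac{1}{N-1}\sum_{j \ne i} q_j.}
#' Normalized charges always sum to zero within a protein, making fingers
#' comparable across proteins of different overall charge.
#'
#' @param charges numeric vector of per-domain net charges, length >= 2.
#' @return Numeric vector of normalized charges, same length.
#' @examples
#' normalizeCharges(c(5, 2, 8))   # 0, -4.5, 4.5
#' @export
normalizeCharges <- function(charges) {
  n <- length(charges)
  if (n < 2L)
    stop("charge normalization requires at least 2 domains (got ", n, ")")
  if (anyNA(charges))
    stop("charges must not contain missing values")
  charges - (sum(charges) - charges) / (n - 1)
}

## Fast per-domain charged-residue counts for a whole cohort.
.countCharges <- function(seqs, conv) {
  aas <- Biostrings::AAStringSet(seqs)
  pos <- rowSums(Biostrings::letterFrequency(aas, conv@positive))
  neg <- rowSums(Biostrings::letterFrequency(aas, conv@negative))
  list(pos = as.integer(pos), neg = as.integer(neg))
}

#' Annotate a cohort with net and normalized charges
#'
#' Sets, for every domain, the counts of positive and negative residues, the
#' integer net charge and the within-protein normalized charge.
#'
#' @param cohort a \code{ZFCohort} with assembled domains.
#' @param conv a \code{ChargeConvention}.
#' @return The annotated \code{ZFCohort}.
#' @export
annotateCharges <- function(cohort, conv = ChargeConvention()) {
  d <- domains(cohort)
  if (nrow(d) == 0L) return(cohort)
  cc <- .countCharges(d$sequence, conv)
  d$n_pos <- cc$pos
  d$n_neg <- cc$neg
  d$net_charge <- cc$pos - cc$neg
  f <- factor(d$protein_id, levels = unique(d$protein_id))
  nsize <- as.integer(table(f))[as.integer(f)]
  if (any(nsize < 2L))
    stop("charge normalization requires at least 2 domains per protein; ",
         "protein ", d$protein_id[which(nsize < 2L)[1]], " has fewer")
  tot <- unsplit(lapply(split(d$net_charge, f), sum), f)
  d$normalized_charge <- d$net_charge - (tot - d$net_charge) / (nsize - 1)
  domains(cohort) <- d
  metadata(cohort)$charge_convention <-
    list(positive = conv@positive, negative = conv@negative)
  cohort
}

#' Cohort-level charge statistics
#'
#' Summaries of the per-domain charged-residue composition: mean and
#' standard deviation of positive counts, negative counts and net charge,
#' the fraction of domains with net charge <= 0, and a per-array-length
#' breakdown (mean net charge by number of domains in the parent protein).
#'
#' @param cohort a charge-annotated \code{ZFCohort}.
#' @return A list with elements \code{n_domains}, \code{pos_mean},
#'   \code{pos_sd}, \code{neg_mean}, \code{neg_sd}, \code{net_mean},
#'   \code{net_sd}, \code{frac_net_nonpositive} and \code{by_length}
#'   (data.frame: n_domains, n, mean_net_charge).
#' @export
cohortChargeStats <- function(cohort) {
  d <- domains(cohort)
  p <- proteins(cohort)
  if (nrow(d) == 0L)
    stop("empty cohort")
  if (anyNA(d$net_charge))
    stop("cohort is not charge-annotated; run annotateCharges() first")
  len <- p$n_domains[match(d$protein_id, p$protein_id)]
  by_len <- do.call(rbind, lapply(split(seq_len(nrow(d)), len), function(ii)
    data.frame(n_domains = len[ii[1]], n = length(ii),
               mean_net_charge = mean(d$net_charge[ii]))))
  rownames(by_len) <- NULL
  res <- list(n_domains = nrow(d),
              pos_mean = mean(d$n_pos), pos_sd = stats::sd(d$n_pos),
              neg_mean = mean(d$n_neg), neg_sd = stats::sd(d$n_neg),
              net_mean = mean(d$net_charge), net_sd = stats::sd(d$net_charge),
              frac_net_nonpositive = mean(d$net_charge <= 0),
              by_length = by_len)
  stopifnot(abs(res$net_mean - (res$pos_mean - res$neg_mean)) < 1e-9)
  res
}

#' Write the per-domain charge table
#'
#' @param cohort a charge-annotated \code{ZFCohort}.
#' @param path output TSV path.
#' @return Invisibly, the written data.frame.
#' @export
writeChargeTable <- function(cohort, path) {
  d <- as.data.frame(domains(cohort))
  out <- d[, c("protein_id", "index", "n_pos", "n_neg", "net_charge",
               "normalized_charge")]
  names(out)[2] <- "domain_index"
  out$normalized_charge <- round(out$normalized_charge, 2)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}
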