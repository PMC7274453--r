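#' Read protein sequences from FASTA
#'
#' Reads a FASTA file of full-length protein sequences. Record ids are the
#' first whitespace-delimited token of each header and must be unique;
#' sequences are upper-cased.
#'
#' @param path path to a FASTA file.
#' @return An \code{AAStringSet} named by protein id.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">P1", "MKKRcpeh", ">P2", "ACDEFGH"), fa)
#' readProteinFasta(fa)
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path))
    stop("FASTA file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L)
    stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    stop("duplicate FASTA record id(s): ", paste(dup, collapse = ", "))
  names(seqs) <- ids
  Biostrings::AAStringSet(toupper(as.character(seqs)))
}

#' Read a zinc-finger domain annotation table
#'
#' Reads a tab-separated table with header columns \code{protein_id},
#' \code{index}, \code{start}, \code{end} (1-based inclusive coordinates,
#' UniProt convention). Lines starting with '#' are ignored. Rows are
#' returned grouped by protein and sorted by start; the \code{index} column
#' is renumbered to the sorted order.
#'
#' @param path path to the TSV file.
#' @return A data.frame with columns protein_id, index, start, end.
#' @export
readDomainTable <- function(path) {
  if (!file.exists(path))
    stop("domain table not found: ", path)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("protein_id", "index", "start", "end")
  if (!all(need %in% colnames(tab)))
    stop("domain table must have header columns: ",
         paste(need, collapse = ", "))
  tab <- tab[, need]
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  bad <- which(tab$start > tab$end | tab$start < 1L)
  if (length(bad) > 0L)
    stop("invalid domain coordinates (start > end or start < 1) for ",
         tab$protein_id[bad[1]], " at row ", bad[1])
  tab <- tab[order(tab$protein_id, tab$start), , drop = FALSE]
  rownames(tab) <- NULL
  for (pid in unique(tab$protein_id)) {
    ii <- which(tab$protein_id == pid)
    tab$index[ii] <- seq_along(ii)
    if (length(ii) > 1L && any(tab$start[ii][-1] <= tab$end[ii][-length(ii)]))
      stop("overlapping domains for protein ", pid)
  }
  tab$index <- as.integer(tab$index)
  tab
}

#' Read a protein abundance table
#'
#' Reads a tab-separated table with header columns \code{protein_id} and
#' \code{abundance} (nonnegative, PaxDb-style values proportional to protein
#' copy number). Proteins absent from the table simply carry missing
#' abundance downstream.
#'
#' @param path path to the TSV file.
#' @return A named numeric vector of abundances.
#' @export
readAbundance <- function(path) {
  if (!file.exists(path))
    stop("abundance table not found: ", path)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!all(c("protein_id", "abundance") %in% colnames(tab)))
    stop("abundance table must have header columns: protein_id, abundance")
  if (nrow(tab) == 0L)
    return(stats::setNames(numeric(0), character(0)))
  ab <- as.numeric(tab$abundance)
  if (anyNA(ab))
    stop("non-numeric abundance value at row ", which(is.na(ab))[1])
  if (any(ab < 0))
    stop("negative abundance for protein ",
         tab$protein_id[which(ab < 0)[1]])
  stats::setNames(ab, tab$protein_id)
}

.checkResidues <- function(seq, where, permissive = FALSE) {
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% AA20)
  if (length(bad) > 0L && !permissive)
    stop("non-standard residue '", chars[bad[1]], "' at position ", bad[1],
         " of ", where)
  invisible(TRUE)
}

#' Assemble a zinc-finger protein cohort
#'
#' Combines full-length sequences, domain annotations and (optionally)
#' abundance values into a \code{\link{ZFCohort}}. Domain sequences are
#' extracted from the protein sequence by the annotated 1-based inclusive
#' coordinates. Proteins are ordered canonically by id so the assembled
#' cohort is invariant to input row order.
#'
#' @param sequences \code{AAStringSet} (or named character) of full protein
#'   sequences, as from \code{\link{readProteinFasta}}.
#' @param domainTable data.frame as from \code{\link{readDomainTable}}.
#' @param abundance optional named numeric vector, as from
#'   \code{\link{readAbundance}}.
#' @param names optional named character vector of free-text protein names.
#' @param permissive if \code{TRUE}, non-standard residues (e.g. X, U) are
#'   tolerated and later treated as uncharged and propensity-neutral;
#'   default is to reject them.
#' @return A \code{ZFCohort}.
#' @export
assembleCohort <- function(sequences, domainTable, abundance = NULL,
                           names = NULL, permissive = FALSE) {
  seqs <- stats::setNames(toupper(as.character(sequences)),
                          base::names(sequences))
  pids <- sort(unique(domainTable$protein_id))
  missing_seq <- setdiff(pids, base::names(seqs))
  if (length(missing_seq) > 0L)
    stop("no sequence for protein(s): ",
         paste(missing_seq, collapse = ", "))
  dt <- domainTable[order(match(domainTable$protein_id, pids),
                          domainTable$start), , drop = FALSE]
  too_long <- dt$end > nchar(seqs[dt$protein_id])
  if (any(too_long))
    stop("domain coordinates exceed sequence length for protein ",
         dt$protein_id[which(too_long)[1]])
  dseq <- substring(seqs[dt$protein_id], dt$start, dt$end)
  if (!permissive) {
    bad <- grep(paste0("[^", paste(AA20, collapse = ""), "]"), dseq)
    for (k in bad)
      .checkResidues(dseq[k], paste0(dt$protein_id[k], " domain ",
                                     dt$index[k]))
  }
  nd <- as.integer(table(factor(dt$protein_id, levels = pids)))
  ab <- rep(NA_real_, length(pids))
  if (!is.null(abundance))
    ab <- unname(abundance[pids])
  nm <- if (is.null(names)) pids else {
    out <- pids
    hit <- match(pids, base::names(names))
    out[!is.na(hit)] <- unname(names[hit[!is.na(hit)]])
    out
  }
  prot <- DataFrame(protein_id = pids, name = nm, n_domains = nd,
                    abundance = as.numeric(ab),
                    pct_asym_nonspec = NA_real_, pct_asym_spec = NA_real_)
  dom <- DataFrame(protein_id = dt$protein_id, index = as.integer(dt$index),
                   start = as.integer(dt$start), end = as.integer(dt$end),
                   sequence = unname(dseq),
                   n_pos = NA_integer_, n_neg = NA_integer_,
                   net_charge = NA_integer_, normalized_charge = NA_real_,
                   res_m1 = NA_character_, res_p2 = NA_character_,
                   res_p3 = NA_character_, res_p6 = NA_character_,
                   specificity_score = NA_real_)
  new("ZFCohort", proteins = prot, domains = dom,
      metadata = list(permissive = permissive))
}

#' Curate a cohort to canonical tandem arrays
#'
#' Applies the curation filters that define a canonical tandem zinc-finger
#' array: every inter-domain linker (residues strictly between one domain's
#' annotated end and the next domain's start) must be at most
#' \code{maxLinker} residues, and the domain count must lie in
#' \code{[minDomains, maxDomains]}. By default a protein containing any long
#' linker is dropped whole; \code{clusterMode = "largest_cluster"} instead
#' retains its longest run of short-linker-connected domains (reindexed from
#' 1) before applying the domain-count filter.
#'
#' @param cohort a \code{ZFCohort}.
#' @param maxLinker maximal linker length kept (default 8: linkers must be
#'   shorter than nine residues).
#' @param minDomains,maxDomains retained domain-count range (default 3-15).
#' @param clusterMode "drop" (default) or "largest_cluster".
#' @return A list with elements \code{kept} (curated \code{ZFCohort}) and
#'   \code{dropped} (data.frame of protein_id and failing rule, one of
#'   "linker", "n_domains").
#' @export
curateCohort <- function(cohort, maxLinker = 8L, minDomains = 3L,
                         maxDomains = 15L,
                         clusterMode = c("drop", "largest_cluster")) {
  clusterMode <- match.arg(clusterMode)
  p <- proteins(cohort)
  d <- domains(cohort)
  n <- nrow(d)
  f <- match(d$protein_id, p$protein_id)
  ## adjacent-row linker lengths, NA across protein boundaries
  linker <- rep(NA_integer_, max(n - 1L, 0L))
  if (n > 1L) {
    same <- f[-1] == f[-n]
    linker[same] <- d$start[-1][same] - d$end[-n][same] - 1L
  }
  has_long <- rep(FALSE, nrow(p))
  if (n > 1L) {
    long_at <- which(!is.na(linker) & linker > maxLinker)
    has_long[unique(f[long_at])] <- TRUE
  }
  keep_row <- rep(TRUE, n)
  reindexed <- FALSE
  reason <- rep(NA_character_, nrow(p))
  if (clusterMode == "drop") {
    reason[has_long] <- "linker"
    keep_row[has_long[f]] <- FALSE
  } else {
    ## largest_cluster: keep the longest run of short-linker-connected
    ## domains in each affected protein
    for (pi in which(has_long)) {
      ii <- which(f == pi)
      lnk <- d$start[ii][-1] - d$end[ii][-length(ii)] - 1L
      breaks <- c(0L, which(lnk > maxLinker), length(ii))
      runs <- mapply(function(a, b) (a + 1L):b, breaks[-length(breaks)],
                     breaks[-1], SIMPLIFY = FALSE)
      best <- runs[[which.max(lengths(runs))]]
      keep_row[setdiff(ii, ii[best])] <- FALSE
      reindexed <- TRUE
    }
  }
  n_eff <- tabulate(f[keep_row], nbins = nrow(p))
  bad_n <- is.na(reason) & (n_eff < minDomains | n_eff > maxDomains)
  reason[bad_n] <- "n_domains"
  keep_row[!is.na(reason)[f]] <- FALSE
  keep_ids <- p$protein_id[is.na(reason)]
  dropped <- data.frame(protein_id = p$protein_id[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  kd <- d[keep_row, , drop = FALSE]
  if (nrow(kd) > 0L && reindexed)
    kd$index <- sequence(tabulate(factor(kd$protein_id,
                                         levels = keep_ids)))
  kp <- p[p$protein_id %in% keep_ids, , drop = FALSE]
  if (nrow(kp) > 0L)
    kp$n_domains <- as.integer(table(factor(kd$protein_id,
                                            levels = kp$protein_id)))
  kept <- new("ZFCohort", proteins = kp, domains = kd,
              metadata = c(metadata(cohort),
                           list(curation = list(maxLinker = maxLinker,
                                                minDomains = minDomains,
                                                maxDomains = maxDomains,
                                                clusterMode = clusterMode))))
  list(kept = kept, dropped = dropped)
}

#' Write the curation report TSV
#'
#' One row per input protein: id, domain count, kept/dropped status and the
#' failing rule for dropped proteins.
#'
#' @param cohort the pre-curation \code{ZFCohort}.
#' @param curated result of \code{\link{curateCohort}} on that cohort.
#' @param path output TSV path.
#' @return Invisibly, the written data.frame.
#' @export
writeCurationReport <- function(cohort, curated, path) {
  p <- proteins(cohort)
  status <- ifelse(p$protein_id %in% proteins(curated$kept)$protein_id,
                   "kept", "dropped")
  reason <- rep("", nrow(p))
  hit <- match(p$protein_id, curated$dropped$protein_id)
  reason[!is.na(hit)] <- curated$dropped$reason[hit[!is.na(hit)]]
  out <- data.frame(protein_id = p$protein_id, n_domains = p$n_domains,
                    status = status, reason = reason,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}
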