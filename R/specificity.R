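#' Default C2H2 template anchor
#'
#' The 25-residue first zinc finger of human early growth response protein 1
#' (Egr-1), the canonical C2H2 finger used to anchor all domain alignments.
#' Its zinc-coordinating scaffold is Cys3/Cys8/His21/His25 and the four
#' specificity-determining recognition-helix positions -1, +2, +3 and +6
#' fall at columns 14, 16, 17 and 20 (residues R, D, E, R in the template).
#'
#' @return A \code{\link{TemplateAnchor}}.
#' @examples
#' defaultTemplateAnchor()
#' @export
defaultTemplateAnchor <- function() {
  new("TemplateAnchor",
      template = "YACPVESCDRRFSRSDELTRHIRIH",
      helixColumns = c("-1" = 14L, "+2" = 16L, "+3" = 17L, "+6" = 20L),
      scaffoldColumns = c(3L, 8L, 21L, 25L))
}

## Template segment capacities: residues before Cys1, between the ligands,
## and after His2.
.anchorCaps <- function(anchor) {
  sc <- anchor@scaffoldColumns
  L <- nchar(anchor@template)
  c(pre = sc[1] - 1L, int1 = sc[2] - sc[1] - 1L,
    int2 = sc[3] - sc[2] - 1L, int3 = sc[4] - sc[3] - 1L,
    post = L - sc[4])
}

## Locate the C..C..H..H zinc-ligand scaffold in one query sequence.
## Candidate ligand quadruples must fit the template segment capacities;
## among valid quadruples the one whose inter-ligand spacer lengths deviate
## least from the template's is chosen (ties broken by leftmost positions),
## which keeps the recognition helix anchored to its His even when extra
## Cys/His occur elsewhere in the finger.
.findScaffold <- function(chars, caps) {
  cpos <- which(chars == "C")
  hpos <- which(chars == "H")
  if (length(cpos) < 2L || length(hpos) < 2L) return(NULL)
  best <- NULL
  best_key <- NULL
  for (c1 in cpos) for (c2 in cpos[cpos > c1]) {
    i1 <- c2 - c1 - 1L
    if (i1 > caps["int1"]) next
    for (h1 in hpos[hpos > c2]) {
      i2 <- h1 - c2 - 1L
      if (i2 > caps["int2"]) next
      for (h2 in hpos[hpos > h1]) {
        i3 <- h2 - h1 - 1L
        if (i3 > caps["int3"]) next
        dev <- abs(i1 - caps[["int1"]]) + abs(i2 - caps[["int2"]]) +
          abs(i3 - caps[["int3"]])
        key <- c(dev, c1, c2, h1, h2)
        if (is.null(best_key)) {
          best <- c(c1, c2, h1, h2); best_key <- key
        } else {
          diff_at <- which(key != best_key)
          if (length(diff_at) > 0L && key[diff_at[1]] < best_key[diff_at[1]]) {
            best <- c(c1, c2, h1, h2); best_key <- key
          }
        }
      }
    }
  }
  best
}

.placeSegment <- function(row, content, cols, justify = c("right", "left")) {
  justify <- match.arg(justify)
  n <- length(content)
  k <- length(cols)
  if (n == 0L || k == 0L) return(row)
  if (n > k) {
    ## overhang beyond template capacity: truncate toward the anchor
    content <- if (justify == "right") content[(n - k + 1L):n]
               else content[seq_len(k)]
    n <- k
  }
  use <- if (justify == "right") cols[(k - n + 1L):k] else cols[seq_len(n)]
  row[use] <- content
  row
}

#' Align zinc-finger domains to the template
#'
#' Places each finger onto the template columns by anchoring its four
#' zinc-ligand residues (Cys, Cys, His, His) to the template scaffold
#' columns. The spacer segments between ligands are right-justified against
#' the downstream ligand (so recognition-helix residues keep their fixed
#' offset from the first scaffold His); short spacers leave gap columns,
#' and terminal overhangs beyond the template are truncated. Fingers in
#' which no ligand quadruple fits the template spacer capacities are flagged
#' unalignable and returned as all-gap rows.
#'
#' @param sequences character vector (or \code{AAStringSet}) of domain
#'   sequences.
#' @param anchor a \code{\link{TemplateAnchor}}.
#' @return A character matrix with one row per input sequence (input order
#'   preserved) and one column per template column; gap cells hold "-".
#'   Attributes: \code{alignable} (logical per row), \code{helixColumns}.
#' @examples
#' a <- defaultTemplateAnchor()
#' alignToTemplate(a@template, a)   # identity row
#' @export
alignToTemplate <- function(sequences, anchor = defaultTemplateAnchor()) {
  seqs <- toupper(as.character(sequences))
  caps <- .anchorCaps(anchor)
  sc <- anchor@scaffoldColumns
  L <- nchar(anchor@template)
  out <- matrix(GAP_CHAR, nrow = length(seqs), ncol = L)
  alignable <- logical(length(seqs))
  for (r in seq_along(seqs)) {
    chars <- strsplit(seqs[r], "")[[1]]
    hit <- .findScaffold(chars, caps)
    if (is.null(hit)) next
    row <- rep(GAP_CHAR, L)
    row[sc] <- c("C", "C", "H", "H")
    segs <- list(
      list(content = chars[seq_len(hit[1] - 1L)],
           cols = seq_len(sc[1] - 1L), justify = "right"),
      list(content = if (hit[2] - hit[1] > 1L)
             chars[(hit[1] + 1L):(hit[2] - 1L)] else character(0),
           cols = if (sc[2] - sc[1] > 1L) (sc[1] + 1L):(sc[2] - 1L)
                  else integer(0), justify = "right"),
      list(content = if (hit[3] - hit[2] > 1L)
             chars[(hit[2] + 1L):(hit[3] - 1L)] else character(0),
           cols = if (sc[3] - sc[2] > 1L) (sc[2] + 1L):(sc[3] - 1L)
                  else integer(0), justify = "right"),
      list(content = if (hit[4] - hit[3] > 1L)
             chars[(hit[3] + 1L):(hit[4] - 1L)] else character(0),
           cols = if (sc[4] - sc[3] > 1L) (sc[3] + 1L):(sc[4] - 1L)
                  else integer(0), justify = "right"),
      list(content = if (length(chars) > hit[4])
             chars[(hit[4] + 1L):length(chars)] else character(0),
           cols = if (L > sc[4]) (sc[4] + 1L):L else integer(0),
           justify = "left"))
    for (s in segs)
      row <- .placeSegment(row, s$content, s$cols, s$justify)
    out[r, ] <- row
    alignable[r] <- TRUE
  }
  rownames(out) <- names(seqs)
  colnames(out) <- seq_len(L)
  attr(out, "alignable") <- alignable
  attr(out, "helixColumns") <- anchor@helixColumns
  out
}

#' Per-column residue propensities from an alignment
#'
#' Estimates the probability of each of the 20 residues (plus the gap as a
#' 21st category) at every template column as
#' \code{(count + pseudocount) / (n + 21 * pseudocount)}, where n is the
#' number of alignable rows. The maximal residue propensity (gap excluded)
#' is recorded for the four recognition-helix columns; these maxima
#' normalize the specificity score.
#'
#' @param alignment matrix from \code{\link{alignToTemplate}}; unalignable
#'   rows are excluded.
#' @param pseudocount additive pseudocount per category (default 0.5; use 0
#'   for exact frequencies).
#' @param anchor the \code{TemplateAnchor} naming the helix columns; taken
#'   from the alignment attributes when available.
#' @return A \code{\link{PropensityTable}}.
#' @export
computePropensities <- function(alignment, pseudocount = 0.5,
                                anchor = NULL) {
  hc <- if (!is.null(anchor)) anchor@helixColumns
        else attr(alignment, "helixColumns")
  if (is.null(hc))
    stop("helix columns unknown: pass the TemplateAnchor")
  ok <- attr(alignment, "alignable")
  if (is.null(ok)) ok <- rep(TRUE, nrow(alignment))
  aln <- alignment[ok, , drop = FALSE]
  n <- nrow(aln)
  if (n < 2L)
    stop("propensity estimation requires at least 2 aligned rows (got ",
         n, ")")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  cats <- c(AA20, GAP_CHAR)
  counts <- apply(aln, 2L, function(col)
    as.integer(table(factor(col, levels = cats))))
  rownames(counts) <- cats
  prob <- (counts + pseudocount) / (n + length(cats) * pseudocount)
  pmax_v <- vapply(hc, function(j) max(prob[AA20, j]), numeric(1))
  pmax_r <- vapply(hc, function(j) AA20[which.max(prob[AA20, j])],
                   character(1))
  if (any(pmax_v <= 0))
    stop("a helix column has zero maximal propensity; use pseudocount > 0")
  new("PropensityTable", prob = prob, helixColumns = hc,
      pMax = pmax_v, pMaxResidue = pmax_r,
      nSequences = as.integer(n), pseudocount = pseudocount)
}

#' Specificity score of one zinc finger
#'
#' Scores the four recognition residues (positions -1, +2, +3, +6) against a
#' propensity table. The score compares the log joint propensity of the
#' observed residues with that of the per-column maximal residues. Under the
#' default \code{"consistent"} orientation
#' \deqn{S = \ln\left(\prod_x P_x^{y,max}\right) / \ln\left(\prod_x P_x^{y}\right)}
#' so S lies in (0, 1], equals 1 exactly when all four residues are
#' column-maximal, and decreases as any residue becomes rarer at its
#' position. The \code{"as_printed"} orientation is the reciprocal ratio
#' (observed over maximal), which is >= 1 and decreases toward 1 for common
#' residues; it is retained for auditability of the score's published form.
#'
#' @param residues character vector of 4 residues in order -1, +2, +3, +6.
#' @param table a \code{\link{PropensityTable}}.
#' @param orientation "consistent" (default) or "as_printed".
#' @return A list: \code{score}, \code{orientation}, \code{residues},
#'   \code{propensity} (per-position P), \code{pMax}.
#' @export
specificityScore <- function(residues, table,
                             orientation = c("consistent", "as_printed")) {
  orientation <- match.arg(orientation)
  if (length(residues) != 4L)
    stop("exactly 4 recognition residues required")
  residues <- toupper(residues)
  bad <- which(!residues %in% AA20)
  if (length(bad) > 0L)
    stop("residue '", residues[bad[1]],
         "' is not in the 20-letter alphabet")
  hc <- table@helixColumns
  p <- table@prob[cbind(match(residues, rownames(table@prob)), hc)]
  names(p) <- names(hc)
  lp <- sum(log(p))
  lpm <- sum(log(table@pMax))
  score <- if (abs(lp - lpm) < 1e-12) 1
           else if (orientation == "consistent") lpm / lp
           else lp / lpm
  list(score = score, orientation = orientation, residues = residues,
       propensity = p, pMax = table@pMax)
}

#' Annotate a cohort with recognition residues and specificity scores
#'
#' Aligns every domain to the template, records the residues at helix
#' positions -1, +2, +3, +6 and sets the per-domain specificity score.
#' Unalignable domains, and domains with a gap at any helix position, carry
#' a missing score and are excluded from downstream asymmetry pairs. When no
#' propensity table is supplied, one is estimated from this cohort's own
#' alignment and stored in the cohort metadata.
#'
#' @param cohort a \code{ZFCohort}.
#' @param anchor a \code{\link{TemplateAnchor}}.
#' @param table optional precomputed \code{\link{PropensityTable}}.
#' @param pseudocount used when estimating the table from the cohort.
#' @param orientation score orientation, see \code{\link{specificityScore}}.
#' @return The annotated \code{ZFCohort}; the table used is available as
#'   \code{metadata(x)$propensity_table}.
#' @export
annotateSpecificity <- function(cohort, anchor = defaultTemplateAnchor(),
                                table = NULL, pseudocount = 0.5,
                                orientation = c("consistent",
                                                "as_printed")) {
  orientation <- match.arg(orientation)
  d <- domains(cohort)
  if (nrow(d) == 0L) return(cohort)
  aln <- alignToTemplate(d$sequence, anchor)
  if (is.null(table))
    table <- computePropensities(aln, pseudocount = pseudocount,
                                 anchor = anchor)
  hc <- table@helixColumns
  res <- aln[, hc, drop = FALSE]
  ok <- attr(aln, "alignable") &
    apply(res, 1L, function(r) all(r %in% AA20))
  d$res_m1 <- ifelse(ok, res[, 1], NA_character_)
  d$res_p2 <- ifelse(ok, res[, 2], NA_character_)
  d$res_p3 <- ifelse(ok, res[, 3], NA_character_)
  d$res_p6 <- ifelse(ok, res[, 4], NA_character_)
  sc <- rep(NA_real_, nrow(d))
  if (any(ok)) {
    lpm <- sum(log(table@pMax))
    cats <- rownames(table@prob)
    pm <- vapply(seq_along(hc), function(k)
      table@prob[match(res[ok, k], cats), hc[k]], numeric(sum(ok)))
    pm <- matrix(pm, nrow = sum(ok))
    lp <- rowSums(log(pm))
    s <- if (orientation == "consistent") lpm / lp else lp / lpm
    s[abs(lp - lpm) < 1e-12] <- 1
    sc[ok] <- s
  }
  d$specificity_score <- sc
  domains(cohort) <- d
  metadata(cohort)$propensity_table <- table
  metadata(cohort)$score_orientation <- orientation
  cohort
}

#' Per-column residue composition of an alignment
#'
#' Raw percentage of each residue category (20 residues plus gap) at every
#' template column, over the alignable rows.
#'
#' @param alignment matrix from \code{\link{alignToTemplate}}.
#' @return A 21 x L matrix of percentages; columns sum to 100.
#' @export
positionComposition <- function(alignment) {
  ok <- attr(alignment, "alignable")
  if (is.null(ok)) ok <- rep(TRUE, nrow(alignment))
  aln <- alignment[ok, , drop = FALSE]
  if (nrow(aln) == 0L)
    stop("no alignable rows")
  cats <- c(AA20, GAP_CHAR)
  counts <- apply(aln, 2L, function(col)
    as.integer(table(factor(col, levels = cats))))
  rownames(counts) <- cats
  100 * counts / nrow(aln)
}

#' Write a propensity table as TSV (percentages)
#'
#' @param table a \code{\link{PropensityTable}}.
#' @param path output TSV path.
#' @return Invisibly, the written data.frame.
#' @export
writePropensityTable <- function(table, path) {
  out <- data.frame(category = rownames(table@prob),
                    round(100 * table@prob, 3), check.names = FALSE)
  names(out)[-1] <- paste0("col", seq_len(ncol(table@prob)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}

#' Write the per-domain specificity score table
#'
#' @param cohort a specificity-annotated \code{ZFCohort}.
#' @param path output TSV path.
#' @return Invisibly, the written data.frame.
#' @export
writeSpecificityTable <- function(cohort, path) {
  d <- as.data.frame(domains(cohort))
  out <- d[, c("protein_id", "index", "res_m1", "res_p2", "res_p3",
               "res_p6", "specificity_score")]
  names(out)[2] <- "domain_index"
  out$orientation <- metadata(cohort)$score_orientation
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}
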