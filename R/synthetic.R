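## Generation propensity model for the four recognition-helix positions:
## a column-maximal residue per position (drawn with probability
## specMaxFraction) and neutral polar alternatives. Arg maxima at -1/+6 and
## the strong Ser preference at +2 mirror the composition of natural
## C2H2 fingers.
GEN_HELIX_MAX <- c("-1" = "R", "+2" = "S", "+3" = "N", "+6" = "R")
GEN_HELIX_ALT <- list("-1" = c("S", "T", "N", "Q"),
                      "+2" = c("T", "N", "Q"),
                      "+3" = c("S", "T", "Q"),
                      "+6" = c("S", "T", "N", "Q"))
## Fill alphabet for non-scaffold, non-recognition, uncharged positions;
## excludes C and H so the zinc-ligand scaffold stays unambiguous, and all
## charged residues so charge targets are exact.
NEUTRAL_AA <- c("A", "G", "S", "T", "N", "Q", "L", "V", "I", "F", "P",
                "M", "W", "Y")

#' Construct synthetic cohort parameters
#'
#' @param nProteins number of proteins (default 100).
#' @param domainCountProbs probability vector over domain counts 3..15;
#'   default is skewed toward short arrays of 3-6 domains.
#' @param posCountMean,posCountSd per-domain positive residue count draw
#'   (default 6.5 / 1.4).
#' @param negCountMean,negCountSd per-domain negative residue count draw
#'   (default 1.6 / 1.0).
#' @param pAsymProtein probability a protein carries injected high/low
#'   net-charge alternation along its array (default 0.4).
#' @param highChargeMean,lowChargeMean alternating net-charge targets for
#'   injected proteins (default 7 and 1).
#' @param specMaxFraction probability a recognition residue is the
#'   column-maximal residue of the generation model (default 0.8).
#' @param hisFraction probability an extra positive residue is His rather
#'   than Lys/Arg (default 0.2).
#' @param abundanceAlpha,abundanceBeta,abundanceNoiseSd log-abundance model
#'   \code{exp(alpha - beta * pctAsymTrue/100 + N(0, sd))}; defaults
#'   log(2), 1, 0.5.
#' @param linkerLength inter-domain linker length (default 5, within the
#'   curation filter).
#' @param seed integer seed of the cohort random stream.
#' @return A \code{\link{CohortParams}} object.
#' @export
CohortParams <- function(nProteins = 100L,
                         domainCountProbs = NULL,
                         posCountMean = 6.5, posCountSd = 1.4,
                         negCountMean = 1.6, negCountSd = 1.0,
                         pAsymProtein = 0.4,
                         highChargeMean = 7, lowChargeMean = 1,
                         specMaxFraction = 0.8, hisFraction = 0.2,
                         abundanceAlpha = log(2), abundanceBeta = 1,
                         abundanceNoiseSd = 0.5,
                         linkerLength = 5L, seed = 1L) {
  if (is.null(domainCountProbs)) {
    domainCountProbs <- c(0.20, 0.18, 0.14, 0.10, 0.08, 0.07, 0.06,
                          0.05, 0.04, 0.03, 0.02, 0.02, 0.01)
    names(domainCountProbs) <- as.character(3:15)
  }
  new("CohortParams", nProteins = as.integer(nProteins),
      domainCountProbs = domainCountProbs,
      posCountMean = posCountMean, posCountSd = posCountSd,
      negCountMean = negCountMean, negCountSd = negCountSd,
      pAsymProtein = pAsymProtein,
      highChargeMean = highChargeMean, lowChargeMean = lowChargeMean,
      specMaxFraction = specMaxFraction, hisFraction = hisFraction,
      abundanceAlpha = abundanceAlpha, abundanceBeta = abundanceBeta,
      abundanceNoiseSd = abundanceNoiseSd,
      linkerLength = as.integer(linkerLength), seed = as.integer(seed))
}

.drawRecognition <- function(specMaxFraction) {
  vapply(names(GEN_HELIX_MAX), function(lab) {
    if (stats::runif(1) < specMaxFraction) GEN_HELIX_MAX[[lab]]
    else sample(GEN_HELIX_ALT[[lab]], 1L)
  }, character(1))
}

#' Generate one synthetic zinc-finger domain sequence
#'
#' Emits a domain on the template scaffold (fixed Cys/Cys/His/His ligands,
#' recognition residues at the four helix columns) whose positive and
#' negative residue counts under \code{conv} are exactly \code{nPos} and
#' \code{nNeg}. Residues already implied by the scaffold and the recognition
#' positions (e.g. the two scaffold His under the default His-positive
#' convention, or an Arg recognition residue) count toward the positive
#' total, so the targets must be at least that large. Uses the caller's RNG
#' stream.
#'
#' @param nPos,nNeg requested counts of positively and negatively charged
#'   residues.
#' @param anchor a \code{\link{TemplateAnchor}} defining scaffold and helix
#'   columns.
#' @param conv the \code{\link{ChargeConvention}} under which counts are
#'   taken.
#' @param specMaxFraction probability each recognition residue is drawn as
#'   its column maximum; ignored when \code{recResidues} is given.
#' @param hisFraction probability an extra positive is His.
#' @param recResidues optional fixed recognition residues (-1, +2, +3, +6).
#' @return The domain sequence (single string) with attribute
#'   \code{recognition}.
#' @examples
#' set.seed(1)
#' s <- generateDomainSequence(6, 1)
#' netCharge(s)   # 5
#' @export
generateDomainSequence <- function(nPos, nNeg,
                                   anchor = defaultTemplateAnchor(),
                                   conv = ChargeConvention(),
                                   specMaxFraction = 0.8,
                                   hisFraction = 0.2,
                                   recResidues = NULL) {
  if (nPos < 0 || nNeg < 0) stop("targets must be >= 0")
  L <- nchar(anchor@template)
  sc <- anchor@scaffoldColumns
  hc <- anchor@helixColumns
  chars <- rep(NA_character_, L)
  chars[sc] <- c("C", "C", "H", "H")
  rec <- if (is.null(recResidues)) .drawRecognition(specMaxFraction)
         else toupper(recResidues)
  if (length(rec) != 4L) stop("recResidues must have length 4")
  chars[hc] <- rec
  placed_pos <- sum(chars %in% conv@positive, na.rm = TRUE)
  placed_neg <- sum(chars %in% conv@negative, na.rm = TRUE)
  extra_pos <- nPos - placed_pos
  extra_neg <- nNeg - placed_neg
  if (extra_pos < 0 || extra_neg < 0)
    stop("charge targets below the scaffold/recognition contribution (",
         placed_pos, " positive, ", placed_neg, " negative)")
  free <- which(is.na(chars))
  if (extra_pos + extra_neg > length(free))
    stop("charge targets exceed the ", length(free),
         " available positions")
  pos_alphabet <- intersect(c("K", "R"), conv@positive)
  his_ok <- "H" %in% conv@positive
  pick <- sample(free, extra_pos + extra_neg)
  if (extra_pos > 0L) {
    ppos <- pick[seq_len(extra_pos)]
    use_his <- his_ok & (stats::runif(extra_pos) < hisFraction)
    chars[ppos] <- ifelse(use_his, "H",
                          sample(pos_alphabet, extra_pos, replace = TRUE))
  }
  if (extra_neg > 0L) {
    npos <- pick[extra_pos + seq_len(extra_neg)]
    chars[npos] <- sample(conv@negative, extra_neg, replace = TRUE)
  }
  rest <- which(is.na(chars))
  if (length(rest) > 0L)
    chars[rest] <- sample(NEUTRAL_AA, length(rest), replace = TRUE)
  out <- paste(chars, collapse = "")
  attr(out, "recognition") <- rec
  out
}

.proteinSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}

#' Generate a synthetic zinc-finger protein cohort
#'
#' Draws a seeded cohort with the statistical structure the analysis
#' assumes: domain counts from \code{domainCountProbs}; per-domain
#' positive/negative residue counts from rounded normal draws (clipped to
#' the feasible range of each domain); a fraction \code{pAsymProtein} of
#' proteins carrying injected high/low net-charge alternation along the
#' array; recognition residues from the generation propensity model; and
#' abundance from the log-linear model
#' \code{exp(alpha - beta * pctAsymTrue/100 + noise)} where
#' \code{pctAsymTrue} is 100 for injected proteins and 0 otherwise. Each
#' protein uses a substream seeded deterministically from the cohort seed,
#' so output is bit-identical for identical (params, seed).
#'
#' @param params a \code{\link{CohortParams}}.
#' @param anchor a \code{\link{TemplateAnchor}}.
#' @param conv the \code{\link{ChargeConvention}} used for charge targets.
#' @return A list: \code{sequences} (named character, full proteins),
#'   \code{domainTable} (protein_id, index, start, end), \code{abundance}
#'   (named numeric), \code{truth} (data.frame: protein_id, n_domains,
#'   injected_asym, pct_asym_true, abundance), \code{params}.
#' @export
generateCohort <- function(params, anchor = defaultTemplateAnchor(),
                           conv = ChargeConvention()) {
  validObject(params)
  n <- params@nProteins
  L <- nchar(anchor@template)
  lens <- as.integer(names(params@domainCountProbs))
  seqs <- character(n)
  ids <- sprintf("SZF%04d", seq_len(n))
  dom_list <- vector("list", n)
  truth <- data.frame(protein_id = ids,
                      n_domains = rep(NA_integer_, n),
                      injected_asym = rep(NA, n),
                      pct_asym_true = rep(NA_real_, n),
                      abundance = rep(NA_real_, n),
                      stringsAsFactors = FALSE)
  sc <- anchor@scaffoldColumns
  hc <- anchor@helixColumns
  free <- setdiff(seq_len(L), c(sc, hc))
  max_extra <- length(free)
  scaffold_pos <- sum(c("C", "C", "H", "H") %in% conv@positive)
  pos_alphabet <- intersect(c("K", "R"), conv@positive)
  his_ok <- "H" %in% conv@positive
  for (i in seq_len(n)) {
    set.seed(.proteinSeed(params@seed, i))
    N <- sample(lens, 1L, prob = params@domainCountProbs)
    injected <- stats::runif(1) < params@pAsymProtein
    ## batched recognition residues (N x 4), then batched count targets
    recMat <- vapply(seq_along(GEN_HELIX_MAX), function(k) {
      alt <- GEN_HELIX_ALT[[k]]
      ifelse(stats::runif(N) < params@specMaxFraction,
             GEN_HELIX_MAX[[k]], alt[sample.int(length(alt), N,
                                                replace = TRUE)])
    }, character(N))
    recMat <- matrix(recMat, nrow = N)
    base_pos <- scaffold_pos +
      rowSums(matrix(recMat %in% conv@positive, nrow = N))
    base_neg <- rowSums(matrix(recMat %in% conv@negative, nrow = N))
    nNeg <- round(stats::rnorm(N, params@negCountMean, params@negCountSd))
    nNeg <- pmin(pmax(nNeg, base_neg), base_neg + max_extra)
    nPos <- if (injected) {
      round(ifelse(seq_len(N) %% 2L == 1L, params@highChargeMean,
                   params@lowChargeMean)) + nNeg
    } else round(stats::rnorm(N, params@posCountMean, params@posCountSd))
    nPos <- pmin(pmax(nPos, base_pos),
                 base_pos + max_extra - (nNeg - base_neg))
    ## assemble all N domains as one character matrix: neutral fill, then
    ## charged residues at randomly chosen free positions per domain
    chars <- matrix(NA_character_, nrow = N, ncol = L)
    chars[, sc] <- rep(c("C", "C", "H", "H"), each = N)
    chars[, hc] <- recMat
    chars[, free] <- sample(NEUTRAL_AA, N * max_extra, replace = TRUE)
    extra_pos <- nPos - base_pos
    extra_neg <- nNeg - base_neg
    for (j in seq_len(N)) {
      ep <- extra_pos[j]; en <- extra_neg[j]
      if (ep + en == 0L) next
      at <- free[sample.int(max_extra, ep + en)]
      if (ep > 0L) {
        use_his <- his_ok & (stats::runif(ep) < params@hisFraction)
        chars[j, at[seq_len(ep)]] <-
          ifelse(use_his, "H",
                 pos_alphabet[sample.int(length(pos_alphabet), ep,
                                         replace = TRUE)])
      }
      if (en > 0L)
        chars[j, at[ep + seq_len(en)]] <-
          conv@negative[sample.int(length(conv@negative), en,
                                   replace = TRUE)]
    }
    dseqs <- do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))
    linker_n <- params@linkerLength
    linkers <- vapply(seq_len(N + 1L), function(k)
      paste(sample(NEUTRAL_AA, linker_n, replace = TRUE), collapse = ""),
      character(1))
    parts <- character(2L * N + 1L)
    parts[seq(1L, 2L * N + 1L, by = 2L)] <- linkers
    parts[seq(2L, 2L * N, by = 2L)] <- dseqs
    seqs[i] <- paste(parts, collapse = "")
    starts <- linker_n + (seq_len(N) - 1L) * (L + linker_n) + 1L
    dom_list[[i]] <- data.frame(protein_id = ids[i], index = seq_len(N),
                                start = starts, end = starts + L - 1L,
                                stringsAsFactors = FALSE)
    pct_true <- if (injected) 100 else 0
    ab <- exp(params@abundanceAlpha -
                params@abundanceBeta * pct_true / 100 +
                stats::rnorm(1, 0, params@abundanceNoiseSd))
    truth$n_domains[i] <- N
    truth$injected_asym[i] <- injected
    truth$pct_asym_true[i] <- pct_true
    truth$abundance[i] <- ab
  }
  names(seqs) <- ids
  domainTable <- if (n > 0L) do.call(rbind, dom_list) else
    data.frame(protein_id = character(0), index = integer(0),
               start = integer(0), end = integer(0))
  list(sequences = seqs, domainTable = domainTable,
       abundance = stats::setNames(truth$abundance, ids),
       truth = truth, params = params)
}

#' Write a generated cohort to disk
#'
#' Emits the exact input formats of the pipeline: \code{cohort.fasta},
#' \code{domains.tsv}, \code{abundance.tsv}, plus \code{truth.tsv} and a
#' \code{cohort-metadata.json} echoing all generator parameters.
#'
#' @param params a \code{\link{CohortParams}}, or a generated cohort list
#'   from \code{\link{generateCohort}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of the written file paths.
#' @export
simulateCohort <- function(params, dir) {
  gen <- if (is(params, "CohortParams")) generateCohort(params) else params
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(fasta = file.path(dir, "cohort.fasta"),
                domains = file.path(dir, "domains.tsv"),
                abundance = file.path(dir, "abundance.tsv"),
                truth = file.path(dir, "truth.tsv"),
                metadata = file.path(dir, "cohort-metadata.json"))
  fa <- character(0)
  if (length(gen$sequences) > 0L)
    fa <- as.vector(rbind(paste0(">", names(gen$sequences)),
                          unname(gen$sequences)))
  writeLines(fa, paths$fasta)
  utils::write.table(gen$domainTable, paths$domains, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ab <- data.frame(protein_id = names(gen$abundance),
                   abundance = unname(gen$abundance))
  utils::write.table(ab, paths$abundance, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(gen$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p <- gen$params
  meta <- list(n_proteins = p@nProteins,
               domain_count_probs = as.list(p@domainCountProbs),
               pos_count = c(mean = p@posCountMean, sd = p@posCountSd),
               neg_count = c(mean = p@negCountMean, sd = p@negCountSd),
               p_asym_protein = p@pAsymProtein,
               high_charge_mean = p@highChargeMean,
               low_charge_mean = p@lowChargeMean,
               spec_max_fraction = p@specMaxFraction,
               his_fraction = p@hisFraction,
               abundance_model = c(alpha = p@abundanceAlpha,
                                   beta = p@abundanceBeta,
                                   noise_sd = p@abundanceNoiseSd),
               abundance_noise_note = paste(
                 "noise sd is a free parameter of the generator;",
                 "no dispersion is specified for real abundance data"),
               linker_length = p@linkerLength,
               seed = p@seed,
               files = lapply(paths, basename))
  jsonlite::write_json(meta, paths$metadata, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Assemble a ZFCohort from a generated cohort (in memory)
#'
#' @param gen result of \code{\link{generateCohort}}.
#' @return A \code{ZFCohort}.
#' @export
cohortFromGenerated <- function(gen) {
  assembleCohort(gen$sequences, gen$domainTable, gen$abundance)
}

#' Run the pipeline on a generated cohort and recover the coupling
#'
#' End-to-end parameter-recovery harness: reads (or takes in memory) a
#' generated cohort, curates it, annotates charges (and optionally
#' specificity), computes percent asymmetry and summarizes the
#' abundance-asymmetry linkage. Used to verify that a cohort generated with
#' a known abundance-asymmetry coupling (beta) yields the expected sign and
#' magnitude of association.
#'
#' @param x a directory written by \code{\link{simulateCohort}}, or the list
#'   returned by \code{\link{generateCohort}}.
#' @param cfg an \code{\link{AsymmetryConfig}}.
#' @param conv a \code{\link{ChargeConvention}}.
#' @param anchor a \code{\link{TemplateAnchor}}.
#' @param threshold group split threshold (percent).
#' @param stages "full" (charge + specificity) or "nonspec" (charge-based
#'   asymmetry only, when only the electrostatic linkage is under study).
#' @param corMethod "pearson" or "spearman".
#' @return A list: \code{nonspec} and (for full runs) \code{spec} linkage
#'   summaries, \code{truth} (when available) and the annotated
#'   \code{cohort}.
#' @export
recoverCoupling <- function(x, cfg = AsymmetryConfig(),
                            conv = ChargeConvention(),
                            anchor = defaultTemplateAnchor(),
                            threshold = 50,
                            stages = c("full", "nonspec"),
                            corMethod = "pearson") {
  stages <- match.arg(stages)
  step <- "input"
  res <- tryCatch({
    if (is.character(x)) {
      step <- "io_curation"
      seqs <- readProteinFasta(file.path(x, "cohort.fasta"))
      dt <- readDomainTable(file.path(x, "domains.tsv"))
      ab <- readAbundance(file.path(x, "abundance.tsv"))
      cohort <- assembleCohort(seqs, dt, ab)
      truth_path <- file.path(x, "truth.tsv")
      truth <- if (file.exists(truth_path))
        utils::read.delim(truth_path, stringsAsFactors = FALSE) else NULL
    } else {
      step <- "io_curation"
      cohort <- cohortFromGenerated(x)
      truth <- x$truth
    }
    step <- "curation"
    cohort <- curateCohort(cohort)$kept
    step <- "electrostatics"
    cohort <- annotateCharges(cohort, conv)
    if (stages == "full") {
      step <- "specificity"
      cohort <- annotateSpecificity(cohort, anchor)
    }
    step <- "asymmetry"
    cohort <- annotateAsymmetry(cohort, cfg)
    step <- "linkage"
    out <- list(nonspec = .linkageSummary(cohort, "nonspec",
                                          threshold = threshold,
                                          corMethod = corMethod))
    if (stages == "full")
      out$spec <- .linkageSummary(cohort, "spec", threshold = threshold,
                                  corMethod = corMethod)
    out$truth <- truth
    out$cohort <- cohort
    out
  }, error = function(e)
    stop("pipeline failed at stage '", step, "': ", conditionMessage(e),
         call. = FALSE))
  res
}
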