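## Default run configuration. Every cutoff of the analysis is a config key
## and is echoed verbatim into the run metadata.
.defaultRunConfig <- function() {
  list(input_fasta = NULL, input_domains = NULL, input_abundance = NULL,
       out_dir = NULL,
       max_linker = 8L, min_domains = 3L, max_domains = 15L,
       cluster_mode = "drop",
       his_positive = TRUE,
       sigma_nonspec = 3, neg_charge_threshold = -2,
       pair_rule_nonspec = "and", use_normalized = TRUE,
       sigma_spec = 0.2, low_spec_threshold = 0.6,
       pair_rule_spec = "either_or_both",
       orientation = "consistent", pseudocount = 0.5,
       group_threshold = 50, bin_edges = c(0, 25, 50, 75, 100),
       welch = FALSE, spearman = FALSE,
       seed = 1L)
}

#' Read a run configuration file
#'
#' Flat key-value YAML; unknown keys are rejected, missing keys take the
#' documented defaults. Keys supplied in \code{overrides} (e.g. from command
#' line flags) take precedence over file values.
#'
#' @param path YAML file path, or \code{NULL} for pure defaults.
#' @param overrides named list of overriding values.
#' @return A complete configuration list.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- .defaultRunConfig()
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  for (src in list(vals, overrides)) {
    unknown <- setdiff(names(src), names(cfg))
    if (length(unknown) > 0L)
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg[names(src)] <- src
  }
  ## validate by constructing the typed config objects
  AsymmetryConfig(sigmaNonspec = cfg$sigma_nonspec,
                  negChargeThreshold = cfg$neg_charge_threshold,
                  pairRuleNonspec = cfg$pair_rule_nonspec,
                  sigmaSpec = cfg$sigma_spec,
                  lowSpecThreshold = cfg$low_spec_threshold,
                  pairRuleSpec = cfg$pair_rule_spec,
                  useNormalized = cfg$use_normalized)
  if (!cfg$orientation %in% c("consistent", "as_printed"))
    stop('orientation must be "consistent" or "as_printed"')
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order curate, charges, specificity, asymmetry,
#' linkage on the configured inputs and writes every stage's table plus a
#' linkage summary JSON and a run-metadata JSON (echoing all cutoffs, so a
#' run can be re-executed from its metadata alone) into the output
#' directory.
#'
#' @param config a configuration list (see \code{\link{readRunConfig}}) or a
#'   YAML file path.
#' @param outDir output directory; defaults to \code{config$out_dir}.
#' @return Invisibly, a list with the annotated \code{cohort}, the
#'   \code{linkage} report, the \code{bins} matrices and the output paths.
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  else config <- readRunConfig(NULL, overrides = config)
  if (is.null(outDir)) outDir <- config$out_dir
  if (is.null(outDir)) stop("an output directory is required (out_dir)")
  for (key in c("input_fasta", "input_domains")) {
    if (is.null(config[[key]]))
      stop("configuration key ", key, " is required")
    if (!file.exists(config[[key]]))
      stop("input file not found (", key, "): ", config[[key]])
  }
  if (!is.null(config$input_abundance) &&
      !file.exists(config$input_abundance))
    stop("input file not found (input_abundance): ", config$input_abundance)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)

  conv <- ChargeConvention(hisPositive = isTRUE(config$his_positive))
  acfg <- AsymmetryConfig(sigmaNonspec = config$sigma_nonspec,
                          negChargeThreshold = config$neg_charge_threshold,
                          pairRuleNonspec = config$pair_rule_nonspec,
                          sigmaSpec = config$sigma_spec,
                          lowSpecThreshold = config$low_spec_threshold,
                          pairRuleSpec = config$pair_rule_spec,
                          useNormalized = isTRUE(config$use_normalized))
  anchor <- defaultTemplateAnchor()

  seqs <- readProteinFasta(config$input_fasta)
  dt <- readDomainTable(config$input_domains)
  ab <- if (is.null(config$input_abundance)) NULL
        else readAbundance(config$input_abundance)
  cohort <- assembleCohort(seqs, dt, ab)
  cur <- curateCohort(cohort, maxLinker = config$max_linker,
                      minDomains = config$min_domains,
                      maxDomains = config$max_domains,
                      clusterMode = config$cluster_mode)
  writeCurationReport(cohort, cur, file.path(outDir, "curation.tsv"))
  cohort <- cur$kept
  if (nProteins(cohort) == 0L)
    stop("no protein survived curation")

  cohort <- annotateCharges(cohort, conv)
  writeChargeTable(cohort, file.path(outDir, "charges.tsv"))

  cohort <- annotateSpecificity(cohort, anchor,
                                pseudocount = config$pseudocount,
                                orientation = config$orientation)
  writePropensityTable(metadata(cohort)$propensity_table,
                       file.path(outDir, "propensities.tsv"))
  writeSpecificityTable(cohort, file.path(outDir, "specificity.tsv"))

  cohort <- annotateAsymmetry(cohort, acfg)
  writeAsymmetryTable(cohort, file.path(outDir, "asymmetry.tsv"))
  pc <- pairClassifications(cohort, acfg)
  utils::write.table(pc, file.path(outDir, "pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  corMethod <- if (isTRUE(config$spearman)) "spearman" else "pearson"
  linkage <- lengthStratifiedReport(cohort,
                                    threshold = config$group_threshold,
                                    welch = isTRUE(config$welch),
                                    corMethod = corMethod)
  bins <- binMatrix(cohort, edges = config$bin_edges)
  utils::write.table(bins$counts,
                     file.path(outDir, "bin_counts.tsv"),
                     sep = "\t", quote = FALSE)
  utils::write.table(round(bins$mean_abundance, 4),
                     file.path(outDir, "bin_mean_abundance.tsv"),
                     sep = "\t", quote = FALSE)
  jsonlite::write_json(linkage, file.path(outDir, "linkage-summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  jsonlite::write_json(config[!vapply(config, is.null, logical(1))],
                       file.path(outDir, "run-metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, linkage = linkage, bins = bins,
                 out_dir = outDir))
}
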