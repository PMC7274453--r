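#' @describeIn ZFCohort-class protein-level annotation table.
#' @export
setMethod("proteins", "ZFCohort", function(x) x@proteins)

#' @describeIn ZFCohort-class replace the protein-level table.
#' @export
setReplaceMethod("proteins", "ZFCohort", function(x, value) {
  x@proteins <- value
  validObject(x)
  x
})

#' @describeIn ZFCohort-class domain-level annotation table.
#' @export
setMethod("domains", "ZFCohort", function(x) x@domains)

#' @describeIn ZFCohort-class replace the domain-level table.
#' @export
setReplaceMethod("domains", "ZFCohort", function(x, value) {
  x@domains <- value
  validObject(x)
  x
})

#' @describeIn ZFCohort-class number of proteins in the cohort.
#' @export
setMethod("nProteins", "ZFCohort", function(x) nrow(x@proteins))

#' @describeIn ZFCohort-class total number of zinc-finger domains.
#' @export
setMethod("nDomains", "ZFCohort", function(x) nrow(x@domains))

setMethod("show", "ZFCohort", function(object) {
  cat("ZFCohort with", nrow(object@proteins), "proteins and",
      nrow(object@domains), "zinc-finger domains\n")
  if (nrow(object@proteins) > 0L) {
    nd <- object@proteins$n_domains
    cat("  domains per protein:", min(nd), "-", max(nd), "\n")
    cat("  abundance set for",
        sum(!is.na(object@proteins$abundance)), "proteins\n")
    ann <- c(
      charges = "net_charge" %in% colnames(object@domains) &&
        any(!is.na(object@domains$net_charge)),
      specificity = "specificity_score" %in% colnames(object@domains) &&
        any(!is.na(object@domains$specificity_score)),
      asymmetry = any(!is.na(object@proteins$pct_asym_nonspec)) ||
        any(!is.na(object@proteins$pct_asym_spec)))
    cat("  annotations:",
        if (any(ann)) paste(names(ann)[ann], collapse = ", ") else "none",
        "\n")
  }
})

setMethod("show", "PropensityTable", function(object) {
  cat("PropensityTable:", ncol(object@prob), "columns x 21 categories,",
      object@nSequences, "sequences, pseudocount", object@pseudocount, "\n")
  cat("  helix-column maxima:\n")
  for (lab in names(object@helixColumns)) {
    cat(sprintf("    %3s (column %2d): %s = %.3f\n", lab,
                object@helixColumns[[lab]], object@pMaxResidue[[lab]],
                object@pMax[[lab]]))
  }
})

setMethod("show", "ChargeConvention", function(object) {
  cat("ChargeConvention: positive {",
      paste(object@positive, collapse = ", "), "}, negative {",
      paste(object@negative, collapse = ", "), "}\n")
})

setMethod("show", "AsymmetryConfig", function(object) {
  cat("AsymmetryConfig\n")
  cat("  non-specific: sigma >=", object@sigmaNonspec,
      "e, negative-charge threshold <", object@negChargeThreshold,
      "e, rule", object@pairRuleNonspec,
      if (object@useNormalized) "(normalized charges)" else "(raw charges)",
      "\n")
  cat("  specific: sigma >=", object@sigmaSpec,
      ", low-specificity threshold <", object@lowSpecThreshold,
      ", rule", object@pairRuleSpec, "\n")
})

setMethod("show", "TemplateAnchor", function(object) {
  cat("TemplateAnchor:", object@template, "\n")
  cat("  scaffold columns:",
      paste(object@scaffoldColumns, collapse = ", "), "\n")
  cat("  helix columns:",
      paste(sprintf("%s=%d", names(object@helixColumns),
                    object@helixColumns), collapse = ", "), "\n")
})

setMethod("show", "CohortParams", function(object) {
  cat("CohortParams:", object@nProteins, "proteins, seed", object@seed, "\n")
  cat(sprintf("  charges: pos %.1f +/- %.1f, neg %.1f +/- %.1f\n",
              object@posCountMean, object@posCountSd,
              object@negCountMean, object@negCountSd))
  cat(sprintf("  asymmetry injection: p = %.2f (net charge %g / %g)\n",
              object@pAsymProtein, object@highChargeMean,
              object@lowChargeMean))
  cat(sprintf("  abundance: exp(%.2f - %.2f * pct/100 + N(0, %.2f))\n",
              object@abundanceAlpha, object@abundanceBeta,
              object@abundanceNoiseSd))
})
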