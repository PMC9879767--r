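setMethod("show", "SummaryStats", function(object) {
  cat("SummaryStats:", object@trait, "[", object@sampleLabel, "]\n")
  cat(" ", nrow(object@records), "SNP records\n")
  if (nrow(object@records))
    print(head(object@records, 3L))
  invisible(NULL)
})

setMethod("show", "InstrumentSet", function(object) {
  cat("InstrumentSet for", object@exposure, "-", length(object@snps),
      "instruments\n")
  if (length(object@snps))
    cat(" ", paste(head(object@snps, 6L), collapse = ", "),
        if (length(object@snps) > 6L) "..." else "", "\n")
  invisible(NULL)
})

setMethod("show", "HarmonisedSet", function(object) {
  cat("HarmonisedSet:", object@exposure, "->", object@outcome, "\n")
  cat(" ", nrow(object@data), "instruments;",
      sum(object@log$action == "dropped"), "dropped during harmonisation\n")
  invisible(NULL)
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("MREstimate [%s, k = %d]: theta = %.4g (SE %.4g, 95%% CI %.4g to %.4g, p = %.3g)\n",
              object@method, object@k, object@theta, object@se,
              object@ciLow, object@ciHigh, object@pval))
  invisible(NULL)
})

setMethod("show", "HeterogeneityReport", function(object) {
  cat(sprintf("Cochran's Q = %.2f on %d df (I2 = %.2f%%, p = %.3g)\n",
              object@Q, object@df, object@I2, object@qPval))
  if (length(object@influential))
    cat("  influential SNPs (Cook's D >", format(object@cooksCutoff),
        "):", paste(object@influential, collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "MREggerFit", function(object) {
  show(object@slope)
  show(object@intercept)
  cat(sprintf("  I2_GX = %.3f%s\n", object@i2gx,
              if (object@nomeOk) "" else " (below 0.9: dilution caution)"))
  invisible(NULL)
})

setMethod("show", "MVMRResult", function(object) {
  cat("Multivariable MR on", object@k, "instruments\n")
  print(object@results)
  invisible(NULL)
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf("SimTruth: m = %d SNPs, theta = %.3g, nExposure = %d, nDuo = %d, seed = %d\n",
              object@m, object@theta, object@nExposure, object@nDuo,
              object@seed))
  invisible(NULL)
})

setMethod("show", "DuoCohort", function(object) {
  cat(sprintf("DuoCohort: %d duos x %d SNPs (realised theta on SD scale %.4g)\n",
              nrow(object@maternalGeno), ncol(object@maternalGeno),
              object@thetaStd))
  invisible(NULL)
})
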