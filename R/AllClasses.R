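#' Per-SNP GWAS summary statistics for one trait from one sample
#'
#' Container for per-variant association records (canonical columns
#' \code{SNP CHR POS EA OA EAF BETA SE Z P N}, optionally \code{N_STUDIES}),
#' one trait, one data source. Rows are unique by \code{SNP}. Effect sizes
#' (\code{BETA}) are per effect-allele copies on the trait's standard-deviation
#' scale unless noted.
#'
#' @slot trait trait name (e.g. an amino acid).
#' @slot sampleLabel data-source tag.
#' @slot records \code{data.frame} of per-SNP records.
#' @slot report load / filter report (named list of counts and reasons).
#' @exportClass SummaryStats
setClass("SummaryStats",
         representation(trait = "character", sampleLabel = "character",
                        records = "data.frame", report = "list"),
         prototype(trait = NA_character_, sampleLabel = NA_character_,
                   records = data.frame(), report = list()))

setValidity("SummaryStats", function(object) {
  rec <- object@records
  msgs <- character()
  if (nrow(rec)) {
    if (!all(c("SNP", "EA", "OA") %in% names(rec)))
      msgs <- c(msgs, "records must contain SNP, EA and OA columns")
    else {
      if (anyDuplicated(rec$SNP))
        msgs <- c(msgs, "SNP ids must be unique within a table")
      if (any(rec$EA == rec$OA, na.rm = TRUE))
        msgs <- c(msgs, "effect and other allele must differ")
    }
    if ("EAF" %in% names(rec) &&
        any(rec$EAF < 0 | rec$EAF > 1, na.rm = TRUE))
      msgs <- c(msgs, "EAF must lie in [0, 1]")
    if ("SE" %in% names(rec) && any(rec$SE <= 0, na.rm = TRUE))
      msgs <- c(msgs, "SE must be positive")
    if (all(c("BETA", "SE", "Z") %in% names(rec))) {
      ok <- stats::complete.cases(rec[, c("BETA", "SE", "Z")])
      if (any(abs(rec$Z[ok] - rec$BETA[ok] / rec$SE[ok]) > 1e-6))
        msgs <- c(msgs, "Z inconsistent with BETA/SE")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Selected genetic instruments for one exposure
#'
#' @slot exposure exposure trait name.
#' @slot snps retained instrument SNP ids (unique).
#' @slot selectionLog ordered \code{data.frame} with columns
#'   \code{snp}, \code{action}, \code{reason}; every removal is logged.
#' @exportClass InstrumentSet
setClass("InstrumentSet",
         representation(exposure = "character", snps = "character",
                        selectionLog = "data.frame"))

setValidity("InstrumentSet", function(object) {
  if (anyDuplicated(object@snps)) "instrument SNPs must be unique" else TRUE
})

#' Harmonised exposure/outcome effects per instrument
#'
#' All effects are aligned to a single effect allele per SNP (the exposure
#' table's effect allele). Ambiguous palindromic SNPs are never retained.
#'
#' @slot exposure,outcome trait names.
#' @slot data per-instrument \code{data.frame}: \code{snp}, \code{EA},
#'   \code{OA}, \code{betaExposure}, \code{seExposure}, \code{betaOutcome},
#'   \code{seOutcome}, \code{eaf} (exposure-side), \code{eafOutcome},
#'   \code{palindromic}, \code{proxySnp} (outcome proxy used, or NA).
#' @slot log harmonisation log (\code{snp}, \code{action}, \code{reason}).
#' @exportClass HarmonisedSet
setClass("HarmonisedSet",
         representation(exposure = "character", outcome = "character",
                        data = "data.frame", log = "data.frame"))

setValidity("HarmonisedSet", function(object) {
  d <- object@data
  msgs <- character()
  if (nrow(d)) {
    if (any(d$seExposure <= 0, na.rm = TRUE) ||
        any(d$seOutcome <= 0, na.rm = TRUE))
      msgs <- c(msgs, "standard errors must be positive")
    if (anyDuplicated(d$snp))
      msgs <- c(msgs, "instrument SNPs must be unique")
  }
  if (length(msgs)) msgs else TRUE
})

#' A causal-effect estimate with provenance
#'
#' @slot method one of \code{wald}, \code{ivw_mre}, \code{egger_slope},
#'   \code{egger_intercept}, \code{weighted_median}.
#' @slot theta causal effect (outcome units per exposure SD).
#' @slot se standard error.
#' @slot ciLow,ciHigh 95\% confidence bounds (normal quantiles).
#' @slot pval two-sided normal p-value.
#' @slot k number of instruments used.
#' @exportClass MREstimate
setClass("MREstimate",
         representation(method = "character", theta = "numeric",
                        se = "numeric", ciLow = "numeric", ciHigh = "numeric",
                        pval = "numeric", k = "integer"))

setValidity("MREstimate", function(object) {
  msgs <- character()
  okMethods <- c("wald", "ivw_mre", "egger_slope", "egger_intercept",
                 "weighted_median", "mvmr_ivw")
  if (!object@method %in% okMethods)
    msgs <- c(msgs, paste("unknown method:", object@method))
  if (is.finite(object@theta) &&
      !(object@ciLow <= object@theta && object@theta <= object@ciHigh))
    msgs <- c(msgs, "confidence interval must bracket the estimate")
  if (object@k < 1L) msgs <- c(msgs, "k must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Heterogeneity and influence diagnostics for an instrument set
#'
#' @slot Q Cochran's Q statistic.
#' @slot df degrees of freedom (k - 1).
#' @slot I2 percent heterogeneity, floored at 0.
#' @slot qPval chi-square upper-tail p-value for Q.
#' @slot cooks per-SNP Cook's distances (named; empty when k < 5).
#' @slot cooksCutoff influence cut-off, 4 / k.
#' @slot influential SNPs exceeding the cut-off.
#' @slot loo leave-one-out IVW estimates (one row per omitted SNP).
#' @exportClass HeterogeneityReport
setClass("HeterogeneityReport",
         representation(Q = "numeric", df = "integer", I2 = "numeric",
                        qPval = "numeric", cooks = "numeric",
                        cooksCutoff = "numeric", influential = "character",
                        loo = "data.frame"))

setValidity("HeterogeneityReport", function(object) {
  msgs <- character()
  if (is.finite(object@Q) && object@Q > 0) {
    expI2 <- max(0, 100 * (object@Q - object@df) / object@Q)
    if (abs(object@I2 - expI2) > 1e-8)
      msgs <- c(msgs, "I2 must equal max(0, 100*(Q-df)/Q)")
  }
  if (length(msgs)) msgs else TRUE
})

#' MR-Egger fit: slope, intercept and regression-dilution diagnostics
#'
#' @slot slope,intercept \code{MREstimate}s for the causal slope and the
#'   average pleiotropy intercept.
#' @slot i2gx regression-dilution statistic in [0, 1] (NOME assumption).
#' @slot nomeOk TRUE when i2gx > 0.9 (relative dilution bias < 10\%).
#' @exportClass MREggerFit
setClass("MREggerFit",
         representation(slope = "MREstimate", intercept = "MREstimate",
                        i2gx = "numeric", nomeOk = "logical"))

setValidity("MREggerFit", function(object) {
  if (object@i2gx < 0 || object@i2gx > 1) "i2gx must lie in [0, 1]" else TRUE
})

#' Joint instrument data for multivariable MR
#'
#' @slot exposures exposure names (columns of the beta matrices).
#' @slot snps instrument SNP ids after joint re-clumping.
#' @slot betaExposure,seExposure k x d matrices of per-exposure effects/SEs.
#' @slot betaOutcome,seOutcome outcome effect and SE per SNP.
#' @slot imputed logical k x d matrix flagging 0-imputed exposure betas.
#' @slot clumpR2 joint clumping threshold used.
#' @slot log processing log.
#' @exportClass MVMRInput
setClass("MVMRInput",
         representation(exposures = "character", snps = "character",
                        betaExposure = "matrix", seExposure = "matrix",
                        betaOutcome = "numeric", seOutcome = "numeric",
                        imputed = "matrix", clumpR2 = "numeric",
                        log = "data.frame"))

setValidity("MVMRInput", function(object) {
  msgs <- character()
  k <- length(object@snps); d <- length(object@exposures)
  if (!all(dim(object@betaExposure) == c(k, d)))
    msgs <- c(msgs, "betaExposure must be k x d")
  if (length(object@betaOutcome) != k)
    msgs <- c(msgs, "betaOutcome length must equal number of SNPs")
  if (length(msgs)) msgs else TRUE
})

#' Multivariable MR result
#'
#' @slot results per-exposure \code{data.frame}: \code{exposure},
#'   \code{theta}, \code{se}, \code{ciLow}, \code{ciHigh}, \code{pval},
#'   \code{conditionalF}, \code{weakFlag}.
#' @slot k number of instruments.
#' @exportClass MVMRResult
setClass("MVMRResult",
         representation(results = "data.frame", k = "integer"))

#' Generative truth of a synthetic mother-child scenario
#'
#' @slot m number of SNPs.
#' @slot maf per-SNP effect-allele frequency in (0, 1).
#' @slot gamma per-SNP effect on the standardised maternal exposure.
#' @slot theta true causal effect of the exposure on birthweight (SD units).
#' @slot phi per-SNP maternal horizontal-pleiotropy effect on birthweight.
#' @slot delta per-SNP fetal direct effect on birthweight.
#' @slot sigmaX,sigmaY residual noise SDs for exposure and birthweight.
#' @slot nExposure,nDuo sample sizes of the exposure GWAS and duo cohort.
#' @slot seed master seed (mandatory; all stages derive sub-seeds from it).
#' @exportClass SimTruth
setClass("SimTruth",
         representation(m = "integer", maf = "numeric", gamma = "numeric",
                        theta = "numeric", phi = "numeric", delta = "numeric",
                        sigmaX = "numeric", sigmaY = "numeric",
                        nExposure = "integer", nDuo = "integer",
                        seed = "integer"))

setValidity("SimTruth", function(object) {
  msgs <- character()
  m <- object@m
  if (any(object@maf <= 0 | object@maf >= 1))
    msgs <- c(msgs, "maf must lie strictly in (0, 1)")
  for (sl in c("maf", "gamma", "phi", "delta"))
    if (length(slot(object, sl)) != m)
      msgs <- c(msgs, paste(sl, "must have length m"))
  if (is.na(object@seed)) msgs <- c(msgs, "seed is mandatory")
  if (length(msgs)) msgs else TRUE
})

#' Simulated mother-child duo cohort
#'
#' Offspring genotypes are built from one allele transmitted uniformly at
#' random from the mother plus one random paternal allele, so the per-SNP
#' mother-child dosage correlation is 0.5 in expectation.
#'
#' @slot maternalGeno,childGeno n x m dosage matrices (0/1/2).
#' @slot exposure standardised maternal exposure values.
#' @slot birthweight standardised offspring birthweight values.
#' @slot snpInfo per-SNP annotation (SNP, CHR, POS, EA, OA, maf).
#' @slot truth the generating \code{SimTruth}.
#' @slot thetaStd realised causal effect on the standardised scales
#'   (theta * sd(X_raw) / sd(Y_raw)).
#' @exportClass DuoCohort
setClass("DuoCohort",
         representation(maternalGeno = "matrix", childGeno = "matrix",
                        exposure = "numeric", birthweight = "numeric",
                        snpInfo = "data.frame", truth = "SimTruth",
                        thetaStd = "numeric"))
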