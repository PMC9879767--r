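#' Define the generative truth of a synthetic mother-child scenario
#'
#' Parameters of the data-generating model: maternal genotypes act on a
#' standardised maternal exposure through per-SNP effects \code{gamma};
#' offspring birthweight receives the causal effect \code{theta} of the
#' exposure, maternal horizontal pleiotropy \code{phi}, a fetal direct
#' effect \code{delta} per transmitted genotype, and Gaussian noise.
#' Defaults give 15 strong, unlinked instruments (mean F well above 100 at
#' the default sample sizes, which mirror the source GWAS scale: 80,000
#' for the exposure, 100,000 mother-child duos).
#'
#' @param m number of SNPs.
#' @param maf per-SNP effect-allele frequencies in (0, 1); default an
#'   even spread over 0.1-0.5.
#' @param gamma per-SNP exposure effects (SD units); default an even
#'   spread over 0.06-0.12.
#' @param theta true causal effect, SD birthweight per SD exposure
#'   (default 0.12).
#' @param phi per-SNP maternal pleiotropy (default 0).
#' @param delta per-SNP fetal direct effect (default 0).
#' @param sigmaX,sigmaY residual SDs; by default chosen so the exposure
#'   and birthweight have approximately unit variance.
#' @param nExposure,nDuo sample sizes.
#' @param seed mandatory master seed.
#' @return \code{SimTruth}.
#' @export
simTruth <- function(m = 15L, maf = NULL, gamma = NULL, theta = 0.12,
                     phi = NULL, delta = NULL, sigmaX = NULL,
                     sigmaY = NULL, nExposure = 80000L, nDuo = 100000L,
                     seed) {
  if (missing(seed)) stop("seed is mandatory")
  m <- as.integer(m)
  if (is.null(maf)) maf <- seq(0.1, 0.5, length.out = m)
  if (is.null(gamma)) gamma <- seq(0.06, 0.12, length.out = m)
  if (is.null(phi)) phi <- rep(0, m)
  if (is.null(delta)) delta <- rep(0, m)
  gVarX <- sum(2 * maf * (1 - maf) * gamma^2)
  if (is.null(sigmaX)) sigmaX <- sqrt(max(0.05, 1 - gVarX))
  if (is.null(sigmaY)) sigmaY <- sqrt(max(0.05, 1 - theta^2))
  new("SimTruth", m = m, maf = maf, gamma = gamma, theta = theta,
      phi = phi, delta = delta, sigmaX = sigmaX, sigmaY = sigmaY,
      nExposure = as.integer(nExposure), nDuo = as.integer(nDuo),
      seed = as.integer(seed))
}

#' Preset study scenarios for the simulator
#'
#' Fixed scenario definitions used throughout the test and calibration
#' suite:
#' \describe{
#'   \item{null}{no causal effect (theta = 0), 15 instruments.}
#'   \item{causal}{theta = 0.12 SD, 15 strong instruments.}
#'   \item{balanced-pleiotropy}{theta = 0.12, 100 equal-precision
#'     instruments with zero-mean pleiotropy phi ~ N(0, 0.01) drawn once
#'     from the seed; the large-k, homoscedastic regime in which the
#'     package's normal-approximation inference and multiplicative
#'     heterogeneity model are calibrated.}
#'   \item{directional-pleiotropy}{theta = 0.12, 20 instruments; a subset
#'     carrying about 30\% of the inverse-variance weight has
#'     phi = +0.03 (directional, mean > 0).}
#'   \item{fetal-effect}{theta = 0.12, delta = 0.1 on every SNP, phi = 0:
#'     the exclusion-restriction threat that maternal-effect
#'     partitioning is designed to remove.}
#' }
#'
#' @param name scenario name.
#' @param seed master seed.
#' @return \code{SimTruth}.
#' @export
mrScenario <- function(name = c("null", "causal", "balanced-pleiotropy",
                                "directional-pleiotropy", "fetal-effect"),
                       seed) {
  name <- match.arg(name)
  if (missing(seed)) stop("seed is mandatory")
  switch(name,
    "null" = simTruth(m = 15L, theta = 0, seed = seed),
    "causal" = simTruth(m = 15L, theta = 0.12, seed = seed),
    "balanced-pleiotropy" = {
      # equal-precision instruments (constant maf, hence constant outcome
      # SE): the regime in which the multiplicative heterogeneity model
      # behind the Egger SEs is correctly specified
      m <- 100L
      old <- .Random.seed.exists()
      set.seed(deriveSeed(seed, 3L))
      phi <- rnorm(m, 0, 0.01)
      restoreSeed(old)
      simTruth(m = m, maf = rep(0.3, m),
               gamma = rep(seq(0.06, 0.12, length.out = 20L), 5L),
               theta = 0.12, phi = phi, seed = seed)
    },
    "directional-pleiotropy" = {
      m <- 20L
      # invalid subset chosen so it carries ~30% of the IVW weight
      # (weights scale with gamma^2 * 2 maf (1 - maf))
      phi <- rep(0, m)
      phi[c(3L, 8L, 13L, 18L, 20L)] <- 0.03
      simTruth(m = m, maf = seq(0.1, 0.5, length.out = m),
               gamma = seq(0.06, 0.12, length.out = m),
               theta = 0.12, phi = phi, seed = seed)
    },
    "fetal-effect" = simTruth(m = 15L, theta = 0.12,
                              delta = rep(0.1, 15L), seed = seed))
}

snpAnnotation <- function(truth) {
  j <- seq_len(truth@m)
  data.frame(SNP = paste0("rs", 1000L + j),
             CHR = as.character(((j - 1L) %% 22L) + 1L),
             POS = 1e6 * (1 + (j - 1L) %/% 22L) + 50000 * j,
             EA = "A", OA = "G", maf = truth@maf,
             stringsAsFactors = FALSE)
}

#' Simulate a mother-child duo cohort
#'
#' Maternal genotypes are Binomial(2, maf) under Hardy-Weinberg; each
#' offspring receives one allele drawn uniformly from the mother's two
#' plus one Bernoulli(maf) paternal allele (random mating), giving the
#' expected mother-child dosage correlation of 0.5 per SNP. The exposure
#' and birthweight are generated per the truth parameters and
#' standardised; the realised causal effect on the standardised scale is
#' recorded as \code{thetaStd}.
#'
#' @param truth \code{SimTruth}.
#' @param n cohort size (default \code{truth@nDuo}).
#' @param seed optional override of the truth's seed (to draw independent
#'   cohorts from the same truth).
#' @return \code{DuoCohort}.
#' @export
simulateDuos <- function(truth, n = NULL, seed = NULL) {
  stopifnot(is(truth, "SimTruth"))
  validObject(truth)
  if (is.null(n)) n <- truth@nDuo
  if (is.null(seed)) seed <- truth@seed
  m <- truth@m
  old <- .Random.seed.exists()
  set.seed(deriveSeed(seed, 1L))
  Gm <- sapply(truth@maf, function(p) rbinom(n, 2L, p))
  transmitted <- matrix(rbinom(n * m, 1L, as.vector(Gm) / 2), n, m)
  paternal <- sapply(truth@maf, function(p) rbinom(n, 1L, p))
  Gc <- transmitted + paternal
  Xraw <- as.vector(Gm %*% truth@gamma) + rnorm(n, 0, truth@sigmaX)
  Yraw <- truth@theta * Xraw + as.vector(Gm %*% truth@phi) +
    as.vector(Gc %*% truth@delta) + rnorm(n, 0, truth@sigmaY)
  restoreSeed(old)
  info <- snpAnnotation(truth)
  colnames(Gm) <- colnames(Gc) <- info$SNP
  sx <- sd(Xraw); sy <- sd(Yraw)
  new("DuoCohort", maternalGeno = Gm, childGeno = Gc,
      exposure = (Xraw - mean(Xraw)) / sx,
      birthweight = (Yraw - mean(Yraw)) / sy,
      snpInfo = info, truth = truth,
      thetaStd = truth@theta * sx / sy)
}

#' Per-SNP GWAS of a phenotype on dosage columns
#'
#' Simple linear regression of the phenotype on each SNP's dosage:
#' slope, SE, z, p, effect-allele frequency and n per SNP. Monomorphic
#' SNPs are dropped with a reason in the report.
#'
#' @param dosages n x m dosage matrix (columns named by SNP) or a
#'   \code{DuoCohort}.
#' @param phenotype numeric phenotype vector; for a \code{DuoCohort}, one
#'   of \code{"exposure"} or \code{"birthweight"}.
#' @param genotypes for a \code{DuoCohort}: \code{"maternal"} or
#'   \code{"child"}.
#' @param trait,sampleLabel metadata for the resulting table.
#' @param snpInfo optional per-SNP annotation (SNP, CHR, POS, EA, OA).
#' @return \code{SummaryStats}.
#' @export
gwasScan <- function(dosages, phenotype, genotypes = "maternal",
                     trait = "trait", sampleLabel = "simulated",
                     snpInfo = NULL) {
  if (is(dosages, "DuoCohort")) {
    cohort <- dosages
    snpInfo <- cohort@snpInfo
    phenoName <- match.arg(phenotype, c("exposure", "birthweight"))
    phenotype <- slot(cohort, phenoName)
    dosages <- if (match.arg(genotypes, c("maternal", "child")) ==
                   "maternal") cohort@maternalGeno else cohort@childGeno
    if (identical(trait, "trait")) trait <- phenoName
  }
  g <- as.matrix(dosages)
  n <- nrow(g)
  stopifnot(n >= 100L, length(phenotype) == n)
  if (is.null(colnames(g))) colnames(g) <- paste0("snp", seq_len(ncol(g)))
  yc <- phenotype - mean(phenotype)
  gm <- colMeans(g)
  sxx <- colSums(g^2) - n * gm^2
  mono <- sxx <= 0
  sxy <- as.vector(crossprod(g, yc))
  beta <- sxy / sxx
  rss <- sum(yc^2) - beta^2 * sxx
  seb <- sqrt(rss / (n - 2) / sxx)
  res <- data.frame(SNP = colnames(g), EAF = gm / 2, BETA = beta,
                    SE = seb, N = n, stringsAsFactors = FALSE)
  if (!is.null(snpInfo)) {
    idx <- match(res$SNP, snpInfo$SNP)
    res$CHR <- snpInfo$CHR[idx]; res$POS <- snpInfo$POS[idx]
    res$EA <- snpInfo$EA[idx]; res$OA <- snpInfo$OA[idx]
  } else { res$EA <- "A"; res$OA <- "G" }
  res <- res[!mono, , drop = FALSE]
  out <- sumstats(res, trait = trait, sampleLabel = sampleLabel)
  out@report$monomorphicDropped <- sum(mono)
  out
}

#' Partition maternal and fetal genetic effects by the weighted linear model
#'
#' Own-birthweight GWAS estimates (individuals' birthweight on their own
#' genotype) mix the fetal direct effect with half the maternal effect,
#' and offspring-birthweight estimates (offspring birthweight on maternal
#' genotype) mix the maternal effect with half the fetal effect, because
#' half of the maternal genotype is transmitted. Solving the expectation
#' system \code{E[bOwn] = bf + bm/2}, \code{E[bOff] = bm + bf/2} gives the
#' adjusted effects \code{bm = (4 bOff - 2 bOwn) / 3} and
#' \code{bf = (4 bOwn - 2 bOff) / 3}; SEs are propagated assuming
#' disjoint samples (zero covariance).
#'
#' @param betaOwn,seOwn own-genotype GWAS effect and SE per SNP.
#' @param betaOffspring,seOffspring maternal-genotype GWAS effect and SE.
#' @return list of two data.frames, \code{maternal} and \code{fetal}, each
#'   with adjusted \code{beta} and \code{se}.
#' @examples
#' wlmPartition(0.1, 0.01, 0.05, 0.01)$maternal$beta  # 0: pure fetal effect
#' @export
wlmPartition <- function(betaOwn, seOwn, betaOffspring, seOffspring) {
  list(
    maternal = data.frame(
      beta = (4 * betaOffspring - 2 * betaOwn) / 3,
      se = sqrt(16 * seOffspring^2 + 4 * seOwn^2) / 3),
    fetal = data.frame(
      beta = (4 * betaOwn - 2 * betaOffspring) / 3,
      se = sqrt(16 * seOwn^2 + 4 * seOffspring^2) / 3))
}

#' Maternal-adjusted outcome table from own and offspring GWAS
#'
#' Applies \code{\link{wlmPartition}} SNP-wise to two aligned
#' \code{SummaryStats} tables and returns the maternal-effect-adjusted
#' outcome table (the estimates a maternal-exposure MR should use).
#'
#' @param own \code{SummaryStats} of the own-genotype birthweight GWAS.
#' @param offspring \code{SummaryStats} of the maternal-genotype GWAS.
#' @return \code{SummaryStats} of WLM-adjusted maternal effects.
#' @export
wlmAdjust <- function(own, offspring) {
  ro <- records(own); rf <- records(offspring)
  shared <- intersect(ro$SNP, rf$SNP)
  ro <- ro[match(shared, ro$SNP), ]; rf <- rf[match(shared, rf$SNP), ]
  stopifnot(all(ro$EA == rf$EA), all(ro$OA == rf$OA))
  adj <- wlmPartition(ro$BETA, ro$SE, rf$BETA, rf$SE)$maternal
  out <- rf
  out$BETA <- adj$beta; out$SE <- adj$se
  out$Z <- out$BETA / out$SE; out$P <- zToP(out$Z)
  sumstats(out, trait = trait(offspring),
           sampleLabel = "wlm_adjusted_maternal")
}

#' Draw summary statistics directly from their sampling distributions
#'
#' Fast path for replicate-heavy calibration: per-SNP estimates are drawn
#' from normal distributions centred on the analytic expectations implied
#' by the truth, with analytic standard errors at the stated sample sizes
#' (\code{se = 1 / sqrt(2 maf (1 - maf) n)} for a standardised trait).
#' The outcome side draws the own-genotype and maternal-genotype
#' birthweight GWAS independently (disjoint samples) and returns both the
#' WLM-adjusted maternal table and the unadjusted maternal-genotype table.
#'
#' @param truth \code{SimTruth}.
#' @param seed optional override of the truth's seed.
#' @return list with \code{exposure}, \code{outcome} (WLM-adjusted
#'   maternal), \code{outcomeUnadjusted} (raw maternal-genotype GWAS) and
#'   \code{truth}.
#' @export
simulateSumstatsDirect <- function(truth, seed = NULL) {
  stopifnot(is(truth, "SimTruth"))
  validObject(truth)
  if (is.null(seed)) seed <- truth@seed
  info <- snpAnnotation(truth)
  het <- 2 * truth@maf * (1 - truth@maf)
  seExp <- 1 / sqrt(het * truth@nExposure)
  seOwn <- seOff <- 1 / sqrt(het * truth@nDuo)
  bm <- truth@theta * truth@gamma + truth@phi   # maternal effect
  bf <- truth@delta                             # fetal direct effect
  old <- .Random.seed.exists()
  set.seed(deriveSeed(seed, 2L))
  bx <- rnorm(truth@m, truth@gamma, seExp)
  bOwn <- rnorm(truth@m, bf + bm / 2, seOwn)
  bOff <- rnorm(truth@m, bm + bf / 2, seOff)
  restoreSeed(old)
  mkTab <- function(beta, sev, trait, label, n) {
    sumstats(data.frame(info[, c("SNP", "CHR", "POS", "EA", "OA")],
                        EAF = truth@maf, BETA = beta, SE = sev,
                        N = n, stringsAsFactors = FALSE),
             trait = trait, sampleLabel = label)
  }
  adj <- wlmPartition(bOwn, seOwn, bOff, seOff)$maternal
  list(exposure = mkTab(bx, seExp, "exposure", "simulated_exposure",
                        truth@nExposure),
       outcome = mkTab(adj$beta, adj$se, "birthweight",
                       "wlm_adjusted_maternal", truth@nDuo),
       outcomeUnadjusted = mkTab(bOff, seOff, "birthweight",
                                 "unadjusted_maternal", truth@nDuo),
       truth = truth)
}

#' Pairwise LD table from dosage columns
#'
#' Squared Pearson correlation of dosage columns, emitted in the long
#' \code{SNP_A SNP_B R2} dialect consumed by the clumping functions.
#' Monomorphic SNPs contribute no pairs and are flagged.
#'
#' @param dosages n x m dosage matrix with SNP column names.
#' @return data.frame \code{SNP_A}, \code{SNP_B}, \code{R2} (upper
#'   triangle), with attribute \code{"monomorphic"}.
#' @export
makeLDTable <- function(dosages) {
  g <- as.matrix(dosages)
  stopifnot(ncol(g) >= 2L)
  if (is.null(colnames(g))) colnames(g) <- paste0("snp", seq_len(ncol(g)))
  v <- apply(g, 2L, var)
  mono <- names(v)[v == 0]
  gg <- g[, v > 0, drop = FALSE]
  r2 <- cor(gg)^2
  idx <- which(upper.tri(r2), arr.ind = TRUE)
  out <- data.frame(SNP_A = rownames(r2)[idx[, 1L]],
                    SNP_B = colnames(r2)[idx[, 2L]],
                    R2 = r2[idx], stringsAsFactors = FALSE)
  attr(out, "monomorphic") <- mono
  out
}
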