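# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except where a test exercises the readers.

# HarmonisedSet straight from a pair of already-aligned simulated tables
# (the simulator emits every SNP on the same effect allele).
hsFromSim <- function(sim) {
  ex <- records(sim$exposure)
  ou <- records(sim$outcome)
  harmonisedSet(ex$BETA, ex$SE, ou$BETA, ou$SE, snp = ex$SNP, eaf = ex$EAF)
}

hsFromTables <- function(exposure, outcome) {
  ex <- records(exposure)
  ou <- records(outcome)
  idx <- match(ex$SNP, ou$SNP)
  harmonisedSet(ex$BETA, ex$SE, ou$BETA[idx], ou$SE[idx],
                snp = ex$SNP, eaf = ex$EAF)
}

# Generic weighted-least-squares oracle via base lm(); returns estimates,
# model SEs and the residual scale so tests can reapply the floor-at-1
# convention independently of the package's own algebra.
wlsOracle <- function(y, X, w, intercept = FALSE) {
  df <- data.frame(y = y, X)
  form <- if (intercept) y ~ . else y ~ . + 0
  fit <- lm(form, data = df, weights = w)
  sm <- summary(fit)
  list(coef = coef(fit), se = sm$coefficients[, "Std. Error"],
       sigma = sm$sigma)
}

# Instrument-accounting fixture mirroring the published selection pipeline:
# 112 metabolome-wide significant candidates, 2 removed at the stringent
# clumping stage (110 left), 5 of those absent from the outcome GWAS with
# proxies for 4 (rs142714816 unproxied), and 3 ambiguous palindromic SNPs
# with MAF 0.42 / 0.44 / 0.48 removed during harmonisation (106 left).
makeAccountingFixture <- function() {
  missingSnps <- c("rs8061221", "rs4253272", "rs1065853", "rs72661853",
                   "rs142714816")
  proxySnps <- c("rs7187819", "rs4253282", "rs7412", "rs112748538")
  palSnps <- c("rs28601761", "rs2422358", "rs1935")
  palEAF <- c(0.42, 0.44, 0.48)
  nGeneric <- 112 - length(missingSnps) - length(palSnps) - 4
  genericSnps <- paste0("rsg", seq_len(nGeneric))
  # two loci where the stringent r2 < 0.01 stage removes one SNP each
  clumpPairs <- c("rs_keepA", "rs_dropA", "rs_keepB", "rs_dropB")

  allSnps <- c(genericSnps, missingSnps, palSnps, clumpPairs)
  n <- length(allSnps)
  stopifnot(n == 112)
  ex <- data.frame(
    SNP = allSnps,
    CHR = c(rep("sep", n - 4), "2", "2", "3", "3"),  # generics unlinked
    POS = c(seq_len(n - 4) * 1e6, 5e7, 5.2e7, 6e7, 6.3e7),
    EA = "A", OA = "G", EAF = 0.2,
    BETA = 0.1, SE = 0.012, N = 86507,
    P = c(rep(1e-15, n - 4), 1e-20, 1e-12, 1e-19, 1e-13),
    stringsAsFactors = FALSE)
  ex$CHR[ex$CHR == "sep"] <- paste0("c", seq_len(n - 4))
  pal <- match(palSnps, ex$SNP)
  ex$EA[pal] <- c("A", "C", "A"); ex$OA[pal] <- c("T", "G", "T")
  ex$EAF[pal] <- palEAF
  exposure <- sumstats(ex, trait = "aminoacid", sampleLabel = "gwas")

  # outcome: everything except the 5 missing SNPs, plus the 4 proxies
  ou <- ex[!ex$SNP %in% missingSnps, ]
  proxyRows <- ou[seq_along(proxySnps), ]
  proxyRows$SNP <- proxySnps
  proxyRows$CHR <- paste0("p", seq_along(proxySnps))
  ou <- rbind(ou, proxyRows)
  ou$BETA <- 0.01; ou$SE <- 0.005; ou$N <- 406063
  outcome <- sumstats(ou, trait = "birthweight", sampleLabel = "wlm")

  ld <- data.frame(SNP_A = c("rs_keepA", "rs_keepB"),
                   SNP_B = c("rs_dropA", "rs_dropB"),
                   R2 = c(0.5, 0.04),    # both >= the stringent 0.01 cut
                   stringsAsFactors = FALSE)
  proxies <- data.frame(
    TARGET = c(missingSnps[1:4], "rs142714816"),
    PROXY = c(proxySnps, "rs_low_ld"),
    R2 = c(0.95, 0.9, 0.85, 0.82, 0.6),   # last one below the 0.8 rule
    stringsAsFactors = FALSE)
  list(exposure = exposure, outcome = outcome, ld = ld, proxies = proxies)
}
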