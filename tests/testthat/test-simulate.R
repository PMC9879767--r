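test_that("truth objects validate their parameters and require a seed", {
  expect_error(simTruth(), "seed")
  tr <- simTruth(seed = 1)
  expect_s4_class(tr, "SimTruth")
  expect_equal(tr@m, 15L)
  expect_error(simTruth(maf = rep(1.2, 15), seed = 1), "maf")
  expect_error(simTruth(gamma = 1:3, seed = 1), "length")
  # scenario presets
  expect_equal(mrScenario("null", seed = 1)@theta, 0)
  expect_equal(mrScenario("fetal-effect", seed = 1)@delta, rep(0.1, 15))
  dir <- mrScenario("directional-pleiotropy", seed = 1)
  expect_gt(mean(dir@phi), 0)
  bal <- mrScenario("balanced-pleiotropy", seed = 1)
  expect_equal(mean(bal@phi), 0, tolerance = 0.01)
  # phi is a deterministic function of the seed
  expect_identical(bal@phi, mrScenario("balanced-pleiotropy", seed = 1)@phi)
})

test_that("duo simulation respects transmission genetics", {
  tr <- simTruth(m = 6L, seed = 99)
  duo <- simulateDuos(tr, n = 60000)
  Gm <- duo@maternalGeno; Gc <- duo@childGeno
  expect_true(all(Gm %in% 0:2) && all(Gc %in% 0:2))
  # per-SNP mother-child dosage correlation approaches 0.5
  rr <- vapply(seq_len(ncol(Gm)), function(j) cor(Gm[, j], Gc[, j]), 0)
  expect_equal(rr, rep(0.5, 6), tolerance = 0.03)
  # allele frequencies match the truth
  expect_equal(colMeans(Gm) / 2, tr@maf, tolerance = 0.02,
               ignore_attr = TRUE)
  expect_equal(colMeans(Gc) / 2, tr@maf, tolerance = 0.02,
               ignore_attr = TRUE)
  # phenotypes are standardised
  expect_equal(sd(duo@exposure), 1, tolerance = 1e-12)
  expect_equal(sd(duo@birthweight), 1, tolerance = 1e-12)
  # reproducible from the seed
  duo2 <- simulateDuos(tr, n = 60000)
  expect_identical(duo@maternalGeno, duo2@maternalGeno)
  expect_identical(duo@birthweight, duo2@birthweight)
  # a different cohort seed draws an independent sample
  duo3 <- simulateDuos(tr, n = 60000, seed = 100)
  expect_false(identical(duo@maternalGeno, duo3@maternalGeno))
})

test_that("null-model association statistics are standard normal", {
  tr <- simTruth(m = 40L, maf = rep(0.3, 40), gamma = rep(0, 40),
                 theta = 0, seed = 5, nDuo = 4000L)
  duo <- simulateDuos(tr, n = 4000)
  gw <- gwasScan(duo, "birthweight", "maternal")
  z <- records(gw)$Z
  expect_equal(mean(z), 0, tolerance = 3 / sqrt(40))
  expect_equal(sd(z), 1, tolerance = 0.35)
  expect_lt(mean(records(gw)$P < 0.05), 0.20)
})

test_that("gwasScan matches the per-SNP least-squares oracle", {
  set.seed(41)
  n <- 500
  g <- cbind(a = rbinom(n, 2, 0.4), b = rbinom(n, 2, 0.2),
             mono = rep(1, n))
  y <- 0.3 * g[, "a"] + rnorm(n)
  gw <- gwasScan(g, y)
  rec <- records(gw)
  expect_false("mono" %in% rec$SNP)           # monomorphic dropped
  expect_equal(gw@report$monomorphicDropped, 1L)
  for (s in c("a", "b")) {
    fit <- summary(lm(y ~ g[, s]))$coefficients
    expect_equal(rec$BETA[rec$SNP == s], fit[2, "Estimate"],
                 tolerance = 1e-10)
    expect_equal(rec$SE[rec$SNP == s], fit[2, "Std. Error"],
                 tolerance = 1e-10)
  }
  expect_equal(rec$EAF, colMeans(g[, 1:2]) / 2, ignore_attr = TRUE)
  # a phenotype equal to a dosage column regresses to slope 1, tiny SE
  gw2 <- gwasScan(g[, 1:2], g[, "a"] + rnorm(n, 0, 1e-8))
  expect_equal(records(gw2)$BETA[1], 1, tolerance = 1e-6)
  expect_lt(records(gw2)$SE[1], 1e-8)
})

test_that("WLM partition solves the transmission expectation system", {
  # pure fetal effect: maternal-adjusted beta is exactly zero
  p <- wlmPartition(0.1, 0.01, 0.05, 0.01)
  expect_equal(p$maternal$beta, 0)
  expect_equal(p$fetal$beta, 0.1)
  # symmetric case
  p2 <- wlmPartition(0.1, 0.01, 0.1, 0.01)
  expect_equal(p2$maternal$beta, 0.2 / 3)
  expect_equal(p2$fetal$beta, 0.2 / 3)
  # null in, null out
  p3 <- wlmPartition(0, 0.01, 0, 0.01)
  expect_equal(p3$maternal$beta, 0)
  expect_equal(p3$fetal$beta, 0)
  # SE propagation under the zero-covariance assumption
  expect_equal(p$maternal$se, sqrt(16 * 0.01^2 + 4 * 0.01^2) / 3)
  # the partition inverts the mixing exactly: round trip through the
  # expectation system recovers any (maternal, fetal) pair
  bm <- 0.07; bf <- -0.03
  p4 <- wlmPartition(bf + bm / 2, 0.01, bm + bf / 2, 0.01)
  expect_equal(p4$maternal$beta, bm, tolerance = 1e-12)
  expect_equal(p4$fetal$beta, bf, tolerance = 1e-12)
})

test_that("wlmAdjust recovers maternal effects from duo GWAS tables", {
  # with a fetal direct effect, the maternal-genotype GWAS is contaminated
  # by transmission; the WLM-adjusted table centres on the true maternal
  # effect
  tr <- simTruth(m = 8L, maf = rep(0.3, 8), gamma = rep(0.1, 8),
                 theta = 0.1, delta = rep(0.15, 8), seed = 13,
                 nDuo = 60000L)
  duo <- simulateDuos(tr)
  own <- gwasScan(duo, "birthweight", "child")
  off <- gwasScan(duo, "birthweight", "maternal")
  adj <- wlmAdjust(own, off)
  bm <- tr@theta * tr@gamma + tr@phi      # truth on the raw scale
  resid <- records(adj)$BETA - bm * duo@thetaStd / tr@theta
  expect_lt(mean(abs(resid)), 3 * mean(records(adj)$SE))
  # whereas the unadjusted maternal GWAS is shifted by delta / 2
  residRaw <- records(off)$BETA - bm * duo@thetaStd / tr@theta
  expect_gt(mean(residRaw), 2 * mean(records(off)$SE))
})

test_that("direct summary-statistic draws have the stated moments", {
  tr <- simTruth(m = 10L, seed = 17)
  s1 <- simulateSumstatsDirect(tr)
  s2 <- simulateSumstatsDirect(tr)
  expect_identical(records(s1$exposure), records(s2$exposure))  # seeded
  # doubling n shrinks the analytic SE by sqrt(2)
  tr2 <- simTruth(m = 10L, nExposure = 160000L, seed = 17)
  sBig <- simulateSumstatsDirect(tr2)
  expect_equal(records(s1$exposure)$SE / records(sBig$exposure)$SE,
               rep(sqrt(2), 10))
  # replicate means approach the generative truth
  reps <- vapply(1:300, function(r) {
    records(simulateSumstatsDirect(tr, seed = deriveSeed(17, r))$exposure)$BETA
  }, numeric(10))
  mcse <- apply(reps, 1, sd) / sqrt(300)
  expect_true(all(abs(rowMeans(reps) - tr@gamma) < 3 * mcse + 1e-4))
  # outcome expectation: maternal effect theta * gamma + phi
  repsO <- vapply(1:300, function(r) {
    records(simulateSumstatsDirect(tr, seed = deriveSeed(17, r))$outcome)$BETA
  }, numeric(10))
  mcseO <- apply(repsO, 1, sd) / sqrt(300)
  expect_true(all(abs(rowMeans(repsO) - tr@theta * tr@gamma) <
                  3 * mcseO + 1e-4))
})

test_that("LD tables reflect the dosage correlation structure", {
  set.seed(44)
  n <- 2000
  a <- rbinom(n, 2, 0.3)
  g <- cbind(s1 = a, s2 = a,                     # perfect LD
             s3 = rbinom(n, 2, 0.3),             # independent
             s4 = pmin(2, pmax(0, a + rbinom(n, 1, 0.2))),  # block partner
             mono = rep(0, n))
  ld <- makeLDTable(g)
  expect_equal(attr(ld, "monomorphic"), "mono")
  getR2 <- function(x, y) ld$R2[(ld$SNP_A == x & ld$SNP_B == y) |
                                (ld$SNP_A == y & ld$SNP_B == x)]
  expect_equal(getR2("s1", "s2"), 1)
  expect_lt(getR2("s1", "s3"), 0.05)
  expect_gt(getR2("s1", "s4"), 0.3)
  # feeds clumping in the canonical dialect
  expect_named(ld, c("SNP_A", "SNP_B", "R2"))
})

test_that("restricting to pleiotropy-free instruments removes the bias", {
  # the conservative-set rationale: under directional pleiotropy, an MR
  # restricted to instruments with no direct outcome pathway is unbiased
  # while the full set is not
  tr <- mrScenario("directional-pleiotropy", seed = 88)
  rs <- replicateSeeds(88, 150, stream = 5L)
  fullEst <- consEst <- numeric(150)
  valid <- which(tr@phi == 0)
  for (r in 1:150) {
    sim <- simulateSumstatsDirect(tr, seed = rs[r])
    ex <- records(sim$exposure); ou <- records(sim$outcome)
    h <- harmonisedSet(ex$BETA, ex$SE, ou$BETA, ou$SE, snp = ex$SNP)
    fullEst[r] <- theta(mrIVW(h))
    d <- harmonisedData(h)[valid, ]
    consEst[r] <- theta(mrIVW(d))
  }
  mc <- sd(consEst) / sqrt(150)
  expect_lt(abs(mean(consEst) - 0.12), 3 * mc)
  expect_gt(abs(mean(fullEst) - 0.12), 10 * sd(fullEst) / sqrt(150))
})

test_that("the causal scenario is recovered end-to-end from a duo cohort", {
  # full pipeline on raw individual-level data: exposure GWAS in one
  # cohort of mothers, duo outcome GWAS in another, WLM adjustment,
  # harmonisation, IVW
  tr <- simTruth(m = 12L, maf = rep(0.3, 12),
                 gamma = rep(0.12, 12), theta = 0.12,
                 nExposure = 30000L, nDuo = 30000L, seed = 55)
  expCohort <- simulateDuos(tr, n = 30000, seed = 56)
  outCohort <- simulateDuos(tr, n = 30000, seed = 57)
  expGwas <- gwasScan(expCohort, "exposure", "maternal")
  adj <- wlmAdjust(gwasScan(outCohort, "birthweight", "child"),
                   gwasScan(outCohort, "birthweight", "maternal"))
  hs <- harmonise(expGwas, adj)
  expect_equal(nInstruments(hs), 12L)
  est <- mrIVW(hs)
  target <- outCohort@thetaStd / sd(expCohort@exposure) *
    1                                    # both phenotypes standardised
  expect_lt(abs(theta(est) - target), 3 * se(est))
})
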