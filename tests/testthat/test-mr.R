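test_that("Wald ratio follows the delta method", {
  # identity instrument
  e1 <- waldRatio(1, 0.1, 0.07, 0.03)
  expect_equal(theta(e1), 0.07)
  expect_equal(se(e1), 0.03)
  # hand delta-method evaluation
  e2 <- waldRatio(0.1, 0.01, 0.005, 0.002)
  expect_equal(theta(e2), 0.05)
  expect_equal(se(e2), 0.02)
  # negating the exposure effect negates theta, se unchanged
  e3 <- waldRatio(-0.1, 0.01, 0.005, 0.002)
  expect_equal(theta(e3), -0.05)
  expect_equal(se(e3), 0.02)
  expect_error(waldRatio(0, 0.01, 0.1, 0.01), "zero")
})

test_that("IVW reproduces the hand-worked weighted regression", {
  hs <- harmonisedSet(c(1, 1), c(0.01, 0.01), c(0.1, 0.3), c(0.1, 0.1))
  est <- mrIVW(hs)
  expect_equal(theta(est), 0.2)
  # fixed-effect se 1/sqrt(200); Q = 2 so the multiplicative scale is sqrt(2)
  expect_equal(se(est), sqrt(1 / 200) * sqrt(2))
  expect_equal(se(mrIVW(hs, reFloor = FALSE)), sqrt(1 / 200) * sqrt(2))
  # homogeneous instruments: floor keeps the fixed-effect SE
  hs2 <- harmonisedSet(c(1, 2), c(0.01, 0.01), c(0.2, 0.4), c(0.1, 0.1))
  expect_equal(se(mrIVW(hs2)), sqrt(1 / sum(c(1, 4) / 0.01)))
  # k = 1 forced through equals the Wald ratio
  hs1 <- harmonisedSet(0.1, 0.01, 0.005, 0.002)
  e1 <- mrIVW(hs1, allowSingle = TRUE)
  expect_equal(theta(e1), 0.05)
  expect_equal(se(e1), 0.02)
  expect_error(mrIVW(hs1), "waldRatio")
})

test_that("IVW and MR-Egger agree with a generic WLS oracle", {
  set.seed(101)
  for (i in 1:25) {
    k <- sample(5:15, 1)
    bx <- abs(rnorm(k, 0.1, 0.05)) + 0.02
    by <- 0.2 * bx + rnorm(k, 0, 0.02)
    sy <- runif(k, 0.01, 0.05)
    sx <- runif(k, 0.002, 0.01)
    hs <- harmonisedSet(bx, sx, by, sy)
    w <- 1 / sy^2
    # IVW: through-origin WLS; model SE rescaled to the floored convention
    o <- wlsOracle(by, data.frame(bx = bx), w)
    est <- mrIVW(hs)
    expect_equal(theta(est), unname(o$coef), tolerance = 1e-10)
    expect_equal(se(est), unname(o$se / o$sigma * max(1, o$sigma)),
                 tolerance = 1e-10)
    # Egger: WLS with intercept (bx already positive)
    oe <- wlsOracle(by, data.frame(bx = bx), w, intercept = TRUE)
    eg <- mrEgger(hs)
    expect_equal(theta(eg@slope), unname(oe$coef["bx"]), tolerance = 1e-10)
    expect_equal(theta(eg@intercept), unname(oe$coef["(Intercept)"]),
                 tolerance = 1e-10)
    expect_equal(se(eg@slope),
                 unname(oe$se["bx"] / oe$sigma * max(1, oe$sigma)),
                 tolerance = 1e-10)
  }
})

test_that("Cochran's Q, I2 and the q p-value behave per the formulas", {
  # identical ratios: no heterogeneity
  hs <- harmonisedSet(c(1, 2, 4), c(0.01, 0.01, 0.01),
                      c(0.1, 0.2, 0.4), c(0.1, 0.1, 0.1))
  rep0 <- cochranQ(hs)
  expect_equal(rep0@Q, 0)
  expect_equal(rep0@I2, 0)
  expect_equal(rep0@df, 2L)
  # I2 transform and floor
  expect_equal(i2FromQ(20, 10), 50)
  expect_equal(i2FromQ(5, 10), 0)
  # Q equals the residual-based form used inside IVW
  hs2 <- harmonisedSet(c(1, 1, 1), c(0.01, 0.01, 0.01),
                       c(0.1, 0.2, 0.6), c(0.1, 0.1, 0.1))
  est <- mrIVW(hs2, reFloor = FALSE)
  q <- cochranQ(hs2)
  expect_equal(q@Q, sum((c(0.1, 0.2, 0.6) - theta(est))^2 / 0.01))
  expect_equal(q@qPval, pchisq(q@Q, 2, lower.tail = FALSE))
})

test_that("MR-Egger recovers an exact line and reports dilution diagnostics", {
  bx <- c(0.05, 0.08, 0.1, 0.12, 0.15)
  by <- 0.01 + 0.3 * bx          # exact line through nonzero intercept
  hs <- harmonisedSet(bx, rep(0.005, 5), by, rep(0.01, 5))
  eg <- mrEgger(hs)
  expect_equal(theta(eg@slope), 0.3, tolerance = 1e-12)
  expect_equal(theta(eg@intercept), 0.01, tolerance = 1e-12)
  # I2_GX: strong spread relative to exposure noise gives a value near 1
  expect_gt(eg@i2gx, 0.9)
  expect_true(eg@nomeOk)
  # noisy exposure effects relative to their spread trigger the caution flag
  hsNoisy <- harmonisedSet(bx, rep(0.05, 5), by, rep(0.01, 5))
  egN <- mrEgger(hsNoisy)
  expect_lt(egN@i2gx, 0.9)
  expect_false(egN@nomeOk)
  expect_true(egN@i2gx >= 0 && egN@i2gx <= 1)
  # zero spread in exposure effects cannot be fit
  hsFlat <- harmonisedSet(rep(0.1, 5), rep(0.005, 5), by, rep(0.01, 5))
  expect_error(mrEgger(hsFlat), "collinear")
  # policy minimum
  expect_error(mrEgger(harmonisedSet(bx[1:4], rep(0.005, 4), by[1:4],
                                     rep(0.01, 4))), "at least 5")
})

test_that("Egger re-orients instruments so exposure effects are positive", {
  bx <- c(0.05, 0.08, 0.1, 0.12, 0.15)
  by <- 0.01 + 0.3 * bx
  flip <- c(1, -1, 1, -1, 1)
  hs <- harmonisedSet(bx * flip, rep(0.005, 5), by * flip, rep(0.01, 5))
  eg <- mrEgger(hs)
  expect_equal(theta(eg@slope), 0.3, tolerance = 1e-12)
  expect_equal(theta(eg@intercept), 0.01, tolerance = 1e-12)
})

test_that("weighted median interpolates the 50% weight point", {
  # equal weights by construction: v_j = sy^2 + by^2 sx^2 = 1 for every SNP
  by <- 1:5
  sy <- sqrt(1 - by^2 * 0.001^2)
  hs <- harmonisedSet(rep(1, 5), rep(0.001, 5), by, sy)
  wm <- weightedMedian(hs, nBoot = 100, seed = 5)
  expect_equal(theta(wm), 3)
  # one instrument carrying most of the weight dominates the median
  hs2 <- harmonisedSet(rep(1, 5), rep(0.001, 5), c(1, 2, 3, 4, 10),
                       c(1, 1, 1, 1, 0.01))
  wm2 <- weightedMedian(hs2, nBoot = 100, seed = 5)
  expect_equal(theta(wm2), 10, tolerance = 0.01)
  # identical seed gives a bit-identical bootstrap SE
  wmA <- weightedMedian(hs, nBoot = 200, seed = 99)
  wmB <- weightedMedian(hs, nBoot = 200, seed = 99)
  expect_identical(se(wmA), se(wmB))
  expect_gt(se(wmA), 0)
  expect_error(weightedMedian(hs, nBoot = 100), "seed")
  expect_error(weightedMedian(hs, nBoot = 50, seed = 1), "100")
})

test_that("leave-one-out re-estimates with each instrument omitted", {
  # k = 2: each omission leaves a single Wald ratio
  hs <- harmonisedSet(c(1, 2), c(0.01, 0.01), c(0.1, 0.4), c(0.1, 0.1))
  loo <- leaveOneOut(hs)
  expect_equal(nrow(loo), 2L)
  expect_equal(loo$theta, c(0.4 / 2, 0.1 / 1))
  # homogeneous set: every estimate equals the full one
  hs2 <- harmonisedSet(c(1, 2, 4), c(0.01, 0.01, 0.01),
                       c(0.1, 0.2, 0.4), c(0.1, 0.1, 0.1))
  loo2 <- leaveOneOut(hs2)
  expect_equal(loo2$theta, rep(theta(mrIVW(hs2)), 3))
  # a planted pleiotropic outlier: omitting it moves theta toward truth
  bx <- rep(1, 6); sy <- rep(0.02, 6)
  by <- c(rep(0.1, 5), 0.5)
  hs3 <- harmonisedSet(bx, rep(0.001, 6), by, sy)
  loo3 <- leaveOneOut(hs3)
  full <- theta(mrIVW(hs3))
  expect_equal(loo3$theta[6], 0.1, tolerance = 1e-12)  # oracle: clean refit
  expect_lt(abs(loo3$theta[6] - 0.1), abs(full - 0.1))
})

test_that("Cook's distances flag influential instruments", {
  # exchangeable points on an exact line: zero residuals, zero distances
  hs <- harmonisedSet(rep(1, 5), rep(0.01, 5), rep(0.2, 5), rep(0.1, 5))
  cd <- cooksDistance(hs)
  expect_equal(unname(cd$distance), rep(0, 5))
  expect_equal(cd$cutoff, 4 / 5)
  expect_length(cd$influential, 0)
  # cutoff arithmetic at k = 20
  hs20 <- harmonisedSet(rep(1, 20), rep(0.01, 20),
                        rnorm(20, 0.2, 0.01), rep(0.1, 20))
  expect_equal(cooksDistance(hs20)$cutoff, 0.2)
  # planted outlier: matches the brute-force deletion identity
  set.seed(7)
  bx <- runif(8, 0.5, 1.5)
  by <- 0.2 * bx + rnorm(8, 0, 0.01)
  by[8] <- by[8] + 0.3
  sy <- runif(8, 0.05, 0.15)
  hs8 <- harmonisedSet(bx, rep(0.01, 8), by, sy)
  cd8 <- cooksDistance(hs8)
  xs <- bx / sy; ys <- by / sy
  full <- sum(xs * ys) / sum(xs^2)
  s2 <- sum((ys - full * xs)^2) / 7
  brute <- vapply(1:8, function(j) {
    drop <- sum(xs[-j] * ys[-j]) / sum(xs[-j]^2)
    (full - drop)^2 * sum(xs^2) / s2
  }, 0)
  expect_equal(unname(cd8$distance), brute, tolerance = 1e-10)
  expect_true("snp8" %in% cd8$influential)
  expect_error(cooksDistance(harmonisedSet(1:3, rep(1, 3), 1:3, rep(1, 3))),
               "at least 5")
})

test_that("the estimators converge on the same effect with valid instruments", {
  # high-precision valid instruments: IVW, Egger slope and weighted median
  # should all sit on the true slope
  truth <- simTruth(m = 40L, gamma = seq(0.08, 0.2, length.out = 40),
                    maf = rep(0.3, 40), theta = 0.12,
                    nExposure = 4e6, nDuo = 4e6, seed = 31)
  sim <- simulateSumstatsDirect(truth)
  hs <- hsFromSim(sim)
  est <- c(ivw = theta(mrIVW(hs)), egger = theta(mrEgger(hs)@slope),
           wm = theta(weightedMedian(hs, nBoot = 200, seed = 3)))
  expect_true(all(abs(est - 0.12) < 0.01))
})

test_that("runMR applies the method-selection policy per exposure", {
  set.seed(12)
  mkSet <- function(k) harmonisedSet(
    seq(0.8, 1.2, length.out = k), rep(0.01, k),
    rnorm(k, 0.2, 0.02), rep(0.1, k))
  sets <- list(one = mkSet(1), two = mkSet(3), many = mkSet(6),
               none = harmonisedSet(numeric(), numeric(), numeric(),
                                    numeric(), snp = character()))
  res <- runMR(sets, seed = 2)
  expect_equal(res$METHOD[res$EXPOSURE == "one"], "wald")
  expect_setequal(res$METHOD[res$EXPOSURE == "two"], "ivw_mre")
  expect_setequal(res$METHOD[res$EXPOSURE == "many"],
                  c("ivw_mre", "weighted_median", "egger_slope",
                    "egger_intercept"))
  expect_named(attr(res, "skipped"), "none")
  # grams columns scale the SD columns by 484
  expect_equal(res$THETA_G, res$THETA_SD * 484)
  expect_equal(res$CI_U_G - res$CI_L_G, 2 * qnorm(0.975) * res$SE_G)
  # heterogeneity fields present for multi-instrument exposures
  expect_false(is.na(res$Q[res$EXPOSURE == "two"]))
  expect_false(any(is.na(res$I2GX[res$METHOD == "egger_slope"])))
  expect_error(runMR(sets), "seed")
})
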