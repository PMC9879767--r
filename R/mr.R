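newEstimate <- function(method, theta, se, k) {
  theta <- unname(as.numeric(theta))
  se <- unname(as.numeric(se))
  bounds <- normalCI(theta, se)
  new("MREstimate", method = method, theta = theta, se = se,
      ciLow = bounds[1L], ciHigh = bounds[2L],
      pval = zToP(theta / se), k = as.integer(k))
}

hsData <- function(x) {
  if (is(x, "HarmonisedSet")) harmonisedData(x) else as.data.frame(x)
}

#' Wald ratio causal estimate from a single instrument
#'
#' \code{theta = betaOutcome / betaExposure} with first-order delta-method
#' standard error \code{seOutcome / |betaExposure|}; CI and p-value from
#' the normal approximation.
#'
#' @param betaExposure,seExposure SNP-exposure effect and SE.
#' @param betaOutcome,seOutcome SNP-outcome effect and SE.
#' @return \code{MREstimate} with method \code{"wald"}.
#' @export
waldRatio <- function(betaExposure, seExposure, betaOutcome, seOutcome) {
  if (betaExposure == 0)
    stop("invalid instrument: betaExposure is zero")
  newEstimate("wald", betaOutcome / betaExposure,
              seOutcome / abs(betaExposure), 1L)
}

#' Inverse-variance weighted estimate (multiplicative random effects)
#'
#' Weighted regression of outcome effects on exposure effects through the
#' origin with weights \code{1 / seOutcome^2}:
#' \code{theta = sum(w bx by) / sum(w bx^2)}, fixed-effect
#' \code{se0 = sqrt(1 / sum(w bx^2))}. Under the multiplicative
#' random-effects model the SE is inflated by the residual heterogeneity
#' scale \code{sqrt(Q / (k - 1))}, floored at 1 by default so homogeneous
#' sets keep the fixed-effect SE.
#'
#' @param x \code{HarmonisedSet} (or data.frame with the same columns).
#' @param reFloor floor the heterogeneity scale at 1 (default TRUE).
#' @param allowSingle permit k = 1, in which case the result equals the
#'   Wald ratio; by default k < 2 is an error directing to
#'   \code{\link{waldRatio}}.
#' @return \code{MREstimate} with method \code{"ivw_mre"}.
#' @export
mrIVW <- function(x, reFloor = TRUE, allowSingle = FALSE) {
  d <- hsData(x)
  k <- nrow(d)
  if (k < 2L && !allowSingle)
    stop("IVW needs at least 2 instruments; use waldRatio() for k = 1")
  if (k < 1L) stop("no instruments")
  w <- 1 / d$seOutcome^2
  swx2 <- sum(w * d$betaExposure^2)
  thetaHat <- sum(w * d$betaExposure * d$betaOutcome) / swx2
  se0 <- sqrt(1 / swx2)
  if (k >= 2L) {
    Q <- sum(w * (d$betaOutcome - thetaHat * d$betaExposure)^2)
    scale <- sqrt(Q / (k - 1))
    if (reFloor) scale <- max(1, scale)
    seHat <- se0 * scale
  } else seHat <- se0
  newEstimate("ivw_mre", thetaHat, seHat, k)
}

#' Percent heterogeneity from Cochran's Q
#' @param Q Cochran statistic.
#' @param df degrees of freedom (k - 1).
#' @return \code{I2 = max(0, 100 * (Q - df) / Q)} in percent.
#' @export
i2FromQ <- function(Q, df) {
  ifelse(Q > 0, pmax(0, 100 * (Q - df) / Q), 0)
}

#' Cochran's Q heterogeneity test across per-SNP causal estimates
#'
#' Per-SNP ratios \code{theta_j = by_j / bx_j} with weights
#' \code{(bx_j / seOutcome_j)^2}; \code{Q = sum(w_j (theta_j - theta_IVW)^2)}
#' on \code{k - 1} degrees of freedom, I2 floored at 0, p-value from the
#' chi-square upper tail.
#'
#' @param x \code{HarmonisedSet} with at least 2 instruments.
#' @return \code{HeterogeneityReport} (Cook's distances and leave-one-out
#'   slots are empty; see \code{\link{mrDiagnostics}}).
#' @export
cochranQ <- function(x) {
  d <- hsData(x)
  k <- nrow(d)
  if (k < 2L) stop("heterogeneity is not defined for k < 2")
  est <- mrIVW(d)
  ratios <- d$betaOutcome / d$betaExposure
  w <- (d$betaExposure / d$seOutcome)^2
  Q <- sum(w * (ratios - theta(est))^2)
  df <- k - 1L
  new("HeterogeneityReport", Q = Q, df = as.integer(df),
      I2 = i2FromQ(Q, df), qPval = pchisq(Q, df, lower.tail = FALSE),
      cooks = setNames(numeric(), character()), cooksCutoff = 4 / k,
      influential = character(), loo = data.frame())
}

#' Leave-one-out IVW analysis
#'
#' Re-estimates the causal effect k times, omitting each instrument in
#' turn (Wald ratio when only one instrument remains). Outlier instruments
#' reveal themselves by moving the estimate when omitted.
#'
#' @param x \code{HarmonisedSet} with at least 2 instruments.
#' @return data.frame keyed by omitted SNP: \code{snp}, \code{theta},
#'   \code{se}, \code{ciLow}, \code{ciHigh}, \code{pval}, \code{k}.
#' @export
leaveOneOut <- function(x) {
  d <- hsData(x)
  k <- nrow(d)
  if (k < 2L) stop("leave-one-out needs at least 2 instruments")
  rows <- lapply(seq_len(k), function(j) {
    dj <- d[-j, , drop = FALSE]
    est <- if (nrow(dj) == 1L)
      waldRatio(dj$betaExposure, dj$seExposure, dj$betaOutcome, dj$seOutcome)
    else mrIVW(dj)
    data.frame(snp = d$snp[j], theta = theta(est), se = se(est),
               ciLow = ci(est)[1L], ciHigh = ci(est)[2L],
               pval = pvalue(est), k = est@k, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cook's distances for instrument influence on the IVW fit
#'
#' The weighted through-origin regression is transformed to unweighted
#' coordinates (\code{y* = by / seOutcome}, \code{x* = bx / seOutcome});
#' then \code{D_j = r_j^2 h_jj / (p s^2 (1 - h_jj)^2)} with one parameter,
#' leverages \code{h_jj = x*_j^2 / sum(x*^2)} and
#' \code{s^2 = sum(r^2) / (k - 1)}. Instruments with \code{D_j > 4 / k}
#' are flagged as influential; a point with leverage 1 gets an infinite
#' distance.
#'
#' @param x \code{HarmonisedSet} with at least 5 instruments (policy).
#' @param minInstruments policy minimum (default 5).
#' @return list with named \code{distance}, \code{cutoff} (= 4/k) and
#'   \code{influential} SNP ids.
#' @export
cooksDistance <- function(x, minInstruments = 5L) {
  d <- hsData(x)
  k <- nrow(d)
  if (k < minInstruments)
    stop("Cook's distance policy requires at least ", minInstruments,
         " instruments")
  xs <- d$betaExposure / d$seOutcome
  ys <- d$betaOutcome / d$seOutcome
  sxx <- sum(xs^2)
  bhat <- sum(xs * ys) / sxx
  r <- ys - bhat * xs
  h <- xs^2 / sxx
  s2 <- sum(r^2) / (k - 1)
  D <- if (s2 == 0) rep(0, k) else    # perfect fit: nothing is influential
    ifelse(h >= 1 - 1e-12, Inf, r^2 * h / (s2 * (1 - h)^2))
  names(D) <- d$snp
  cutoff <- 4 / k
  list(distance = D, cutoff = cutoff,
       influential = d$snp[is.infinite(D) | D > cutoff])
}

#' Full heterogeneity / influence diagnostics bundle
#'
#' Combines \code{\link{cochranQ}}, \code{\link{leaveOneOut}} (k >= 2) and
#' \code{\link{cooksDistance}} (k >= 5) into one
#' \code{HeterogeneityReport}.
#'
#' @param x \code{HarmonisedSet}.
#' @return \code{HeterogeneityReport}.
#' @export
mrDiagnostics <- function(x) {
  rep <- cochranQ(x)
  rep@loo <- leaveOneOut(x)
  if (nInstruments(x) >= 5L) {
    cd <- cooksDistance(x)
    rep@cooks <- cd$distance
    rep@influential <- cd$influential
  }
  validObject(rep)
  rep
}

#' MR-Egger regression with regression-dilution diagnostics
#'
#' Weighted regression \code{by = alpha + theta bx} with weights
#' \code{1 / seOutcome^2}, after re-orienting instruments so every
#' exposure effect is positive. The intercept estimates average unbalanced
#' pleiotropy; the slope estimates the causal effect under the INSIDE
#' assumption. Standard errors use the weighted fit with the residual
#' scale floored at 1 (matching the IVW convention). The I2_GX statistic
#' quantifies dilution from measurement error in the exposure effects
#' (NOME assumption): values above 0.9 indicate under 10\% relative bias.
#'
#' @param x \code{HarmonisedSet} with at least \code{minInstruments}.
#' @param minInstruments policy minimum (default 5).
#' @return \code{MREggerFit}.
#' @export
mrEgger <- function(x, minInstruments = 5L) {
  d <- hsData(x)
  k <- nrow(d)
  if (k < minInstruments)
    stop("MR-Egger policy requires at least ", minInstruments,
         " instruments")
  flip <- sign(d$betaExposure)
  flip[flip == 0] <- 1
  bx <- d$betaExposure * flip
  by <- d$betaOutcome * flip
  sx <- d$seExposure
  sy <- d$seOutcome
  if (var(bx) == 0) stop("no spread in exposure effects: collinear fit")
  w <- 1 / sy^2
  X <- cbind(intercept = 1, slope = bx)
  XtWX <- crossprod(X, w * X)
  betaHat <- solve(XtWX, crossprod(X, w * by))
  r <- by - X %*% betaHat
  sigma2 <- sum(w * r^2) / (k - 2)
  covU <- solve(XtWX) * max(1, sigma2)
  ses <- sqrt(diag(covU))
  wgx <- 1 / sx^2
  bxw <- sum(wgx * bx) / sum(wgx)
  Qgx <- sum((bx - bxw)^2 / sx^2)
  i2gx <- if (Qgx <= 0) 0 else max(0, (Qgx - (k - 1)) / Qgx)
  new("MREggerFit",
      slope = newEstimate("egger_slope", betaHat["slope", 1L],
                          ses["slope"], k),
      intercept = newEstimate("egger_intercept", betaHat["intercept", 1L],
                              ses["intercept"], k),
      i2gx = i2gx, nomeOk = i2gx > 0.9)
}

wmInterpolate <- function(ratios, w) {
  w <- w / sum(w)
  o <- order(ratios)
  ratios <- ratios[o]; w <- w[o]
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1L]) return(ratios[1L])
  if (0.5 >= s[length(s)]) return(ratios[length(s)])
  approx(s, ratios, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' Per-SNP Wald ratios are ordered and the inverse-variance weighted
#' median is read off by linear interpolation of the standardised
#' cumulative weights at 50\%; consistent as long as more than half of the
#' weight comes from valid instruments. The standard error is the SD of
#' the estimator over parametric-bootstrap resamples in which each SNP's
#' exposure and outcome effects are redrawn from their normal sampling
#' distributions.
#'
#' @param x \code{HarmonisedSet} with at least \code{minInstruments}.
#' @param nBoot bootstrap replicates (default 1000, minimum 100).
#' @param seed mandatory integer seed for the bootstrap.
#' @param minInstruments policy minimum (default 5).
#' @return \code{MREstimate} with method \code{"weighted_median"}.
#' @export
weightedMedian <- function(x, nBoot = 1000L, seed, minInstruments = 5L) {
  d <- hsData(x)
  k <- nrow(d)
  if (k < minInstruments)
    stop("weighted median policy requires at least ", minInstruments,
         " instruments")
  if (missing(seed)) stop("an explicit seed is required")
  if (nBoot < 100L) stop("nBoot must be at least 100")
  ratioWeights <- function(bx, by, sx, sy) {
    v <- sy^2 / bx^2 + (by^2 * sx^2) / bx^4   # first-order ratio variance
    1 / v
  }
  pt <- wmInterpolate(d$betaOutcome / d$betaExposure,
                      ratioWeights(d$betaExposure, d$betaOutcome,
                                   d$seExposure, d$seOutcome))
  old <- .Random.seed.exists()
  set.seed(deriveSeed(seed, 7L))
  boots <- vapply(seq_len(nBoot), function(i) {
    bx <- rnorm(k, d$betaExposure, d$seExposure)
    by <- rnorm(k, d$betaOutcome, d$seOutcome)
    wmInterpolate(by / bx, ratioWeights(bx, by, d$seExposure, d$seOutcome))
  }, 0)
  restoreSeed(old)
  newEstimate("weighted_median", pt, sd(boots), k)
}

.Random.seed.exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

restoreSeed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Run the full MR estimator and diagnostics suite per exposure
#'
#' Applies the method-selection policy: 1 instrument gives a Wald ratio;
#' 2 or more add multiplicative random-effects IVW, Cochran's Q and
#' leave-one-out; 5 or more add the weighted median, MR-Egger (with I2_GX)
#' and Cook's distances. Exposures with no instruments are skipped with a
#' reason. Results are reported both in outcome-SD units and in grams.
#'
#' @param sets named list of \code{HarmonisedSet}, one per exposure.
#' @param sdGrams grams per outcome SD (default 484).
#' @param nBoot weighted-median bootstrap replicates.
#' @param seed mandatory seed (weighted-median bootstrap).
#' @return data.frame with columns \code{EXPOSURE METHOD K THETA_SD SE_SD
#'   THETA_G SE_G CI_L_G CI_U_G PVAL Q DF I2 Q_PVAL I2GX}; skipped
#'   exposures and per-exposure diagnostics are in attributes
#'   \code{"skipped"} and \code{"diagnostics"}.
#' @export
runMR <- function(sets, sdGrams = 484, nBoot = 1000L, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  stopifnot(length(names(sets)) == length(sets))
  rows <- list(); skipped <- list(); diagnostics <- list()
  asRow <- function(exposure, est, Q = NA, df = NA, i2 = NA, qp = NA,
                    i2gx = NA) {
    g <- sdToGrams(est, sdGrams)
    data.frame(EXPOSURE = exposure, METHOD = est@method, K = est@k,
               THETA_SD = theta(est), SE_SD = se(est),
               THETA_G = theta(g), SE_G = se(g),
               CI_L_G = ci(g)[1L], CI_U_G = ci(g)[2L], PVAL = pvalue(est),
               Q = Q, DF = df, I2 = i2, Q_PVAL = qp, I2GX = i2gx,
               stringsAsFactors = FALSE)
  }
  for (exposure in names(sets)) {
    hs <- sets[[exposure]]
    k <- nInstruments(hs)
    if (k == 0L) {
      skipped[[exposure]] <- "no available genetic instruments"
      next
    }
    d <- harmonisedData(hs)
    if (k == 1L) {
      rows[[length(rows) + 1L]] <-
        asRow(exposure, waldRatio(d$betaExposure, d$seExposure,
                                  d$betaOutcome, d$seOutcome))
      next
    }
    het <- mrDiagnostics(hs)
    diagnostics[[exposure]] <- het
    rows[[length(rows) + 1L]] <-
      asRow(exposure, mrIVW(hs), het@Q, het@df, het@I2, het@qPval)
    if (k >= 5L) {
      wm <- weightedMedian(hs, nBoot = nBoot,
                           seed = deriveSeed(seed, match(exposure,
                                                         names(sets))))
      rows[[length(rows) + 1L]] <- asRow(exposure, wm)
      eg <- mrEgger(hs)
      rows[[length(rows) + 1L]] <- asRow(exposure, eg@slope,
                                         i2gx = eg@i2gx)
      rows[[length(rows) + 1L]] <- asRow(exposure, eg@intercept,
                                         i2gx = eg@i2gx)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else NULL
  attr(res, "skipped") <- skipped
  attr(res, "diagnostics") <- diagnostics
  res
}
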