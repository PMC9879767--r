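#' Joint re-clumping and assembly of multivariable MR input
#'
#' Takes the union of the per-exposure instrument sets, re-clumps it
#' greedily at the stricter multivariable threshold (default r2 < 0.001,
#' 10,000 kb window) with priority given to the smallest p-value across
#' exposures, and extracts each exposure's effect estimate for every
#' retained SNP. Union SNPs missing from an exposure's summary statistics
#' are 0-imputed with a flag (their SE is set to Inf so they carry no
#' weight in conditional-F calculations); in strict mode they are dropped
#' instead. Outcome effects are aligned to the first exposure table's
#' effect allele.
#'
#' @param instrumentSets named list of \code{InstrumentSet}, one per
#'   exposure.
#' @param exposureTables named list of \code{SummaryStats} matching
#'   \code{instrumentSets} (BETA/SE present).
#' @param outcome \code{SummaryStats} for the outcome.
#' @param ld LD table (\code{SNP_A}, \code{SNP_B}, \code{R2}).
#' @param r2Max joint clumping threshold (default 0.001).
#' @param windowKb clumping half-window in kb (default 10000).
#' @param strict drop SNPs missing from any exposure instead of 0-imputing.
#' @return \code{MVMRInput}.
#' @export
jointClump <- function(instrumentSets, exposureTables, outcome, ld,
                       r2Max = 0.001, windowKb = 10000, strict = FALSE) {
  stopifnot(identical(names(instrumentSets), names(exposureTables)),
            length(instrumentSets) >= 2L)
  exposures <- names(instrumentSets)
  unionSnps <- unique(unlist(lapply(instrumentSets, instruments)))
  # per-SNP min p across exposures + coordinates from first table carrying it
  cand <- do.call(rbind, lapply(unionSnps, function(snp) {
    best <- NULL
    for (tab in exposureTables) {
      r <- records(tab)
      r <- r[r$SNP == snp, , drop = FALSE]
      if (nrow(r) == 1L && (is.null(best) ||
                            (!is.na(r$P) && r$P < best$P)))
        best <- r[, c("SNP", "CHR", "POS", "EA", "OA", "P")]
    }
    best
  }))
  candTab <- sumstats(cand, trait = "joint", sampleLabel = "union")
  clumped <- clumpInstruments(candTab, ld = ld, r2Max = r2Max,
                              windowKb = windowKb)
  snps <- instruments(clumped)
  log <- selectionLog(clumped)

  ouRec <- records(outcome)
  d <- length(exposures); refTab <- records(exposureTables[[1L]])
  betaX <- seX <- imputed <- NULL
  bOut <- sOut <- numeric()
  keptSnps <- character()
  for (snp in snps) {
    ref <- refTab[refTab$SNP == snp, , drop = FALSE]
    if (nrow(ref) != 1L) {   # reference alleles from whichever table has it
      for (tab in exposureTables) {
        r <- records(tab); r <- r[r$SNP == snp, , drop = FALSE]
        if (nrow(r) == 1L) { ref <- r; break }
      }
    }
    yr <- ouRec[ouRec$SNP == snp, , drop = FALSE]
    if (nrow(yr) != 1L) {
      log <- rbind(log, logEntry(snp, "dropped", "missing from outcome"))
      next
    }
    s <- alleleOrientation(ref$EA, ref$OA, yr$EA, yr$OA)
    if (is.na(s)) {
      log <- rbind(log, logEntry(snp, "dropped", "outcome allele mismatch"))
      next
    }
    bx <- sx <- rep(NA_real_, d); imp <- rep(FALSE, d)
    for (j in seq_len(d)) {
      r <- records(exposureTables[[j]])
      r <- r[r$SNP == snp, , drop = FALSE]
      if (nrow(r) == 1L && !is.na(r$BETA)) {
        sj <- alleleOrientation(ref$EA, ref$OA, r$EA, r$OA)
        if (is.na(sj)) { r <- r[0, , drop = FALSE] } else {
          bx[j] <- sj * r$BETA; sx[j] <- r$SE
        }
      }
      if (is.na(bx[j])) {
        if (strict) { bx <- NULL; break }
        bx[j] <- 0; sx[j] <- Inf; imp[j] <- TRUE
        log <- rbind(log, logEntry(snp, "imputed",
                                   paste0("0-imputed for ", exposures[j])))
      }
    }
    if (is.null(bx)) {
      log <- rbind(log, logEntry(snp, "dropped",
                                 "missing exposure beta (strict mode)"))
      next
    }
    keptSnps <- c(keptSnps, snp)
    betaX <- rbind(betaX, bx); seX <- rbind(seX, sx)
    imputed <- rbind(imputed, imp)
    bOut <- c(bOut, s * yr$BETA); sOut <- c(sOut, yr$SE)
  }
  if (is.null(betaX)) betaX <- seX <- matrix(0, 0, d)
  if (is.null(imputed)) imputed <- matrix(FALSE, 0, d)
  dimnames(betaX) <- dimnames(seX) <- dimnames(imputed) <-
    list(keptSnps, exposures)
  new("MVMRInput", exposures = exposures, snps = keptSnps,
      betaExposure = betaX, seExposure = seX, betaOutcome = bOut,
      seOutcome = sOut, imputed = imputed, clumpR2 = r2Max, log = log)
}

#' Direct constructor for multivariable MR input
#'
#' Assembles an \code{MVMRInput} from already-aligned effect matrices,
#' bypassing clumping; useful for simulations and oracle checks.
#'
#' @param betaExposure,seExposure k x d matrices (columns named by
#'   exposure).
#' @param betaOutcome,seOutcome outcome effect and SE per SNP.
#' @param snps optional SNP ids.
#' @return \code{MVMRInput}.
#' @export
mvmrInput <- function(betaExposure, seExposure, betaOutcome, seOutcome,
                      snps = NULL) {
  betaExposure <- as.matrix(betaExposure)
  seExposure <- as.matrix(seExposure)
  if (is.null(colnames(betaExposure)))
    colnames(betaExposure) <- paste0("exposure", seq_len(ncol(betaExposure)))
  colnames(seExposure) <- colnames(betaExposure)
  if (is.null(snps)) snps <- paste0("snp", seq_len(nrow(betaExposure)))
  new("MVMRInput", exposures = colnames(betaExposure), snps = snps,
      betaExposure = betaExposure, seExposure = seExposure,
      betaOutcome = betaOutcome, seOutcome = seOutcome,
      imputed = matrix(FALSE, nrow(betaExposure), ncol(betaExposure),
                       dimnames = list(snps, colnames(betaExposure))),
      clumpR2 = NA_real_, log = emptyLog())
}

#' Multivariable IVW estimate
#'
#' Weighted regression of outcome effects on the matrix of exposure
#' effects without intercept, weights \code{1 / seOutcome^2}; the
#' cross-exposure covariance of genetic associations is fixed at zero.
#' Standard errors come from the weighted fit with multiplicative residual
#' scaling floored at 1. Exposure columns that are identically zero cannot
#' be estimated: they get an NA estimate (with a warning) and the rest of
#' the model is fit without them, so a null second exposure reproduces the
#' univariable IVW estimate exactly. Genuinely collinear non-zero columns
#' raise an error naming the exposures.
#'
#' @param input \code{MVMRInput} with at least 2 exposures and more SNPs
#'   than exposures.
#' @param conditionalF also compute per-exposure conditional F statistics
#'   (default TRUE).
#' @return \code{MVMRResult}.
#' @export
mvmrIVW <- function(input, conditionalF = TRUE) {
  stopifnot(is(input, "MVMRInput"))
  X <- input@betaExposure
  y <- input@betaOutcome
  k <- nrow(X); d <- ncol(X)
  if (d < 2L) stop("multivariable MR needs at least 2 exposures")
  if (k <= d) stop("needs more instruments than exposures")
  zero <- apply(X, 2L, function(col) all(col == 0))
  if (any(zero))
    warning("exposure(s) with all-zero effects dropped from the fit: ",
            paste(colnames(X)[zero], collapse = ", "))
  Xf <- X[, !zero, drop = FALSE]
  qrX <- qr(Xf)
  if (qrX$rank < ncol(Xf))
    stop("collinear exposure effects: ",
         paste(colnames(Xf), collapse = ", "))
  w <- 1 / input@seOutcome^2
  XtWX <- crossprod(Xf, w * Xf)
  betaHat <- solve(XtWX, crossprod(Xf, w * y))
  r <- y - Xf %*% betaHat
  sigma2 <- sum(w * r^2) / (k - ncol(Xf))
  covU <- solve(XtWX) * max(1, sigma2)
  ses <- sqrt(diag(covU))
  thetaAll <- seAll <- rep(NA_real_, d)
  names(thetaAll) <- names(seAll) <- colnames(X)
  thetaAll[!zero] <- betaHat[, 1L]
  seAll[!zero] <- ses
  condF <- rep(NA_real_, d)
  if (conditionalF && d >= 2L)
    condF <- vapply(colnames(X), function(e)
      tryCatch(conditionalFStat(input, e), error = function(err) NA_real_),
      0)
  q <- qnorm(0.975)
  res <- data.frame(
    exposure = colnames(X), theta = thetaAll, se = seAll,
    ciLow = thetaAll - q * seAll, ciHigh = thetaAll + q * seAll,
    pval = zToP(thetaAll / seAll), conditionalF = condF,
    weakFlag = !is.na(condF) & condF < 10, stringsAsFactors = FALSE,
    row.names = NULL)
  new("MVMRResult", results = res, k = as.integer(k))
}

#' Conditional F statistic for instrument strength in multivariable MR
#'
#' Regresses the target exposure's instrument effects on those of all
#' other exposures through the origin (weights \code{1 / seExposure^2} of
#' the target, zero cross-covariance); the conditional F is the weighted
#' residual sum of squares divided by \code{k - d}, where d counts the
#' other exposures plus one. With uninformative other exposures this
#' reduces to approximately the mean univariable F; instruments whose
#' effects are fully explained by the other exposures give F near 0.
#' Values below 10 flag conditionally weak instruments. 0-imputed target
#' entries carry zero weight.
#'
#' @param input \code{MVMRInput}.
#' @param exposure target exposure name.
#' @return conditional F statistic (numeric scalar).
#' @export
conditionalFStat <- function(input, exposure) {
  stopifnot(is(input, "MVMRInput"), exposure %in% input@exposures)
  j <- match(exposure, input@exposures)
  yv <- input@betaExposure[, j]
  Z <- input@betaExposure[, -j, drop = FALSE]
  w <- 1 / input@seExposure[, j]^2
  w[!is.finite(w)] <- 0
  d <- length(input@exposures)             # other exposures + 1
  k <- sum(w > 0)
  if (k <= d)
    stop("too few weighted instruments to condition ", exposure)
  # through-origin conditioning regression; collinear or all-zero columns
  # of the conditioning design are dropped (they carry no information)
  qrZ <- qr(sqrt(w) * Z)
  if (qrZ$rank > 0L) {
    use <- qrZ$pivot[seq_len(qrZ$rank)]
    Zu <- Z[, use, drop = FALSE]
    g <- solve(crossprod(Zu, w * Zu), crossprod(Zu, w * yv))
    r <- yv - Zu %*% g
  } else r <- yv
  sum(w * r^2) / (k - d)
}
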