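#' Pre-process a pregnancy biomarker for SNP association testing
#'
#' Natural-log transform, winsorise at \code{winsorSd} standard deviations
#' around the mean, transform to Z scores, then residualise on maternal
#' age and genomic principal components by least squares. Non-positive
#' concentrations are excluded and counted.
#'
#' @param values raw concentrations (> 0).
#' @param age optional maternal age covariate.
#' @param pcs optional matrix/data.frame of principal components
#'   (conventionally the top 10).
#' @param winsorSd winsorising bound in SD units (default 5).
#' @return numeric residuals (NA where the input was excluded), with
#'   attribute \code{"nExcluded"}.
#' @export
preprocessBiomarker <- function(values, age = NULL, pcs = NULL,
                                winsorSd = 5) {
  ok <- !is.na(values) & values > 0
  nExcluded <- sum(!ok)
  lv <- log(values[ok])
  m <- mean(lv); s <- sd(lv)
  wv <- pmin(pmax(lv, m - winsorSd * s), m + winsorSd * s)
  z <- (wv - mean(wv)) / sd(wv)
  covars <- NULL
  if (!is.null(age)) covars <- cbind(covars, age = age[ok])
  if (!is.null(pcs)) covars <- cbind(covars, as.matrix(pcs)[ok, , drop = FALSE])
  resids <- if (is.null(covars)) z else
    stats::residuals(lm(z ~ covars))
  out <- rep(NA_real_, length(values))
  out[ok] <- resids
  attr(out, "nExcluded") <- nExcluded
  out
}

#' Per-SNP association of genotype dosages with biomarker residuals
#'
#' Simple least-squares slope and standard error of the residualised
#' biomarker on each SNP's dosage. Monomorphic SNPs are excluded with a
#' reason; rows with missing residuals are dropped pairwise.
#'
#' @param dosages numeric vector or n x m matrix of dosages in [0, 2]
#'   (columns named by SNP).
#' @param residuals residualised biomarker values (see
#'   \code{\link{preprocessBiomarker}}).
#' @return data.frame with \code{snp}, \code{beta}, \code{se}, \code{n};
#'   excluded SNPs listed in attribute \code{"excluded"}.
#' @export
snpAssoc <- function(dosages, residuals) {
  g <- as.matrix(dosages)
  if (is.null(colnames(g))) colnames(g) <- paste0("snp", seq_len(ncol(g)))
  rows <- list(); excluded <- character()
  for (j in seq_len(ncol(g))) {
    ok <- !is.na(g[, j]) & !is.na(residuals)
    gj <- g[ok, j]; yj <- residuals[ok]
    if (length(unique(gj)) < 2L) {
      excluded <- c(excluded, colnames(g)[j])
      next
    }
    gc <- gj - mean(gj); yc <- yj - mean(yj)
    sxx <- sum(gc^2)
    beta <- sum(gc * yc) / sxx
    rss <- sum(yc^2) - beta^2 * sxx
    seb <- sqrt(rss / (length(gj) - 2) / sxx)
    rows[[length(rows) + 1L]] <- data.frame(
      snp = colnames(g)[j], beta = beta, se = seb, n = length(gj),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp = character(), beta = numeric(), se = numeric(),
               n = integer())
  attr(out, "excluded") <- excluded
  out
}

#' Fixed-effect heterogeneity test for one association across sources
#'
#' Pools per-source estimates with inverse-variance weights and computes
#' Cochran's Q on \code{sources - 1} degrees of freedom; the association
#' is flagged consistent when the heterogeneity p-value exceeds 0.05.
#' Invariant to source ordering.
#'
#' @param beta per-source effect estimates (length >= 2).
#' @param se per-source standard errors (> 0).
#' @param alpha consistency threshold on the heterogeneity p (default
#'   0.05).
#' @return list with \code{pooled}, \code{pooledSE}, \code{Q}, \code{df},
#'   \code{pval}, \code{consistent}.
#' @export
crossSourceHeterogeneity <- function(beta, se, alpha = 0.05) {
  stopifnot(length(beta) == length(se), all(se > 0))
  if (length(beta) < 2L)
    stop("heterogeneity needs at least 2 sources")
  w <- 1 / se^2
  pooled <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - pooled)^2)
  df <- length(beta) - 1L
  pval <- pchisq(Q, df, lower.tail = FALSE)
  list(pooled = pooled, pooledSE = sqrt(1 / sum(w)), Q = Q, df = df,
       pval = pval, consistent = pval > alpha)
}

#' Per-exposure pooled comparison across data sources
#'
#' Within each source the exposure's instrument associations are pooled by
#' fixed-effect inverse-variance meta-analysis; cross-source heterogeneity
#' is then tested on the pooled values.
#'
#' @param estimates data.frame with columns \code{source}, \code{beta},
#'   \code{se} (one row per instrument per source).
#' @return list with \code{perSource} (pooled estimate per source) and the
#'   cross-source heterogeneity fields of
#'   \code{\link{crossSourceHeterogeneity}}.
#' @export
metaPerExposure <- function(estimates) {
  stopifnot(all(c("source", "beta", "se") %in% names(estimates)))
  bySource <- split(estimates, estimates$source)
  perSource <- do.call(rbind, lapply(names(bySource), function(s) {
    e <- bySource[[s]]
    w <- 1 / e$se^2
    data.frame(source = s, pooled = sum(w * e$beta) / sum(w),
               se = sqrt(1 / sum(w)), k = nrow(e),
               stringsAsFactors = FALSE)
  }))
  het <- crossSourceHeterogeneity(perSource$pooled, perSource$se)
  c(list(perSource = perSource), het)
}

#' Pairwise Pearson correlation of SNP-effect vectors across exposures
#'
#' For each exposure pair, the per-SNP effect estimates (aligned to a
#' common effect allele per SNP, taken from the first table carrying it)
#' are correlated over pairwise-complete SNPs. Pairs sharing fewer than
#' \code{minShared} SNPs, or with a zero-variance vector, get NA with a
#' flag. The matrix is exactly symmetric with unit diagonal.
#'
#' @param tables named list of \code{SummaryStats}, one per exposure.
#' @param snps optional SNP subset.
#' @param minShared minimum shared SNPs per pair (default 3).
#' @return list with matrices \code{r} (correlations) and \code{nSnps}
#'   (pairwise-complete counts).
#' @export
pairwiseEffectCorrelation <- function(tables, snps = NULL, minShared = 3L) {
  stopifnot(length(names(tables)) == length(tables))
  allSnps <- unique(unlist(lapply(tables, function(t) records(t)$SNP)))
  if (!is.null(snps)) allSnps <- intersect(allSnps, snps)
  # reference alleles per SNP: first table carrying it
  refEA <- refOA <- setNames(rep(NA_character_, length(allSnps)), allSnps)
  for (t in tables) {
    r <- records(t)
    hit <- r$SNP %in% allSnps[is.na(refEA[r$SNP])]
    refEA[r$SNP[hit]] <- r$EA[hit]
    refOA[r$SNP[hit]] <- r$OA[hit]
  }
  B <- matrix(NA_real_, length(allSnps), length(tables),
              dimnames = list(allSnps, names(tables)))
  for (e in names(tables)) {
    r <- records(tables[[e]])
    r <- r[r$SNP %in% allSnps & !is.na(r$BETA), , drop = FALSE]
    for (i in seq_len(nrow(r))) {
      s <- alleleOrientation(refEA[r$SNP[i]], refOA[r$SNP[i]],
                             r$EA[i], r$OA[i])
      if (!is.na(s)) B[r$SNP[i], e] <- s * r$BETA[i]
    }
  }
  d <- ncol(B)
  rMat <- matrix(NA_real_, d, d,
                 dimnames = list(colnames(B), colnames(B)))
  diag(rMat) <- 1
  nMat <- matrix(0, d, d, dimnames = dimnames(rMat))
  diag(nMat) <- colSums(!is.na(B))
  for (i in seq_len(d)) for (j in seq_len(d)) {
    if (i >= j) next
    ok <- !is.na(B[, i]) & !is.na(B[, j])
    nMat[i, j] <- nMat[j, i] <- sum(ok)
    if (sum(ok) < minShared) next
    if (var(B[ok, i]) == 0 || var(B[ok, j]) == 0) next  # undefined entry
    rMat[i, j] <- rMat[j, i] <- cor(B[ok, i], B[ok, j])
  }
  list(r = rMat, nSnps = nMat)
}
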