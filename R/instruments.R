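#' Select genome-wide significant instruments for one exposure
#'
#' Keeps SNPs with p-value strictly below the metabolome-wide adjusted
#' threshold (default 5e-8 / 102 = 4.9e-10, the conventional genome-wide
#' level divided by the number of principal components explaining 95\% of
#' metabolite variation), sorted by ascending p.
#'
#' @param x \code{SummaryStats} for the exposure.
#' @param pThreshold significance level (strict \code{<}).
#' @return \code{InstrumentSet}; empty (with a warning) if nothing passes.
#' @export
selectInstruments <- function(x, pThreshold = 5e-8 / 102) {
  stopifnot(is(x, "SummaryStats"))
  rec <- records(x)
  keep <- !is.na(rec$P) & rec$P < pThreshold
  rec <- rec[keep, , drop = FALSE]
  rec <- rec[order(rec$P, rec$POS, rec$SNP), , drop = FALSE]
  if (!nrow(rec)) warning("no instruments pass p < ", pThreshold,
                          " for ", trait(x))
  new("InstrumentSet", exposure = trait(x), snps = rec$SNP,
      selectionLog = if (nrow(rec))
        logEntry(rec$SNP, "selected", sprintf("p < %.3g", pThreshold))
      else emptyLog())
}

ldLookup <- function(ld) {
  if (is.null(ld) || !nrow(ld)) return(function(a, b) 0)
  key <- c(paste(ld$SNP_A, ld$SNP_B, sep = "\r"),
           paste(ld$SNP_B, ld$SNP_A, sep = "\r"))
  val <- c(ld$R2, ld$R2)
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(key)) assign(key[i], val[i], envir = env)
  function(a, b) {
    v <- mget(paste(a, b, sep = "\r"), envir = env,
              ifnotfound = list(0))[[1L]]
    as.numeric(v)
  }
}

#' Greedy LD clumping of candidate instruments
#'
#' Repeatedly takes the lowest-p unclaimed SNP as an index variant and
#' removes every unclaimed SNP with \code{r2 >= r2Max} within
#' \code{windowKb} kb on either side (same chromosome). Pairs absent from
#' the LD table are treated as r2 = 0. Ties are broken deterministically by
#' p-value, then position, then SNP id, so the result is invariant to input
#' row order. The defaults reproduce the stringent second-stage rule
#' (r2 < 0.01, 10,000 kb window); \code{r2Max = 0.05} with a 1,000 kb
#' window reproduces the first-stage sentinel rule.
#'
#' @param x \code{SummaryStats} or \code{InstrumentSet} paired with
#'   \code{table} holding P/CHR/POS for its SNPs.
#' @param ld data.frame with columns \code{SNP_A}, \code{SNP_B}, \code{R2}.
#' @param r2Max LD threshold: a neighbour is removed when its r2 with the
#'   index SNP is \code{>= r2Max}.
#' @param windowKb half-window in kb around the index SNP.
#' @param table \code{SummaryStats} carrying P/CHR/POS when \code{x} is an
#'   \code{InstrumentSet}.
#' @return \code{InstrumentSet} of retained index SNPs (ordered by p) whose
#'   selection log records every removal.
#' @export
clumpInstruments <- function(x, ld, r2Max = 0.01, windowKb = 10000,
                             table = NULL) {
  if (is(x, "InstrumentSet")) {
    stopifnot(is(table, "SummaryStats"))
    rec <- records(table)
    rec <- rec[rec$SNP %in% instruments(x), , drop = FALSE]
    exposure <- x@exposure
    log <- selectionLog(x)
  } else {
    stopifnot(is(x, "SummaryStats"))
    rec <- records(x)
    exposure <- trait(x)
    log <- emptyLog()
  }
  if (!nrow(rec))
    return(new("InstrumentSet", exposure = exposure, snps = character(),
               selectionLog = log))
  rec <- rec[order(rec$P, rec$POS, rec$SNP), , drop = FALSE]
  r2 <- ldLookup(ld)
  win <- windowKb * 1000
  unclaimed <- rep(TRUE, nrow(rec))
  kept <- logical(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    if (!unclaimed[i]) next
    unclaimed[i] <- FALSE
    kept[i] <- TRUE
    idx <- rec[i, ]
    for (j in seq_len(nrow(rec))) {
      if (!unclaimed[j]) next
      other <- rec[j, ]
      rr <- r2(idx$SNP, other$SNP)
      if (rr >= r2Max) {
        if (is.na(idx$POS) || is.na(other$POS))
          stop("SNP missing position for clumping window check: ",
               if (is.na(idx$POS)) idx$SNP else other$SNP)
        sameChr <- !is.na(idx$CHR) && !is.na(other$CHR) &&
          idx$CHR == other$CHR
        if (sameChr && abs(idx$POS - other$POS) <= win) {
          unclaimed[j] <- FALSE
          log <- rbind(log, logEntry(other$SNP, "removed",
                                     sprintf("r2 = %.3g with index %s",
                                             rr, idx$SNP)))
        }
      }
    }
  }
  new("InstrumentSet", exposure = exposure, snps = rec$SNP[kept],
      selectionLog = rbind(log, logEntry(rec$SNP[kept], "clump_index",
                                         "retained as index SNP")))
}

#' Look up the best LD proxy for a missing SNP
#'
#' Returns the highest-r2 proxy with \code{r2 >= r2Min} (default 0.8) from
#' a precomputed proxy table, or \code{NA} when no proxy qualifies. Ties
#' break lexicographically on the proxy id.
#'
#' @param snp target SNP id.
#' @param proxies data.frame with columns \code{TARGET}, \code{PROXY},
#'   \code{R2} and optionally \code{EA_MAP} (allele translation, format
#'   \code{"tEA=pEA,tOA=pOA"}).
#' @param r2Min minimum r2.
#' @param available optional character vector; only proxies in it qualify
#'   (e.g. SNPs present in the outcome GWAS).
#' @return single proxy SNP id, or \code{NA_character_}.
#' @export
findProxy <- function(snp, proxies, r2Min = 0.8, available = NULL) {
  if (is.null(proxies) || !nrow(proxies)) return(NA_character_)
  cand <- proxies[proxies$TARGET == snp & proxies$R2 >= r2Min, , drop = FALSE]
  if (!is.null(available))
    cand <- cand[cand$PROXY %in% available, , drop = FALSE]
  if (!nrow(cand)) return(NA_character_)
  cand <- cand[order(-cand$R2, cand$PROXY), , drop = FALSE]
  cand$PROXY[1L]
}

#' Is an allele pair palindromic (A/T or C/G)?
#'
#' Palindromic variants read the same on both strands, so strand cannot be
#' inferred from alleles alone. Indel alleles are never palindromic.
#'
#' @param ea,oa allele strings.
#' @return logical vector.
#' @examples
#' isPalindromic("A", "T")  # TRUE
#' isPalindromic("A", "G")  # FALSE
#' @export
isPalindromic <- function(ea, oa) {
  ea <- upperAllele(ea); oa <- upperAllele(oa)
  single <- nchar(ea) == 1L & nchar(oa) == 1L
  single & ((ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
            (ea == "C" & oa == "G") | (ea == "G" & oa == "C"))
}

parseEaMap <- function(eaMap) {
  if (is.null(eaMap) || is.na(eaMap) || !nzchar(eaMap)) return(NULL)
  pairs <- strsplit(strsplit(eaMap, ",", fixed = TRUE)[[1L]], "=", fixed = TRUE)
  stats::setNames(vapply(pairs, `[`, "", 1L), vapply(pairs, `[`, "", 2L))
}

#' Harmonise exposure and outcome summary statistics per instrument
#'
#' Aligns SNP-outcome effects to the exposure table's effect allele:
#' identical orientation is kept, swapped alleles flip the outcome effect
#' sign and frequency, strand complements are resolved for non-palindromic
#' SNPs. Palindromic SNPs are retained only when the minor allele frequency
#' is below \code{ambiguityMaf} on both sides and the frequencies are
#' concordant (within \code{eafTol}) under one orientation, in which case
#' the frequency decides the orientation; otherwise they are dropped as
#' ambiguous. SNPs absent from the outcome are substituted by their best
#' LD proxy (\code{r2 >= proxyR2Min}) when a proxy table is supplied and
#' dropped otherwise. Every exclusion is logged with a reason.
#'
#' @param exposure \code{SummaryStats} with BETA/SE present (see
#'   \code{\link{reconstructEffects}}).
#' @param outcome \code{SummaryStats} for the outcome.
#' @param snps optional SNP subset (e.g. \code{instruments()} of a clumped
#'   set); default: every exposure SNP.
#' @param proxies optional proxy table (see \code{\link{findProxy}}).
#' @param proxyR2Min minimum proxy r2.
#' @param ambiguityMaf palindromic SNPs with MAF at or above this value on
#'   either side are dropped (default 0.30).
#' @param eafTol frequency-concordance tolerance for orienting palindromic
#'   SNPs (default 0.08).
#' @return \code{HarmonisedSet}.
#' @export
harmonise <- function(exposure, outcome, snps = NULL, proxies = NULL,
                      proxyR2Min = 0.8, ambiguityMaf = 0.30, eafTol = 0.08) {
  stopifnot(is(exposure, "SummaryStats"), is(outcome, "SummaryStats"))
  ex <- records(exposure)
  ou <- records(outcome)
  if (is.null(snps)) snps <- ex$SNP
  log <- emptyLog()
  rows <- list()
  for (snp in snps) {
    xr <- ex[ex$SNP == snp, , drop = FALSE]
    if (nrow(xr) != 1L) {
      log <- rbind(log, logEntry(snp, "dropped", "absent from exposure"))
      next
    }
    if (is.na(xr$BETA) || is.na(xr$SE)) {
      stop("exposure record for ", snp, " lacks BETA/SE; run ",
           "reconstructEffects() first")
    }
    proxySnp <- NA_character_
    eaMap <- NULL
    yr <- ou[ou$SNP == snp, , drop = FALSE]
    if (nrow(yr) != 1L) {
      p <- findProxy(snp, proxies, r2Min = proxyR2Min, available = ou$SNP)
      if (is.na(p)) {
        log <- rbind(log, logEntry(snp, "dropped",
                                   "missing from outcome, no proxy"))
        next
      }
      proxySnp <- p
      yr <- ou[ou$SNP == p, , drop = FALSE]
      pm <- proxies[proxies$TARGET == snp & proxies$PROXY == p, , drop = FALSE]
      if ("EA_MAP" %in% names(pm) && nrow(pm))
        eaMap <- parseEaMap(pm$EA_MAP[1L])
      log <- rbind(log, logEntry(snp, "proxied",
                                 sprintf("substituted by %s (r2 >= %.2f)",
                                         p, proxyR2Min)))
    }
    yEA <- yr$EA; yOA <- yr$OA
    if (!is.null(eaMap)) {           # translate proxy alleles to target space
      yEA <- if (yEA %in% names(eaMap)) unname(eaMap[yEA]) else yEA
      yOA <- if (yOA %in% names(eaMap)) unname(eaMap[yOA]) else yOA
    }
    by <- yr$BETA; sy <- yr$SE; eafY <- yr$EAF
    pal <- isPalindromic(xr$EA, xr$OA)
    if (pal) {
      # nominal alignment by allele label (strand is uninformative here)
      if (yEA == xr$EA && yOA == xr$OA) {
        # as is
      } else if (yEA == xr$OA && yOA == xr$EA) {
        by <- -by; eafY <- 1 - eafY
      } else {
        log <- rbind(log, logEntry(snp, "dropped", "allele mismatch"))
        next
      }
      if (is.na(xr$EAF) || is.na(eafY)) {
        log <- rbind(log, logEntry(snp, "dropped",
                                   "palindromic, frequency unavailable"))
        next
      }
      mafX <- min(xr$EAF, 1 - xr$EAF)
      mafY <- min(eafY, 1 - eafY)
      if (mafX >= ambiguityMaf || mafY >= ambiguityMaf) {
        log <- rbind(log, logEntry(snp, "dropped", "ambiguous palindromic"))
        next
      }
      if (abs(xr$EAF - eafY) <= eafTol) {
        # orientation confirmed by frequency
      } else if (abs(xr$EAF - (1 - eafY)) <= eafTol) {
        by <- -by; eafY <- 1 - eafY
        log <- rbind(log, logEntry(snp, "flipped",
                                   "palindromic re-oriented by frequency"))
      } else {
        log <- rbind(log, logEntry(snp, "dropped",
                                   "palindromic frequency discordant"))
        next
      }
    } else {
      s <- alleleOrientation(xr$EA, xr$OA, yEA, yOA)
      if (is.na(s)) {
        log <- rbind(log, logEntry(snp, "dropped", "allele mismatch"))
        next
      }
      if (s < 0) { by <- -by; eafY <- 1 - eafY }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      snp = snp, EA = xr$EA, OA = xr$OA,
      betaExposure = xr$BETA, seExposure = xr$SE,
      betaOutcome = by, seOutcome = sy,
      eaf = xr$EAF, eafOutcome = eafY, palindromic = pal,
      proxySnp = proxySnp, stringsAsFactors = FALSE)
  }
  d <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp = character(), EA = character(), OA = character(),
               betaExposure = numeric(), seExposure = numeric(),
               betaOutcome = numeric(), seOutcome = numeric(),
               eaf = numeric(), eafOutcome = numeric(),
               palindromic = logical(), proxySnp = character(),
               stringsAsFactors = FALSE)
  rownames(d) <- NULL
  new("HarmonisedSet", exposure = trait(exposure), outcome = trait(outcome),
      data = d, log = log)
}

#' Direct constructor for a harmonised instrument set
#'
#' Builds a \code{HarmonisedSet} from already-aligned effect vectors;
#' convenient for simulations and for feeding externally harmonised data
#' into the estimators.
#'
#' @param betaExposure,seExposure SNP-exposure effects and SEs (SD units).
#' @param betaOutcome,seOutcome SNP-outcome effects and SEs.
#' @param snp SNP ids (default snp1..snpK).
#' @param eaf optional effect-allele frequencies.
#' @param exposure,outcome trait names.
#' @return \code{HarmonisedSet}.
#' @export
harmonisedSet <- function(betaExposure, seExposure, betaOutcome, seOutcome,
                          snp = NULL, eaf = NA_real_,
                          exposure = "exposure", outcome = "outcome") {
  k <- length(betaExposure)
  if (is.null(snp)) snp <- paste0("snp", seq_len(k))
  d <- data.frame(snp = snp, EA = rep("A", k), OA = rep("G", k),
                  betaExposure = betaExposure, seExposure = seExposure,
                  betaOutcome = betaOutcome, seOutcome = seOutcome,
                  eaf = rep(eaf, length.out = k),
                  eafOutcome = rep(eaf, length.out = k),
                  palindromic = rep(FALSE, k),
                  proxySnp = rep(NA_character_, k),
                  stringsAsFactors = FALSE)
  new("HarmonisedSet", exposure = exposure, outcome = outcome, data = d,
      log = emptyLog())
}

#' Variance in the exposure explained by instruments
#'
#' For a standardised exposure each instrument contributes
#' \code{r2 = 2 * eaf * (1 - eaf) * beta^2}; the per-exposure total is the
#' sum over instruments.
#'
#' @param betaExposure per-SNP effects in exposure-SD units.
#' @param eaf effect-allele frequencies.
#' @return list with per-SNP \code{r2} and the \code{total}.
#' @export
varianceExplained <- function(betaExposure, eaf) {
  r2 <- 2 * eaf * (1 - eaf) * betaExposure^2
  total <- sum(r2)
  if (isTRUE(total > 1))
    stop("variance explained exceeds 1; effects are not on the SD scale")
  list(r2 = r2, total = total)
}

#' Per-instrument F statistic
#'
#' \code{F = (beta / se)^2}; values below 10 conventionally flag weak
#' instruments.
#'
#' @param betaExposure,seExposure SNP-exposure effect and SE.
#' @return numeric F statistic(s).
#' @export
instrumentF <- function(betaExposure, seExposure) {
  if (any(seExposure <= 0)) stop("seExposure must be positive")
  (betaExposure / seExposure)^2
}
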