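# Internal helpers shared across modules.

#' Derive a stage-specific sub-seed from a master seed
#'
#' Every stage of a simulation (genotype draw, replicate r, bootstrap)
#' draws from its own sub-stream derived deterministically from
#' (master seed, stage index), so stages and replicates are independently
#' reproducible from one integer seed. Simple multiplicative congruential
#' scheme kept inside the 32-bit integer range.
#'
#' @param seed master integer seed.
#' @param stage integer stage / replicate index.
#' @return an integer seed.
#' @export
deriveSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  m <- 2147483647
  s <- abs(as.double(seed)) %% m
  for (k in c(as.double(stage), 40543)) {
    s <- (s * 69069 + k + 1) %% m
  }
  # pass the combined value through the generator's own scrambling so
  # sub-streams whose combined values sit at fixed arithmetic offsets are
  # statistically independent
  old <- .Random.seed.exists()
  set.seed(as.integer(floor(s)))
  out <- sample.int(2147483646L, 1L)
  restoreSeed(old)
  out
}

#' Draw independent replicate seeds from a master seed
#'
#' Replicate studies in a Monte-Carlo experiment each need their own seed.
#' Arithmetic seed chains (consecutive integers or fixed offsets) can leave
#' detectable correlation between generator streams, so replicate seeds are
#' drawn through R's own generator, seeded from the master seed.
#'
#' @param seed master integer seed.
#' @param n number of replicate seeds.
#' @param stream experiment index, so distinct experiments sharing one
#'   master seed get distinct seed sequences.
#' @return integer vector of n seeds in [1, 2^31 - 2].
#' @export
replicateSeeds <- function(seed, n, stream = 1L) {
  old <- .Random.seed.exists()
  set.seed(deriveSeed(seed, 90L + stream))
  out <- sample.int(2147483646L, n)
  restoreSeed(old)
  out
}

upperAllele <- function(a) toupper(trimws(as.character(a)))

complementAllele <- function(a) {
  ifelse(nchar(a) == 1L & a %in% c("A", "C", "G", "T"),
         chartr("ACGT", "TGCA", a), a)
}

# Orientation of an allele pair (ea, oa) against a reference pair.
# Returns +1 (same), -1 (swapped; effect sign and eaf flip), or NA
# (irreconcilable). Strand complements are tried for single-nucleotide,
# non-palindromic pairs only.
alleleOrientation <- function(refEA, refOA, ea, oa) {
  if (ea == refEA && oa == refOA) return(1)
  if (ea == refOA && oa == refEA) return(-1)
  if (nchar(ea) == 1L && nchar(oa) == 1L &&
      !isPalindromic(ea, oa) && !isPalindromic(refEA, refOA)) {
    cea <- complementAllele(ea)
    coa <- complementAllele(oa)
    if (cea == refEA && coa == refOA) return(1)
    if (cea == refOA && coa == refEA) return(-1)
  }
  NA_real_
}

zToP <- function(z) 2 * pnorm(-abs(z))

normalCI <- function(theta, se, level = 0.95) {
  q <- qnorm(1 - (1 - level) / 2)
  c(theta - q * se, theta + q * se)
}

emptyLog <- function() {
  data.frame(snp = character(), action = character(), reason = character(),
             stringsAsFactors = FALSE)
}

logEntry <- function(snp, action, reason) {
  data.frame(snp = snp, action = action, reason = reason,
             stringsAsFactors = FALSE)
}
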