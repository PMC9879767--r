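canonicalCols <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE",
                   "Z", "P", "N", "N_STUDIES")
numericCols <- c("POS", "EAF", "BETA", "SE", "Z", "P", "N", "N_STUDIES")

#' Construct a summary-statistic table from a data.frame
#'
#' Low-level constructor used by the readers and the simulator. Alleles are
#' upper-cased, missing canonical columns are added as NA, rows violating
#' basic invariants (missing SNP/alleles, non-positive SE, EAF outside
#' [0, 1], duplicated SNP id, i.e. multi-allelic sites) are dropped and
#' counted in the report.
#'
#' @param x data.frame with (a subset of) the canonical columns
#'   \code{SNP CHR POS EA OA EAF BETA SE Z P N N_STUDIES}.
#' @param trait trait name.
#' @param sampleLabel data-source tag.
#' @return a \code{SummaryStats} object; its load report is in
#'   \code{loadReport()}.
#' @export
sumstats <- function(x, trait, sampleLabel = "unknown") {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  for (cc in setdiff(canonicalCols, names(x))) x[[cc]] <- NA
  x <- x[, canonicalCols]
  nRead <- nrow(x)
  x$SNP <- as.character(x$SNP)
  x$CHR <- as.character(x$CHR)
  x$EA <- upperAllele(x$EA)
  x$OA <- upperAllele(x$OA)
  for (cc in numericCols) x[[cc]] <- suppressWarnings(as.numeric(x[[cc]]))

  dropped <- character()
  dropRows <- function(bad, reason) {
    bad[is.na(bad)] <- FALSE
    if (any(bad)) {
      dropped <<- c(dropped, setNames(rep(reason, sum(bad)), x$SNP[bad]))
      x <<- x[!bad, , drop = FALSE]
    }
  }
  dropRows(is.na(x$SNP) | x$SNP == "" | is.na(x$EA) | x$EA == "" |
           is.na(x$OA) | x$OA == "", "missing mandatory field")
  dropRows(x$EA == x$OA, "identical alleles")
  dropRows(!is.na(x$SE) & x$SE <= 0, "non-positive SE")
  dropRows(!is.na(x$EAF) & (x$EAF < 0 | x$EAF > 1), "EAF outside [0, 1]")
  dup <- x$SNP %in% x$SNP[duplicated(x$SNP)]
  dropRows(dup, "multi-allelic or duplicated site")

  # fill Z from BETA/SE (and vice versa checks are a validity concern)
  needZ <- is.na(x$Z) & !is.na(x$BETA) & !is.na(x$SE)
  x$Z[needZ] <- x$BETA[needZ] / x$SE[needZ]
  needP <- is.na(x$P) & !is.na(x$Z)
  x$P[needP] <- zToP(x$Z[needP])
  rownames(x) <- NULL

  report <- list(nRead = nRead, nKept = nrow(x),
                 dropped = as.list(table(unname(dropped))))
  new("SummaryStats", trait = as.character(trait),
      sampleLabel = as.character(sampleLabel), records = x, report = report)
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab- or whitespace-separated file with a header row into a
#' \code{SummaryStats} table. Non-canonical column names are mapped through
#' \code{dialect}; unparseable or invariant-violating rows are dropped and
#' counted in the load report.
#'
#' @param path file path.
#' @param trait trait name for the table.
#' @param sampleLabel data-source tag.
#' @param dialect named character vector mapping canonical names onto the
#'   file's column names, e.g. \code{c(SNP = "rsid", P = "pval")}. Columns
#'   already canonically named need no entry.
#' @return \code{SummaryStats}.
#' @export
readSumstats <- function(path, trait, sampleLabel = "unknown",
                         dialect = NULL) {
  if (!file.exists(path)) stop("cannot read summary statistics: ", path)
  x <- tryCatch(
    read.table(path, header = TRUE, sep = "", quote = "",
               comment.char = "", stringsAsFactors = FALSE,
               check.names = FALSE),
    error = function(e) stop("malformed summary-statistic file '", path,
                             "': ", conditionMessage(e)))
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      src <- dialect[[canon]]
      if (src %in% names(x)) names(x)[names(x) == src] <- canon
    }
  }
  if (!"SNP" %in% names(x))
    stop("no parseable rows: missing SNP column in ", path)
  out <- sumstats(x, trait = trait, sampleLabel = sampleLabel)
  if (nrow(records(out)) == 0L && nrow(x) > 0L)
    stop("no parseable rows in ", path, "; first offending row: ",
         paste(unlist(x[1, ]), collapse = "\t"))
  out
}

#' Write a summary-statistic table in the canonical TSV dialect
#'
#' Fixed column order \code{SNP CHR POS EA OA EAF BETA SE Z P N [N_STUDIES]},
#' tab-separated, '.' decimal mark, 'NA' for missing; byte-stable for a
#' given table.
#'
#' @param x \code{SummaryStats}.
#' @param path output path.
#' @param report optional path for a JSON sidecar with the load report.
#' @return \code{path}, invisibly.
#' @export
writeSumstats <- function(x, path, report = NULL) {
  stopifnot(is(x, "SummaryStats"))
  rec <- records(x)
  if (all(is.na(rec$N_STUDIES))) rec$N_STUDIES <- NULL
  write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  if (!is.null(report))
    jsonlite::write_json(loadReport(x), report, auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' Load / filter report of a summary-statistic table
#' @param x \code{SummaryStats}.
#' @return named list with counts of rows read, kept and dropped by reason.
#' @export
loadReport <- function(x) x@report

#' Reconstruct beta and SE from a z-score, allele frequency and sample size
#'
#' For a standardised trait the per-allele effect implied by a z-score is
#' recovered as \code{se = 1 / sqrt(2 * eaf * (1 - eaf) * (n + z^2))} and
#' \code{beta = z * se}. The formula depends on the frequency only through
#' \code{eaf * (1 - eaf)}, so effect-allele frequency and folded MAF give
#' identical results.
#'
#' @param z z-statistic(s).
#' @param eaf effect-allele frequency, strictly inside (0, 1).
#' @param n sample size, at least 2.
#' @return data.frame with columns \code{beta} and \code{se} (SD units).
#' @examples
#' zscoreToBeta(0, 0.5, 50)   # beta 0, se 0.2
#' @export
zscoreToBeta <- function(z, eaf, n) {
  if (any(!is.finite(eaf) | eaf <= 0 | eaf >= 1))
    stop("degenerate allele frequency: eaf must lie strictly in (0, 1)")
  if (any(!is.finite(n) | n < 2))
    stop("sample size must be at least 2")
  se <- 1 / sqrt(2 * eaf * (1 - eaf) * (n + z^2))
  data.frame(beta = z * se, se = se)
}

#' Fill BETA/SE of a table from its z-scores
#'
#' Applies \code{\link{zscoreToBeta}} to every record with Z, EAF and N
#' available; records lacking any of the three keep their existing values.
#'
#' @param x \code{SummaryStats}.
#' @return \code{SummaryStats} with BETA and SE populated.
#' @export
reconstructEffects <- function(x) {
  stopifnot(is(x, "SummaryStats"))
  rec <- records(x)
  ok <- !is.na(rec$Z) & !is.na(rec$EAF) & !is.na(rec$N) &
    rec$EAF > 0 & rec$EAF < 1 & rec$N >= 2
  if (any(ok)) {
    bs <- zscoreToBeta(rec$Z[ok], rec$EAF[ok], rec$N[ok])
    rec$BETA[ok] <- bs$beta
    rec$SE[ok] <- bs$se
  }
  initialize(x, records = rec)
}

#' Sample-size weighted z-score meta-analysis
#'
#' Combines per-SNP z-scores across tables with weights \code{sqrt(n)}:
#' \code{z_meta = sum(w_i z_i) / sqrt(sum(w_i^2))}. Before combining, each
#' study's record is aligned to the allele orientation of the first table
#' carrying the SNP (sign flip on allele swap, strand complement where
#' unambiguous); records whose alleles cannot be reconciled are dropped
#' with a reason code. The pooled record carries \code{N = sum(n_i)}, an
#' n-weighted mean EAF, the number of contributing studies
#' (\code{N_STUDIES}) and a p-value recomputed from \code{z_meta}.
#'
#' @param tables list of two or more \code{SummaryStats}.
#' @param trait trait name of the pooled table (default: first table's).
#' @return \code{SummaryStats}; the report counts dropped study records.
#' @export
metaAnalyseZ <- function(tables, trait = NULL) {
  stopifnot(length(tables) >= 2L)
  recs <- lapply(tables, records)
  allSnps <- unique(unlist(lapply(recs, `[[`, "SNP")))
  out <- vector("list", length(allSnps))
  nDropped <- 0L
  for (i in seq_along(allSnps)) {
    snp <- allSnps[i]
    rows <- lapply(recs, function(r) r[r$SNP == snp, , drop = FALSE])
    rows <- rows[vapply(rows, nrow, 0L) == 1L]
    ref <- rows[[1L]]
    zs <- ns <- eafs <- numeric()
    for (r in rows) {
      s <- alleleOrientation(ref$EA, ref$OA, r$EA, r$OA)
      if (is.na(s) || is.na(r$Z) || is.na(r$N)) { nDropped <- nDropped + 1L; next }
      swapped <- (r$EA == ref$OA || complementAllele(r$EA) == ref$OA) &&
        !(r$EA == ref$EA || complementAllele(r$EA) == ref$EA)
      zs <- c(zs, s * r$Z)
      ns <- c(ns, r$N)
      eafs <- c(eafs, if (swapped) 1 - r$EAF else r$EAF)
    }
    if (!length(zs)) next
    w <- sqrt(ns)
    zMeta <- sum(w * zs) / sqrt(sum(w^2))
    out[[i]] <- data.frame(
      SNP = snp, CHR = ref$CHR, POS = ref$POS, EA = ref$EA, OA = ref$OA,
      EAF = if (all(is.na(eafs))) NA_real_ else
        sum(ns * eafs, na.rm = TRUE) / sum(ns[!is.na(eafs)]),
      BETA = NA_real_, SE = NA_real_, Z = zMeta, P = zToP(zMeta),
      N = sum(ns), N_STUDIES = length(zs), stringsAsFactors = FALSE)
  }
  pooled <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  res <- sumstats(pooled,
                  trait = if (is.null(trait)) trait(tables[[1L]]) else trait,
                  sampleLabel = "meta")
  res@report$droppedStudyRecords <- nDropped
  res
}

#' Post-meta-analysis quality-control filter
#'
#' Retains SNPs whose minor allele frequency is at least \code{mafMin}
#' (default 0.5\%) AND that were captured by at least \code{coverageMin}
#' (default half) of the participating studies or of the maximum per-trait
#' sample size — either coverage criterion suffices. Removals are counted
#' by reason in the report.
#'
#' @param x \code{SummaryStats} with EAF and, ideally, N and/or N_STUDIES.
#' @param mafMin minimum minor-allele frequency.
#' @param coverageMin minimum coverage fraction.
#' @return filtered \code{SummaryStats} (possibly empty, with a warning).
#' @export
qcFilter <- function(x, mafMin = 0.005, coverageMin = 0.5) {
  stopifnot(is(x, "SummaryStats"))
  rec <- records(x)
  if (!nrow(rec)) return(x)
  maf <- pmin(rec$EAF, 1 - rec$EAF)
  mafOk <- !is.na(maf) & maf >= mafMin
  covStudies <- if (all(is.na(rec$N_STUDIES))) rep(NA_real_, nrow(rec)) else
    rec$N_STUDIES / max(rec$N_STUDIES, na.rm = TRUE)
  covN <- if (all(is.na(rec$N))) rep(NA_real_, nrow(rec)) else
    rec$N / max(rec$N, na.rm = TRUE)
  covOk <- (!is.na(covStudies) & covStudies >= coverageMin) |
    (!is.na(covN) & covN >= coverageMin)
  covOk[is.na(covStudies) & is.na(covN)] <- TRUE  # no coverage info: pass
  keep <- mafOk & covOk
  y <- initialize(x, records = rec[keep, , drop = FALSE])
  y@report$qc <- list(removedMaf = sum(!mafOk),
                      removedCoverage = sum(mafOk & !covOk),
                      kept = sum(keep))
  if (!any(keep)) warning("qcFilter removed every SNP for trait ", trait(x))
  validObject(y)
  y
}
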