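#' Accessors for matmr classes
#'
#' Small accessor generics so slot layout stays private: \code{records} /
#' \code{trait} for \code{SummaryStats}; \code{instruments} /
#' \code{selectionLog} for \code{InstrumentSet}; \code{harmonisedData} /
#' \code{nInstruments} for \code{HarmonisedSet}; \code{theta}, \code{se},
#' \code{ci}, \code{pvalue} for \code{MREstimate}.
#'
#' @param x an object of the documented class.
#' @return the corresponding slot contents.
#' @name accessors
#' @aliases records trait instruments selectionLog harmonisedData
#'   nInstruments theta se ci pvalue
NULL

#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname accessors
#' @export
setGeneric("trait", function(x) standardGeneric("trait"))
#' @rdname accessors
#' @export
setGeneric("instruments", function(x) standardGeneric("instruments"))
#' @rdname accessors
#' @export
setGeneric("selectionLog", function(x) standardGeneric("selectionLog"))
#' @rdname accessors
#' @export
setGeneric("harmonisedData", function(x) standardGeneric("harmonisedData"))
#' @rdname accessors
#' @export
setGeneric("nInstruments", function(x) standardGeneric("nInstruments"))
#' @rdname accessors
#' @export
setGeneric("theta", function(x) standardGeneric("theta"))
#' @rdname accessors
#' @export
setGeneric("se", function(x) standardGeneric("se"))
#' @rdname accessors
#' @export
setGeneric("ci", function(x) standardGeneric("ci"))
#' @rdname accessors
#' @export
setGeneric("pvalue", function(x) standardGeneric("pvalue"))

#' Rescale an effect from outcome-SD units to grams
#'
#' Birthweight GWAS effects are reported in standard-deviation units; the
#' conventional conversion multiplies point estimate, standard error and
#' confidence bounds by the median birthweight SD of the contributing
#' cohorts, 484 g.
#'
#' @param x a numeric vector of SD-unit quantities, or an
#'   \code{MREstimate}.
#' @param sdGrams positive scale factor (grams per outcome SD, default 484).
#' @return object of the same class with all effect quantities multiplied
#'   by \code{sdGrams}.
#' @examples
#' sdToGrams(1)               # 484
#' sdToGrams(c(0.5, 0.25, 0.75))  # linear in every component
#' @export
setGeneric("sdToGrams", function(x, sdGrams = 484) standardGeneric("sdToGrams"))

setMethod("records", "SummaryStats", function(x) x@records)
setMethod("trait", "SummaryStats", function(x) x@trait)
setMethod("instruments", "InstrumentSet", function(x) x@snps)
setMethod("selectionLog", "InstrumentSet", function(x) x@selectionLog)
setMethod("selectionLog", "HarmonisedSet", function(x) x@log)
setMethod("harmonisedData", "HarmonisedSet", function(x) x@data)
setMethod("nInstruments", "HarmonisedSet", function(x) nrow(x@data))
setMethod("nInstruments", "InstrumentSet", function(x) length(x@snps))
setMethod("theta", "MREstimate", function(x) x@theta)
setMethod("se", "MREstimate", function(x) x@se)
setMethod("ci", "MREstimate", function(x) c(x@ciLow, x@ciHigh))
setMethod("pvalue", "MREstimate", function(x) x@pval)
setMethod("theta", "MREggerFit", function(x) x@slope@theta)

setMethod("sdToGrams", "numeric", function(x, sdGrams = 484) {
  if (!is.numeric(sdGrams) || length(sdGrams) != 1L || sdGrams <= 0)
    stop("sdGrams must be a positive scalar")
  x * sdGrams
})

setMethod("sdToGrams", "MREstimate", function(x, sdGrams = 484) {
  if (!is.numeric(sdGrams) || length(sdGrams) != 1L || sdGrams <= 0)
    stop("sdGrams must be a positive scalar")
  initialize(x, theta = x@theta * sdGrams, se = x@se * sdGrams,
             ciLow = x@ciLow * sdGrams, ciHigh = x@ciHigh * sdGrams)
})
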