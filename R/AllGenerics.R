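#' @rdname accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname accessors
#' @export
setGeneric("rateUnits", function(x) standardGeneric("rateUnits"))

#' @rdname accessors
#' @export
setGeneric("rateValues", function(x, chrom = NULL) standardGeneric("rateValues"))

#' @rdname accessors
#' @export
setGeneric("densityValues", function(x, chrom = NULL)
  standardGeneric("densityValues"))

#' @rdname accessors
#' @export
setGeneric("trackBins", function(x) standardGeneric("trackBins"))

#' @rdname accessors
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @rdname accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname accessors
#' @export
setGeneric("motifName", function(x) standardGeneric("motifName"))

#' @rdname accessors
#' @export
setGeneric("motifProbs", function(x) standardGeneric("motifProbs"))

#' @rdname accessors
#' @export
setGeneric("motifLength", function(x) standardGeneric("motifLength"))

#' @rdname accessors
#' @export
setGeneric("matrixDialect", function(x) standardGeneric("matrixDialect"))

#' @rdname accessors
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))
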