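#' @rdname SpectraSet
#' @param x,object a \code{SpectraSet} (or \code{Spectrum} where documented).
#' @export
setGeneric("axisValues", function(x) standardGeneric("axisValues"))

#' @rdname SpectraSet
#' @export
setGeneric("axisKind", function(x) standardGeneric("axisKind"))

#' @rdname SpectraSet
#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))

#' @rdname SpectraSet
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' @rdname SpectraSet
#' @export
setGeneric("region", function(x) standardGeneric("region"))

#' @rdname SpectraSet
#' @param i sample index.
#' @export
setGeneric("getSpectrum", function(x, i) standardGeneric("getSpectrum"))
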