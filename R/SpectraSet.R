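#' Construct a SpectraSet
#'
#' @param axis numeric vector of axis values. Must be strictly monotone; a
#'   strictly decreasing axis (the native ordering of MIR spectra, 4000 to
#'   500 reciprocal centimetres) is reversed to ascending together with the
#'   absorbance rows.
#' @param absorbance numeric matrix, channels x samples (one column per
#'   sample), absorbance units.
#' @param concentrations numeric vector of reference lactate concentrations
#'   (mmol/L), one per sample.
#' @param region \code{"uvvis"}, \code{"nir"} or \code{"mir"}.
#' @param labels optional character vector of sample labels.
#' @return a validated [SpectraSet-class] with an ascending axis.
#' @examples
#' s <- SpectraSet(axis = 1:5, absorbance = matrix(runif(10), 5, 2),
#'                 concentrations = c(0, 1), region = "nir")
#' nSamples(s)
#' @export
SpectraSet <- function(axis, absorbance, concentrations, region,
                       labels = NULL) {
  region <- .checkRegion(region)
  if (is.vector(absorbance)) absorbance <- matrix(absorbance, ncol = 1L)
  if (nrow(absorbance) != length(axis))
    stop("absorbance must have one row per axis point (got ",
         nrow(absorbance), " rows for ", length(axis), " axis points)")
  if (ncol(absorbance) != length(concentrations))
    stop("one concentration per sample column is required")
  if (length(axis) >= 2L && all(diff(axis) < 0)) {
    axis <- rev(axis)
    absorbance <- absorbance[rev(seq_len(nrow(absorbance))), , drop = FALSE]
  }
  if (!.isMonotoneIncreasing(axis))
    stop("axis must be strictly monotone")
  if (is.null(labels))
    labels <- sprintf("sample_%02d", seq_along(concentrations))
  dimnames(absorbance) <- list(NULL, labels)
  se <- SummarizedExperiment(
    assays = S4Vectors::SimpleList(absorbance = absorbance),
    rowData = S4Vectors::DataFrame(axis = as.numeric(axis)),
    colData = S4Vectors::DataFrame(concentration = as.numeric(concentrations),
                                   row.names = labels))
  S4Vectors::metadata(se)$region <- region
  S4Vectors::metadata(se)$axisKind <- .axisKindFor(region)
  new("SpectraSet", se)
}

#' @rdname SpectraSet
#' @export
setMethod("axisValues", "SpectraSet", function(x) rowData(x)$axis)

#' @rdname SpectraSet
#' @export
setMethod("axisKind", "SpectraSet", function(x) metadata(x)$axisKind)

#' @rdname SpectraSet
#' @export
setMethod("absorbance", "SpectraSet", function(x) assay(x, "absorbance"))

#' @rdname SpectraSet
#' @export
setMethod("concentrations", "SpectraSet",
          function(x) colData(x)$concentration)

#' @rdname SpectraSet
#' @export
setMethod("region", "SpectraSet", function(x) metadata(x)$region)

#' @rdname SpectraSet
#' @export
nSamples <- function(x) ncol(x)

#' @rdname SpectraSet
#' @export
nChannels <- function(x) nrow(x)

#' @rdname SpectraSet
#' @export
setMethod("getSpectrum", "SpectraSet", function(x, i) {
  stopifnot(length(i) == 1L, i >= 1L, i <= ncol(x))
  new("Spectrum", axis = axisValues(x), axisKind = axisKind(x),
      absorbance = as.numeric(assay(x, "absorbance")[, i]),
      label = colnames(x)[i])
})

setMethod("show", "SpectraSet", function(object) {
  cc <- concentrations(object)
  ax <- axisValues(object)
  unit <- if (axisKind(object) == "wavelength_nm") "nm" else "cm^-1"
  cat("SpectraSet (", metadata(object)$region, "): ",
      ncol(object), " samples x ", nrow(object), " channels\n", sep = "")
  cat("  axis: ", ax[1], "-", ax[length(ax)], " ", unit, "\n", sep = "")
  cat("  concentrations: ", min(cc), "-", max(cc), " mmol/L\n", sep = "")
})

setMethod("show", "Spectrum", function(object) {
  cat("Spectrum '", object@label, "': ", length(object@axis),
      " points (", object@axisKind, ")\n", sep = "")
})

#' Restrict a SpectraSet to an axis window
#'
#' Keeps only axis points inside the closed interval \code{[lo, hi]}.
#'
#' @param set a [SpectraSet-class].
#' @param lo,hi window bounds in axis units, \code{lo < hi}.
#' @return the restricted \code{SpectraSet}.
#' @export
restrictToAxisWindow <- function(set, lo, hi) {
  stopifnot(is(set, "SpectraSet"))
  if (!(lo < hi)) stop("lo must be < hi")
  keep <- which(axisValues(set) >= lo & axisValues(set) <= hi)
  if (length(keep) == 0L)
    stop("window [", lo, ", ", hi, "] does not overlap the axis")
  set[keep, ]
}
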