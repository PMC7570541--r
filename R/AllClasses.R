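#' @import methods
#' @importFrom S4Vectors DataFrame metadata SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' SpectraSet: a set of absorbance spectra sharing one axis
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' set of absorbance spectra on a common, strictly increasing axis. Channels
#' (axis points) are rows; samples are columns. The single assay
#' \code{"absorbance"} is in absorbance units (AU). \code{rowData} carries the
#' axis values (nm for UV/Vis and NIR, reciprocal centimetres for MIR, always
#' stored ascending); \code{colData} carries the per-sample reference lactate
#' concentration in mmol/L.
#'
#' @slot ... inherited from \code{SummarizedExperiment}.
#' @seealso [SpectraSet()], [readSpectraCsv()], [writeSpectraCsv()]
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

setValidity("SpectraSet", function(object) {
  msg <- character()
  if (!"absorbance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'absorbance' is required")
  rd <- rowData(object)
  if (!"axis" %in% colnames(rd)) {
    msg <- c(msg, "rowData column 'axis' is required")
  } else {
    ax <- rd$axis
    if (!all(is.finite(ax))) msg <- c(msg, "axis values must be finite")
    else if (!.isMonotoneIncreasing(ax))
      msg <- c(msg, "axis must be strictly monotone increasing")
  }
  cd <- colData(object)
  if (!"concentration" %in% colnames(cd)) {
    msg <- c(msg, "colData column 'concentration' is required")
  } else {
    cc <- cd$concentration
    if (!all(is.finite(cc)) || any(cc < 0))
      msg <- c(msg, "concentrations must be finite and >= 0")
  }
  md <- metadata(object)
  if (is.null(md$region) || !md$region %in% REGIONS)
    msg <- c(msg, "metadata 'region' must be one of uvvis, nir, mir")
  if (length(msg) > 0 &&
      "absorbance" %in% SummarizedExperiment::assayNames(object)) {
    # length consistency is enforced by SummarizedExperiment itself
  }
  a <- tryCatch(assay(object, "absorbance"), error = function(e) NULL)
  if (!is.null(a) && !all(is.finite(a)))
    msg <- c(msg, "absorbance values must be finite")
  if (length(msg)) msg else TRUE
})

#' Spectrum: a single absorbance trace
#'
#' Lightweight value class for one spectrum, used for single-trace operations
#' such as peak detection and as the reference argument of [rlmsc()].
#'
#' @slot axis numeric, strictly increasing axis values.
#' @slot axisKind \code{"wavelength_nm"} or \code{"wavenumber_cm1"}.
#' @slot absorbance numeric, same length as \code{axis}, AU.
#' @slot label free-text label.
#' @export
setClass("Spectrum",
  representation(axis = "numeric", axisKind = "character",
                 absorbance = "numeric", label = "character"),
  prototype(axisKind = "wavelength_nm", label = ""))

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@axis) != length(object@absorbance))
    msg <- c(msg, "axis and absorbance must have equal length")
  if (!all(is.finite(object@axis)) || !.isMonotoneIncreasing(object@axis))
    msg <- c(msg, "axis must be finite and strictly monotone increasing")
  if (!all(is.finite(object@absorbance)))
    msg <- c(msg, "absorbance values must be finite")
  if (!object@axisKind %in% c("wavelength_nm", "wavenumber_cm1"))
    msg <- c(msg, "axisKind must be wavelength_nm or wavenumber_cm1")
  if (length(msg)) msg else TRUE
})

#' BandLibrary: absorption bands of one spectral region
#'
#' Holds the water and lactate absorption bands of one region as a data frame
#' with columns \code{center}, \code{fwhm}, \code{shape}
#' (\code{"gaussian"}/\code{"lorentzian"}), \code{absorptivity},
#' \code{component} (\code{"water"}/\code{"lactate"}), \code{bond},
#' \code{harmonicLabel} and \code{note}. For lactate bands
#' \code{absorptivity} is AU per mmol/L at band centre; for water bands it is
#' the band amplitude (AU) of the lactate-free matrix, subsequently scaled by
#' the water-displacement factor.
#'
#' @slot region one of \code{"uvvis"}, \code{"nir"}, \code{"mir"}.
#' @slot bands data.frame as described above.
#' @seealso [buildBandLibrary()]
#' @export
setClass("BandLibrary",
  representation(region = "character", bands = "data.frame"))

setValidity("BandLibrary", function(object) {
  msg <- character()
  if (!object@region %in% REGIONS) msg <- c(msg, "invalid region")
  need <- c("center", "fwhm", "shape", "absorptivity", "component", "bond",
            "harmonicLabel", "note")
  if (!all(need %in% colnames(object@bands)))
    msg <- c(msg, paste("bands must have columns:", paste(need, collapse = ", ")))
  else {
    if (any(object@bands$fwhm <= 0)) msg <- c(msg, "fwhm must be > 0")
    if (!all(object@bands$shape %in% c("gaussian", "lorentzian")))
      msg <- c(msg, "shape must be gaussian or lorentzian")
    if (!all(object@bands$component %in% c("water", "lactate", "other")))
      msg <- c(msg, "component must be water, lactate or other")
    rng <- regionGridRange(object@region)
    if (any(object@bands$center < rng[1] | object@bands$center > rng[2]))
      msg <- c(msg, "band centers must lie inside the region's axis range")
  }
  if (length(msg)) msg else TRUE
})

#' InstrumentModel: stochastic instrument imperfections
#'
#' Parameters of the per-sample noise model used by [generateSpectra()]:
#' additive white noise, a random affine baseline, a random multiplicative
#' gain, and inflated noise inside detector-saturation regions. All standard
#' deviations are in AU except \code{baselineSlopeSd} (AU per axis unit) and
#' \code{scatterSlopeSd} (dimensionless gain spread).
#'
#' @slot baselineOffsetSd,baselineSlopeSd,scatterSlopeSd,noiseSd,inflatedNoiseSd
#'   numeric scalars, all \code{>= 0}.
#' @slot saturationRegions list of \code{c(lo, hi)} axis intervals.
#' @slot seed integer seed governing every stochastic draw.
#' @seealso [instrumentModel()], [defaultInstrumentModel()]
#' @export
setClass("InstrumentModel",
  representation(baselineOffsetSd = "numeric", baselineSlopeSd = "numeric",
                 scatterSlopeSd = "numeric", noiseSd = "numeric",
                 saturationRegions = "list", inflatedNoiseSd = "numeric",
                 seed = "integer"))

setValidity("InstrumentModel", function(object) {
  sds <- c(object@baselineOffsetSd, object@baselineSlopeSd,
           object@scatterSlopeSd, object@noiseSd, object@inflatedNoiseSd)
  msg <- character()
  if (any(!is.finite(sds)) || any(sds < 0))
    msg <- c(msg, "all standard deviations must be finite and >= 0")
  ok <- vapply(object@saturationRegions,
               function(r) is.numeric(r) && length(r) == 2L && r[1] < r[2],
               logical(1))
  if (length(ok) && !all(ok))
    msg <- c(msg, "saturationRegions must be c(lo, hi) intervals with lo < hi")
  if (length(msg)) msg else TRUE
})

#' PreprocessConfig: settings for the preprocessing chain
#'
#' Region-specific settings for [preprocessPipeline()]: noise-region masks,
#' the base-spectrum subtraction and scatter-correction switches, and the
#' Savitzky-Golay filter parameters.
#'
#' @slot region one of \code{"uvvis"}, \code{"nir"}, \code{"mir"}.
#' @slot maskRegions list of \code{c(lo, hi)} closed intervals to drop.
#' @slot doBaselineSubtract,doRlmsc,doSavgol logical stage switches.
#' @slot sgWindow odd window length in points; \code{sgPolyorder} polynomial
#'   order; \code{sgDeriv} derivative order.
#' @seealso [preprocessConfig()], [defaultPreprocessConfig()]
#' @export
setClass("PreprocessConfig",
  representation(region = "character", maskRegions = "list",
                 doBaselineSubtract = "logical", doRlmsc = "logical",
                 doSavgol = "logical", sgWindow = "integer",
                 sgPolyorder = "integer", sgDeriv = "integer"))

setValidity("PreprocessConfig", function(object) {
  msg <- character()
  if (!object@region %in% REGIONS) msg <- c(msg, "invalid region")
  if (object@sgWindow %% 2L != 1L) msg <- c(msg, "sgWindow must be odd")
  if (object@sgWindow <= object@sgPolyorder)
    msg <- c(msg, "sgWindow must exceed sgPolyorder")
  if (object@sgDeriv > object@sgPolyorder)
    msg <- c(msg, "sgDeriv must not exceed sgPolyorder")
  if (object@sgDeriv < 0L || object@sgPolyorder < 0L)
    msg <- c(msg, "orders must be non-negative")
  if (length(msg)) msg else TRUE
})

#' PLSModel: a fitted PLS1 calibration model
#'
#' Mean-centred NIPALS PLS1 model. \code{weights} (W) and \code{loadings} (P)
#' have one column per latent variable, \code{yLoadings} (q) one entry per
#' latent variable; \code{regressionVector} collapses the model to a single
#' per-channel coefficient vector b so that
#' \code{yhat = (x - xMean) . b + yMean}.
#'
#' @slot xMean per-channel mean (AU); \code{yMean} mean concentration.
#' @slot weights,loadings numeric matrices (channels x nLv).
#' @slot yLoadings numeric of length nLv.
#' @slot regressionVector numeric, one coefficient per channel.
#' @slot nLv integer number of latent variables.
#' @seealso [fitPls1()], [predict][predict,PLSModel-method]
#' @export
setClass("PLSModel",
  representation(xMean = "numeric", yMean = "numeric", weights = "matrix",
                 loadings = "matrix", yLoadings = "numeric",
                 regressionVector = "numeric", nLv = "integer"))

setValidity("PLSModel", function(object) {
  msg <- character()
  if (object@nLv < 1L) msg <- c(msg, "nLv must be >= 1")
  if (ncol(object@weights) != object@nLv ||
      ncol(object@loadings) != object@nLv ||
      length(object@yLoadings) != object@nLv)
    msg <- c(msg, "W, P, q dimensions must match nLv")
  if (length(object@regressionVector) != length(object@xMean))
    msg <- c(msg, "regressionVector length must match channel count")
  if (length(msg)) msg else TRUE
})

#' CVReport: cross-validation summary of a calibration
#'
#' PRESS-per-LV curve, leave-one-out predictions and the derived accuracy
#' metrics. \code{r2} is 1 - SS_res/SS_tot computed on the cross-validated
#' predictions; \code{rmsecv} is sqrt(mean squared CV residual), mmol/L.
#'
#' @slot press numeric PRESS per candidate LV count (mmol^2/L^2); may be
#'   empty when only a fixed-LV evaluation was run.
#' @slot chosenNLv integer LV count used for the reported predictions.
#' @slot predictions,reference numeric, one value per sample (mmol/L).
#' @slot r2,rmsecv numeric scalars.
#' @seealso [loocvEvaluate()], [calibrateSpectra()], [writeCvReportJson()]
#' @export
setClass("CVReport",
  representation(press = "numeric", chosenNLv = "integer",
                 predictions = "numeric", reference = "numeric",
                 r2 = "numeric", rmsecv = "numeric"))

setValidity("CVReport", function(object) {
  msg <- character()
  if (length(object@predictions) != length(object@reference))
    msg <- c(msg, "predictions and reference must have equal length")
  if (length(object@r2) != 1L || object@r2 > 1 + 1e-12)
    msg <- c(msg, "r2 must be a scalar <= 1")
  if (length(object@rmsecv) != 1L || object@rmsecv < 0)
    msg <- c(msg, "rmsecv must be a non-negative scalar")
  if (length(msg)) msg else TRUE
})

#' RunConfig: one end-to-end pipeline run
#'
#' Configuration of [runPipeline()]: the spectral region, exactly one input
#' source (a synthetic-generator block or a CSV path), preprocessing settings,
#' calibration settings and an output directory.
#'
#' @slot region one of \code{"uvvis"}, \code{"nir"}, \code{"mir"}.
#' @slot synthetic logical; \code{TRUE} to generate input spectra.
#' @slot planKind sample plan for synthetic input (\code{"main37"}, ...).
#' @slot csvPath input CSV path (\code{NA} for synthetic input).
#' @slot seed integer seed for all randomness in the run.
#' @slot noiseScale multiplier applied to every instrument noise sd.
#' @slot preprocess a [PreprocessConfig].
#' @slot maxLv,pressTolerance calibration settings.
#' @slot outputDir artifact directory.
#' @seealso [runConfig()], [readRunConfig()], [writeRunConfig()]
#' @export
setClass("RunConfig",
  representation(region = "character", synthetic = "logical",
                 planKind = "character", csvPath = "character",
                 seed = "integer", noiseScale = "numeric",
                 preprocess = "PreprocessConfig", maxLv = "integer",
                 pressTolerance = "numeric", outputDir = "character"))

setValidity("RunConfig", function(object) {
  msg <- character()
  if (!object@region %in% REGIONS) msg <- c(msg, "invalid region")
  hasCsv <- !is.na(object@csvPath)
  if (object@synthetic == hasCsv)
    msg <- c(msg, "exactly one input source required: synthetic or csvPath")
  if (object@preprocess@region != object@region)
    msg <- c(msg, "preprocess region must match run region")
  if (object@maxLv < 1L) msg <- c(msg, "maxLv must be >= 1")
  if (object@pressTolerance < 0) msg <- c(msg, "pressTolerance must be >= 0")
  if (object@noiseScale < 0) msg <- c(msg, "noiseScale must be >= 0")
  if (length(msg)) msg else TRUE
})
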