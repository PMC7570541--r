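# Preprocessing chain: noise-region masking, base-spectrum subtraction,
# robust linear multiplicative scatter correction (RLMSC), Savitzky-Golay
# derivative filtering.

#' Construct a preprocessing configuration
#'
#' @param region \code{"uvvis"}, \code{"nir"} or \code{"mir"}.
#' @param maskRegions list of closed \code{c(lo, hi)} intervals to remove.
#' @param doBaselineSubtract subtract the 0 mmol/L base spectrum.
#' @param doRlmsc apply [rlmsc()] (off by default; see the package vignette
#'   for why per-sample scatter renormalization of baseline-subtracted
#'   Beer-Lambert spectra removes the analyte signal).
#' @param doSavgol apply the Savitzky-Golay filter.
#' @param sgWindow,sgPolyorder,sgDeriv Savitzky-Golay settings.
#' @return a [PreprocessConfig-class].
#' @export
preprocessConfig <- function(region, maskRegions = list(),
                             doBaselineSubtract = TRUE, doRlmsc = FALSE,
                             doSavgol = TRUE, sgWindow = 21L,
                             sgPolyorder = 2L, sgDeriv = 1L) {
  new("PreprocessConfig", region = .checkRegion(region),
      maskRegions = maskRegions, doBaselineSubtract = doBaselineSubtract,
      doRlmsc = doRlmsc, doSavgol = doSavgol, sgWindow = as.integer(sgWindow),
      sgPolyorder = as.integer(sgPolyorder), sgDeriv = as.integer(sgDeriv))
}

#' Default preprocessing configuration of a region
#'
#' Savitzky-Golay windows of 21 (UV/Vis), 51 (NIR) and 31 (MIR) points with
#' polynomial order 2 and derivative order 1; default masks are the
#' detector-saturation regions 1900-1960 and 2350-2600 nm (NIR) and
#' 500-700 cm^-1 (MIR), none for UV/Vis.
#'
#' @inheritParams preprocessConfig
#' @return a [PreprocessConfig-class].
#' @export
defaultPreprocessConfig <- function(region) {
  region <- .checkRegion(region)
  masks <- switch(region,
                  uvvis = list(),
                  nir = list(c(1900, 1960), c(2350, 2600)),
                  mir = list(c(500, 700)))
  win <- switch(region, uvvis = 21L, nir = 51L, mir = 31L)
  preprocessConfig(region, maskRegions = masks, sgWindow = win)
}

setMethod("show", "PreprocessConfig", function(object) {
  cat("PreprocessConfig (", object@region, "): ",
      length(object@maskRegions), " mask(s); subtract=",
      object@doBaselineSubtract, "; rlmsc=", object@doRlmsc,
      "; SG ", object@sgWindow, "/", object@sgPolyorder, "/",
      object@sgDeriv, "\n", sep = "")
})

#' Remove noise regions from a spectra set
#'
#' Drops every axis point inside any of the listed closed intervals from the
#' axis and from all samples.
#'
#' @param set a [SpectraSet-class].
#' @param regions list of \code{c(lo, hi)} intervals (inclusive endpoints).
#' @return the masked \code{SpectraSet}.
#' @export
maskNoiseRegions <- function(set, regions) {
  stopifnot(is(set, "SpectraSet"))
  if (length(regions) == 0L) return(set)
  ax <- axisValues(set)
  drop <- rep(FALSE, length(ax))
  for (r in regions) {
    if (length(r) != 2L || r[1] >= r[2])
      stop("each mask region must be c(lo, hi) with lo < hi")
    drop <- drop | (ax >= r[1] & ax <= r[2])
  }
  if (all(drop))
    stop("validation error: masking removes every axis point")
  set[!drop, ]
}

#' Subtract the base (0 mmol/L) spectrum
#'
#' Subtracts the lactate-free sample's spectrum (the mean over such samples
#' if there are several) pointwise from every sample, suppressing the large
#' common matrix absorption so that small analyte-related features become
#' visible: water-dominated channels go negative, lactate bands positive.
#' Concentrations are unchanged.
#'
#' @param set a [SpectraSet-class] containing at least one 0 mmol/L sample.
#' @return the baseline-subtracted \code{SpectraSet}.
#' @export
baselineSubtract <- function(set) {
  stopifnot(is(set, "SpectraSet"))
  zero <- which(concentrations(set) == 0)
  if (length(zero) == 0L)
    stop("precondition error: no 0 mmol/L sample to use as base spectrum")
  a <- absorbance(set)
  base <- rowMeans(a[, zero, drop = FALSE])
  SummarizedExperiment::assay(set, "absorbance") <- a - base
  validObject(set)
  set
}

# one robust affine fit x ~ a*r + b by iteratively reweighted least squares
# with the Tukey bisquare, tuning constant 4.685, initialized at OLS
.rlmscFitOne <- function(x, r, maxIter = 50L, tol = 1e-10, tune = 4.685) {
  D <- cbind(r, 1)
  beta <- qr.coef(qr(D), x)
  for (it in seq_len(maxIter)) {
    res <- x - D %*% beta
    sigma <- stats::median(abs(res)) / 0.6745
    if (sigma < 1e-14) break
    u <- res / (tune * sigma)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w > 0) < 2L) break
    sw <- sqrt(as.numeric(w))
    betaNew <- qr.coef(qr(D * sw), x * sw)
    if (max(abs(betaNew - beta)) < tol) { beta <- betaNew; break }
    beta <- betaNew
  }
  c(a = beta[1], b = beta[2])
}

#' Robust linear multiplicative scatter correction
#'
#' For each sample \code{x}, robustly fits \code{x = a * r + b} against the
#' reference spectrum \code{r} (iteratively reweighted least squares with the
#' Tukey bisquare, tuning constant 4.685, at most 50 iterations, convergence
#' when the coefficient change drops below 1e-10) and returns
#' \code{(x - b) / a}. The reference defaults to the set's mean spectrum.
#'
#' @param set a [SpectraSet-class] with at least two axis points.
#' @param reference optional [Spectrum-class] or numeric vector on the same
#'   axis.
#' @return the corrected \code{SpectraSet}, with the fitted \code{a} and
#'   \code{b} attached as metadata \code{rlmscCoefficients}.
#' @export
rlmsc <- function(set, reference = NULL) {
  stopifnot(is(set, "SpectraSet"))
  if (nrow(set) < 2L) stop("rlmsc needs at least 2 axis points")
  a <- absorbance(set)
  r <- if (is.null(reference)) rowMeans(a)
       else if (is(reference, "Spectrum")) reference@absorbance
       else as.numeric(reference)
  if (length(r) != nrow(a))
    stop("reference length must match the channel count")
  coefs <- matrix(NA_real_, ncol(a), 2L,
                  dimnames = list(colnames(a), c("a", "b")))
  out <- a
  for (j in seq_len(ncol(a))) {
    cf <- .rlmscFitOne(a[, j], r)
    if (abs(cf[1]) < 1e-12)
      stop("degenerate-sample error: sample ", j,
           " has multiplicative coefficient |a| < 1e-12")
    out[, j] <- (a[, j] - cf[2]) / cf[1]
    coefs[j, ] <- cf
  }
  SummarizedExperiment::assay(set, "absorbance") <- out
  S4Vectors::metadata(set)$rlmscCoefficients <- coefs
  set
}

#' Savitzky-Golay convolution weights
#'
#' Computes the central-window weights from first principles by solving the
#' local least-squares polynomial normal equations on the window offsets: the
#' filtered value at the window centre is the fitted polynomial's
#' \code{deriv}-th derivative there. For \code{deriv = 0} the weights sum to
#' 1; for \code{deriv >= 1} they sum to 0 (vanishing-moment identity), and
#' derivative weights scale with \code{spacing^-deriv}.
#'
#' @param window odd window length in points.
#' @param polyorder polynomial order (\code{< window}).
#' @param deriv derivative order (\code{<= polyorder}).
#' @param spacing axis step between adjacent points.
#' @return numeric weight vector of length \code{window}.
#' @export
sgCoefficients <- function(window, polyorder, deriv = 0L, spacing = 1) {
  if (window %% 2L != 1L || window <= polyorder)
    stop("validation error: window must be odd and > polyorder")
  if (deriv > polyorder || deriv < 0L)
    stop("validation error: need 0 <= deriv <= polyorder")
  h <- (window - 1L) %/% 2L
  t <- (-h:h) * spacing
  A <- outer(t, 0:polyorder, `^`)
  C <- solve(crossprod(A), t(A))       # (polyorder+1) x window
  factorial(deriv) * C[deriv + 1L, ]
}

# fit weights evaluating the deriv-th derivative at offset t0 from the first
# point of a one-sided window with offsets t (edge handling)
.sgEdgeWeights <- function(t, t0, polyorder, deriv) {
  A <- outer(t - t0, 0:polyorder, `^`)
  C <- solve(crossprod(A), t(A))
  factorial(deriv) * C[deriv + 1L, ]
}

# split an axis into contiguous uniformly spaced blocks (masking creates gaps)
.contiguousBlocks <- function(axis) {
  if (length(axis) < 2L) return(list(seq_along(axis)))
  d <- diff(axis)
  step <- min(d)
  cut <- which(d > step * 1.5)
  starts <- c(1L, cut + 1L)
  ends <- c(cut, length(axis))
  lapply(seq_along(starts), function(i) starts[i]:ends[i])
}

#' Apply a Savitzky-Golay filter to a spectra set
#'
#' The convolution runs independently inside each contiguous uniformly spaced
#' axis block (masking may have split the axis), so no information leaks
#' across masked gaps. Edges are handled by fitting the local polynomial over
#' the one-sided window and evaluating its derivative at the edge point; no
#' data are fabricated by padding.
#'
#' @param set a [SpectraSet-class].
#' @param config a [PreprocessConfig-class] supplying window, polynomial
#'   order and derivative order.
#' @return the filtered \code{SpectraSet}.
#' @export
applySavgol <- function(set, config) {
  stopifnot(is(set, "SpectraSet"), is(config, "PreprocessConfig"))
  ax <- axisValues(set)
  a <- absorbance(set)
  win <- config@sgWindow
  h <- (win - 1L) %/% 2L
  out <- a
  for (blk in .contiguousBlocks(ax)) {
    n <- length(blk)
    if (n < win)
      stop("validation error: block [", ax[blk[1]], ", ", ax[blk[n]],
           "] has ", n, " points, shorter than the SG window (", win, ")")
    x <- ax[blk]
    d <- diff(x)
    spacing <- d[1]
    if (any(abs(d - spacing) > 1e-8 * max(abs(spacing), 1)))
      stop("validation error: block [", x[1], ", ", x[n],
           "] is not uniformly spaced")
    wC <- sgCoefficients(win, config@sgPolyorder, config@sgDeriv, spacing)
    tWin <- (0:(win - 1L)) * spacing
    yBlk <- a[blk, , drop = FALSE]
    res <- matrix(0, n, ncol(yBlk))
    # interior: straight convolution with the central stencil
    for (j in seq_len(ncol(yBlk)))
      res[(h + 1L):(n - h), j] <-
        as.numeric(stats::embed(yBlk[, j], win) %*% rev(wC))
    # edges: one-sided local polynomial fits
    for (e in seq_len(h)) {
      wL <- .sgEdgeWeights(tWin, tWin[e], config@sgPolyorder, config@sgDeriv)
      wR <- .sgEdgeWeights(tWin, tWin[win - e + 1L], config@sgPolyorder,
                           config@sgDeriv)
      res[e, ] <- wL %*% yBlk[1:win, , drop = FALSE]
      res[n - e + 1L, ] <- wR %*% yBlk[(n - win + 1L):n, , drop = FALSE]
    }
    out[blk, ] <- res
  }
  SummarizedExperiment::assay(set, "absorbance") <- out
  set
}

#' Run the full preprocessing chain
#'
#' Applies, in fixed order and honouring the configuration switches:
#' noise-region masking, base-spectrum subtraction, RLMSC, Savitzky-Golay
#' filtering. Every stage is recorded in the returned log (with its
#' parameters and whether it was applied), so runs are auditable.
#'
#' @param set a [SpectraSet-class] whose region matches \code{config}.
#' @param config a [PreprocessConfig-class].
#' @return list with elements \code{set} (the processed [SpectraSet-class])
#'   and \code{log} (character vector, one entry per stage).
#' @export
preprocessPipeline <- function(set, config) {
  stopifnot(is(set, "SpectraSet"), is(config, "PreprocessConfig"))
  if (region(set) != config@region)
    stop("config region (", config@region, ") does not match set region (",
         region(set), ")")
  log <- character()
  note <- function(stage, applied, detail)
    sprintf("%s [%s] %s", stage, if (applied) "applied" else "skipped", detail)

  doMask <- length(config@maskRegions) > 0L
  if (doMask) set <- maskNoiseRegions(set, config@maskRegions)
  log <- c(log, note("mask_noise_regions", doMask,
                     paste0("regions=", length(config@maskRegions))))

  if (config@doBaselineSubtract) set <- baselineSubtract(set)
  log <- c(log, note("baseline_subtract", config@doBaselineSubtract,
                     "base = mean of 0 mmol/L samples"))

  if (config@doRlmsc) set <- rlmsc(set)
  log <- c(log, note("rlmsc", config@doRlmsc,
                     "Tukey bisquare c=4.685, reference = mean spectrum"))

  if (config@doSavgol) set <- applySavgol(set, config)
  log <- c(log, note("savitzky_golay", config@doSavgol,
                     sprintf("window=%d polyorder=%d deriv=%d",
                             config@sgWindow, config@sgPolyorder,
                             config@sgDeriv)))
  list(set = set, log = log)
}

#' Serialize a preprocessing configuration as YAML
#'
#' @param config a [PreprocessConfig-class]; \code{path} a file path.
#' @return \code{readPreprocessConfigYaml} returns a
#'   \code{PreprocessConfig}; the writer invisibly returns \code{path}.
#' @export
writePreprocessConfigYaml <- function(config, path) {
  stopifnot(is(config, "PreprocessConfig"))
  yaml::write_yaml(list(
    region = config@region,
    maskRegions = lapply(config@maskRegions, as.numeric),
    doBaselineSubtract = config@doBaselineSubtract,
    doRlmsc = config@doRlmsc, doSavgol = config@doSavgol,
    sgWindow = config@sgWindow, sgPolyorder = config@sgPolyorder,
    sgDeriv = config@sgDeriv), path)
  invisible(path)
}

#' @rdname writePreprocessConfigYaml
#' @export
readPreprocessConfigYaml <- function(path) {
  y <- yaml::read_yaml(path)
  preprocessConfig(region = y$region,
                   maskRegions = lapply(y$maskRegions, as.numeric),
                   doBaselineSubtract = y$doBaselineSubtract,
                   doRlmsc = y$doRlmsc, doSavgol = y$doSavgol,
                   sgWindow = y$sgWindow,
                   sgPolyorder = y$sgPolyorder, sgDeriv = y$sgDeriv)
}
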