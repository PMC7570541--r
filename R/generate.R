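# Beer-Lambert synthetic-spectra generator.
#
# For a sample of lactate concentration c (mmol/L), the noise-free trace is
#   A(x) = sum_water A_b(x) * w(c) + sum_lactate eps_b(x) * c
# with the water-displacement factor w(c) = 1 - c / 600 reflecting equivolume
# serial dilution from a 600 mmol/L stock: adding lactate stock displaces an
# equal volume of aqueous matrix, so the water signal falls linearly in c.
# Instrument imperfections are then applied per sample:
#   gain * (trace + baseline(x)) + noise(x)
# with noise sd inflated inside the detector-saturation regions.

C_STOCK <- 600  # stock concentration, mmol/L

#' Construct an instrument noise model
#'
#' @param baselineOffsetSd sd of the per-sample constant baseline offset, AU.
#' @param baselineSlopeSd sd of the per-sample baseline slope, AU per axis
#'   unit (applied around the axis midpoint).
#' @param scatterSlopeSd sd of the per-sample multiplicative gain around 1.
#' @param noiseSd sd of additive white noise, AU.
#' @param saturationRegions list of \code{c(lo, hi)} axis intervals in which
#'   the noise sd is \code{inflatedNoiseSd} instead of \code{noiseSd}.
#' @param inflatedNoiseSd noise sd inside the saturation regions, AU.
#' @param seed integer; the single seed governing all stochastic draws.
#' @return an [InstrumentModel-class].
#' @export
instrumentModel <- function(baselineOffsetSd = 0, baselineSlopeSd = 0,
                            scatterSlopeSd = 0, noiseSd = 0,
                            saturationRegions = list(),
                            inflatedNoiseSd = noiseSd, seed = 1L) {
  new("InstrumentModel", baselineOffsetSd = baselineOffsetSd,
      baselineSlopeSd = baselineSlopeSd, scatterSlopeSd = scatterSlopeSd,
      noiseSd = noiseSd, saturationRegions = saturationRegions,
      inflatedNoiseSd = inflatedNoiseSd, seed = as.integer(seed))
}

#' Default instrument model of a region
#'
#' Noise magnitudes typical of a research-grade dual-beam spectrophotometer
#' and a bench FTIR: 5e-4 AU white noise (5e-2 AU inside the
#' water-saturation regions), 2e-3 AU baseline offset spread, a gentle random
#' baseline tilt and a 0.1 percent multiplicative gain spread (the
#' sample-to-sample photometric repeatability class of a baseline-corrected
#' dual-beam instrument). Saturation
#' regions are 1900-1960 and 2350-2600 nm (NIR) and 500-700 cm^-1 (MIR).
#'
#' @param region \code{"uvvis"}, \code{"nir"} or \code{"mir"}.
#' @param seed integer seed.
#' @param noiseScale multiplier applied to every standard deviation;
#'   \code{0} gives a noise-free instrument.
#' @return an [InstrumentModel-class].
#' @export
defaultInstrumentModel <- function(region, seed = 1L, noiseScale = 1) {
  region <- .checkRegion(region)
  sat <- switch(region,
                uvvis = list(),
                nir = list(c(1900, 1960), c(2350, 2600)),
                mir = list(c(500, 700)))
  slopeSd <- if (region == "mir") 5e-7 else 1e-6
  instrumentModel(baselineOffsetSd = 2e-3 * noiseScale,
                  baselineSlopeSd = slopeSd * noiseScale,
                  scatterSlopeSd = 1e-3 * noiseScale,
                  noiseSd = 5e-4 * noiseScale,
                  saturationRegions = sat,
                  inflatedNoiseSd = 5e-2 * noiseScale,
                  seed = seed)
}

setMethod("show", "InstrumentModel", function(object) {
  cat("InstrumentModel: noiseSd=", object@noiseSd,
      " AU (inflated ", object@inflatedNoiseSd, " in ",
      length(object@saturationRegions), " region(s)), gain sd=",
      object@scatterSlopeSd, ", seed=", object@seed, "\n", sep = "")
})

#' Water-displacement factor
#'
#' Fraction of the aqueous-matrix signal remaining at lactate concentration
#' \code{c} under equivolume serial dilution from the 600 mmol/L stock:
#' \code{1 - c/600}.
#'
#' @param concentration mmol/L.
#' @return dimensionless factor in \code{[0, 1]} over the stock range.
#' @export
waterDisplacement <- function(concentration) 1 - concentration / C_STOCK

# band profile with unit amplitude at the centre
.bandProfile <- function(axis, center, fwhm, shape) {
  if (shape == "gaussian") {
    exp(-4 * log(2) * ((axis - center) / fwhm)^2)
  } else {  # lorentzian
    1 / (1 + (2 * (axis - center) / fwhm)^2)
  }
}

# summed component traces of a library on an axis (water at w(c)=1, lactate
# per unit concentration)
.componentTraces <- function(library, axis) {
  tab <- bands(library)
  water <- numeric(length(axis))
  lactate <- numeric(length(axis))
  for (i in seq_len(nrow(tab))) {
    prof <- tab$absorptivity[i] *
      .bandProfile(axis, tab$center[i], tab$fwhm[i], tab$shape[i])
    if (tab$component[i] == "water") water <- water + prof
    else lactate <- lactate + prof
  }
  list(water = water, lactate = lactate)
}

#' Generate a synthetic spectra set
#'
#' Renders one absorbance spectrum per plan entry on the region's grid using
#' the Beer-Lambert band construction described above, then applies the
#' instrument model. All randomness flows from \code{instrument@seed}; equal
#' inputs give bit-identical output and the caller's RNG state is left
#' untouched.
#'
#' @param plan numeric concentration vector (see [buildSamplePlan()]).
#' @param library a [BandLibrary-class].
#' @param instrument an [InstrumentModel-class].
#' @param grid optional axis vector; defaults to [regionGrid()] of the
#'   library's region and must match it.
#' @return a [SpectraSet-class].
#' @examples
#' set <- generateSpectra(buildSamplePlan("main37"), buildBandLibrary("nir"),
#'                        defaultInstrumentModel("nir", seed = 7))
#' set
#' @export
generateSpectra <- function(plan, library, instrument = NULL, grid = NULL) {
  stopifnot(is(library, "BandLibrary"))
  if (is.null(instrument)) instrument <- instrumentModel(seed = 1L)
  stopifnot(is(instrument, "InstrumentModel"))
  regionAxis <- regionGrid(library@region)
  if (is.null(grid)) grid <- regionAxis
  if (length(grid) != length(regionAxis) || !isTRUE(all.equal(grid, regionAxis)))
    stop("validation error: grid does not match the ", library@region,
         " region grid")
  if (length(plan) < 1L) stop("validation error: empty sample plan")
  if (any(plan < 0)) stop("validation error: negative concentration in plan")
  for (r in instrument@saturationRegions)
    if (r[1] < grid[1] || r[2] > grid[length(grid)])
      stop("saturation region [", r[1], ", ", r[2], "] outside the axis range")

  comp <- .componentTraces(library, grid)
  sdVec <- rep(instrument@noiseSd, length(grid))
  for (r in instrument@saturationRegions)
    sdVec[grid >= r[1] & grid <= r[2]] <- instrument@inflatedNoiseSd
  mid <- mean(range(grid))

  mat <- .withSeed(instrument@seed, {
    out <- matrix(0, nrow = length(grid), ncol = length(plan))
    for (j in seq_along(plan)) {
      c_j <- plan[j]
      clean <- comp$water * waterDisplacement(c_j) + comp$lactate * c_j
      gain <- 1 + stats::rnorm(1, 0, instrument@scatterSlopeSd)
      offset <- stats::rnorm(1, 0, instrument@baselineOffsetSd)
      slope <- stats::rnorm(1, 0, instrument@baselineSlopeSd)
      noise <- stats::rnorm(length(grid), 0, 1) * sdVec
      out[, j] <- gain * (clean + offset + slope * (grid - mid)) + noise
    }
    out
  })
  SpectraSet(axis = grid, absorbance = mat, concentrations = plan,
             region = library@region)
}
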