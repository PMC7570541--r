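# Region grids and the absorption-band library.
#
# Band widths and intensities are not tabulated in published peak lists; the
# defaults below are chosen once so that at 20 mmol/L the lactate band
# amplitudes are ~1e-3 of the dominant water band of the region (the regime
# in which the analyte signal is barely noticeable by eye and multivariate
# calibration is required). All values are collected in one constants table
# per region.

#' Acquisition grid of a spectral region
#'
#' UV/Vis: 300-800 nm at 1 nm; NIR: 800-2600 nm at 1 nm; MIR: 500-4000
#' reciprocal centimetres at 1 cm^-1 (stored ascending).
#'
#' @param region \code{"uvvis"}, \code{"nir"} or \code{"mir"}.
#' @return numeric axis vector.
#' @export
regionGrid <- function(region) {
  region <- .checkRegion(region)
  switch(region,
         uvvis = seq(300, 800, by = 1),
         nir = seq(800, 2600, by = 1),
         mir = seq(500, 4000, by = 1))
}

#' @rdname regionGrid
#' @export
regionGridRange <- function(region) range(regionGrid(region))

.bandRow <- function(center, fwhm, absorptivity, component, bond,
                     harmonicLabel = "", note = "", shape = "gaussian") {
  data.frame(center = center, fwhm = fwhm, shape = shape,
             absorptivity = absorptivity, component = component, bond = bond,
             harmonicLabel = harmonicLabel, note = note,
             stringsAsFactors = FALSE)
}

.uvvisBands <- function() rbind(
  .bandRow(310, 60, 0.0250, "water", "O–H / UV absorption edge"),
  .bandRow(401, 30, 0.0006, "water", "O–H stretch", "8th harmonic"),
  .bandRow(449, 35, 0.0010, "water", "O–H stretch", "7th harmonic"),
  .bandRow(485, 35, 0.0015, "water",
           "O–H stretch and bend (ν3)", "6th harmonic", "text-only"),
  .bandRow(513, 35, 0.0020, "water",
           "O–H stretch (ν1/ν3)", "6th harmonic"),
  .bandRow(605, 40, 0.0040, "water", "O–H stretch", "5th harmonic"),
  .bandRow(662, 45, 0.0060, "water",
           "O–H stretch and bend (ν3)", "4th harmonic", "text-only"),
  .bandRow(742, 50, 0.0120, "water",
           "O–H stretch (ν1/ν3)", "4th harmonic"),
  .bandRow(747, 25, 1e-7, "lactate", "lactate electronic absorption", "",
           "amplitude far below the water bands"))

.nirBands <- function() rbind(
  .bandRow(970, 60, 0.045, "water", "O–H stretch", "2nd overtone"),
  .bandRow(1180, 90, 0.100, "water", "O–H stretch", "2nd overtone"),
  .bandRow(1450, 110, 1.200, "water", "O–H stretch", "1st overtone"),
  .bandRow(1920, 160, 2.600, "water",
           "O–H stretch with O–H bend", "combination"),
  .bandRow(1215, 30, 4e-5, "lactate", "C–H stretching", "2nd C–H overtone"),
  .bandRow(1684, 40, 6e-5, "lactate", "C–H stretching", "1st C–H overtone"),
  .bandRow(1730, 40, 7e-5, "lactate", "C–H stretching", "1st C–H overtone"),
  .bandRow(2259, 35, 9e-5, "lactate",
           "combination of C–H stretch with C–H bend", "combination"),
  .bandRow(2299, 35, 8e-5, "lactate",
           "combination of C–H stretch with C–H bend", "combination"))

.mirBands <- function() rbind(
  .bandRow(1638, 80, 0.350, "water",
           "O–H bend (overlapping C=O stretch region)", "fundamental"),
  .bandRow(3283, 300, 1.000, "water", "O–H stretch", "fundamental"),
  # fingerprint region (<= 1500 cm^-1)
  .bandRow(779, 25, 3.0e-5, "lactate", "C–H bending", "fingerprint"),
  .bandRow(854, 25, 3.5e-5, "lactate", "C–H bending", "fingerprint"),
  .bandRow(940, 28, 3.0e-5, "lactate", "C–C stretch", "fingerprint"),
  .bandRow(1040, 30, 5.0e-5, "lactate", "C–O stretch", "fingerprint"),
  .bandRow(1126, 28, 5.5e-5, "lactate", "C–O / C–OH stretch", "fingerprint"),
  .bandRow(1157, 26, 4.0e-5, "lactate", "C–OH stretch", "fingerprint"),
  .bandRow(1315, 30, 3.5e-5, "lactate", "CH3 stretch (medium)", "fingerprint"),
  .bandRow(1365, 30, 4.5e-5, "lactate", "CH3 stretch (medium)", "fingerprint"),
  .bandRow(1416, 30, 5.0e-5, "lactate", "CH3 stretch (medium)", "fingerprint"),
  .bandRow(1455, 30, 4.5e-5, "lactate", "CH3 stretch (medium)", "fingerprint"),
  # diagnostic region
  .bandRow(2852, 40, 3.0e-5, "lactate", "C–H stretching", "diagnostic"),
  .bandRow(2930, 45, 4.5e-5, "lactate", "CH3 symmetric stretch", "diagnostic"),
  .bandRow(2988, 45, 4.0e-5, "lactate", "CH3 asymmetric stretch", "diagnostic"),
  .bandRow(3159, 60, 3.0e-5, "lactate", "C–H stretch (broad)", "diagnostic"))

#' Build the absorption-band library of a region
#'
#' Returns every published water (O-H harmonic/overtone/combination) and
#' lactate (C-H / C-C / C-O / CH3 / carboxylate-region) band of the region,
#' with the package's documented default widths and intensities. Water-band
#' \code{absorptivity} is the amplitude (AU) of the lactate-free matrix;
#' lactate-band \code{absorptivity} is AU per mmol/L at band centre.
#'
#' @param region \code{"uvvis"}, \code{"nir"} or \code{"mir"}.
#' @return a [BandLibrary-class].
#' @examples
#' lib <- buildBandLibrary("nir")
#' subset(bands(lib), component == "lactate")$center
#' @export
buildBandLibrary <- function(region) {
  region <- .checkRegion(region)
  tab <- switch(region, uvvis = .uvvisBands(), nir = .nirBands(),
                mir = .mirBands())
  new("BandLibrary", region = region, bands = tab)
}

#' @rdname buildBandLibrary
#' @param library a \code{BandLibrary}.
#' @export
bands <- function(library) {
  stopifnot(is(library, "BandLibrary"))
  library@bands
}

setMethod("show", "BandLibrary", function(object) {
  tab <- object@bands
  cat("BandLibrary (", object@region, "): ",
      sum(tab$component == "water"), " water + ",
      sum(tab$component == "lactate"), " lactate bands\n", sep = "")
})

#' Dump or load a band library as CSV
#'
#' @param library a [BandLibrary-class]; \code{path} a file path;
#'   \code{region} the region of the library being read.
#' @return \code{readBandLibraryCsv} returns a \code{BandLibrary};
#'   \code{writeBandLibraryCsv} invisibly returns \code{path}.
#' @export
writeBandLibraryCsv <- function(library, path) {
  stopifnot(is(library, "BandLibrary"))
  utils::write.csv(library@bands, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBandLibraryCsv
#' @export
readBandLibraryCsv <- function(path, region) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("harmonicLabel", "note", "bond"))
    tab[[col]] <- ifelse(is.na(tab[[col]]), "", as.character(tab[[col]]))
  new("BandLibrary", region = .checkRegion(region), bands = tab)
}
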