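# Sample plans and preparation arithmetic for the serial-dilution design:
# 37 equivolume samples of sodium lactate in isotonic PBS spanning
# 0-20 mmol/L, diluted from a 600 mmol/L stock.

#' Molar mass of sodium L-lactate (C3H5NaO3), g/mol
#'
#' Computed from standard atomic weights and rounded to the commonly
#' tabulated value.
#' @export
naLacMolarMass <- 112.06

#' Build a sample concentration plan
#'
#' \code{"main37"} is the calibration design: 21 levels from 0 to 5 mmol/L in
#' 0.25 mmol/L steps followed by 16 levels from 5 to 20 mmol/L in 1 mmol/L
#' steps (5 mmol/L appears in both sub-grids as two distinct physical
#' samples, giving 37 in total). \code{"hc6"} is the high-concentration
#' validation set \{100, ..., 600\} mmol/L.
#'
#' @param kind \code{"main37"}, \code{"hc6"} or \code{"custom"}.
#' @param customLevels numeric vector of levels, required iff
#'   \code{kind = "custom"}.
#' @return numeric vector of concentrations (mmol/L).
#' @examples
#' length(buildSamplePlan("main37"))  # 37
#' @export
buildSamplePlan <- function(kind = c("main37", "hc6", "custom"),
                            customLevels = NULL) {
  kind <- match.arg(kind)
  if (kind == "custom") {
    if (is.null(customLevels) || length(customLevels) == 0L)
      stop("validation error: custom plan requires a non-empty customLevels")
    if (any(!is.finite(customLevels)) || any(customLevels < 0))
      stop("validation error: custom levels must be finite and >= 0")
    return(as.numeric(customLevels))
  }
  if (!is.null(customLevels))
    stop("customLevels is only allowed with kind = 'custom'")
  switch(kind,
         main37 = c(seq(0, 5, by = 0.25), seq(5, 20, by = 1)),
         hc6 = seq(100, 600, by = 100))
}

#' Mass of solute needed for a stock solution
#'
#' \code{concentration / 1000 * volume * molarMass} grams; e.g. a 600 mmol/L
#' sodium lactate stock in one litre requires 67.236 g of powder.
#'
#' @param concentration target concentration, mmol/L.
#' @param volume solution volume, L.
#' @param molarMass solute molar mass, g/mol (defaults to sodium lactate).
#' @return mass in grams.
#' @export
stockMassFor <- function(concentration, volume, molarMass = naLacMolarMass) {
  vals <- c(concentration, volume, molarMass)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("validation error: concentration, volume and molarMass must be > 0")
  concentration / 1000 * volume * molarMass
}

#' Number of internal reflections in an ATR crystal
#'
#' For a trough-plate ATR crystal of given length and thickness at a given
#' effective angle of incidence, the beam makes
#' \code{floor(length / (2 * thickness * tan(angle)))} reflections; the
#' 80 mm x 4 mm ZnSe crystal at 45 degrees gives 10.
#'
#' @param crystalLength,crystalThickness mm, both > 0.
#' @param incidenceAngle degrees, strictly between 0 and 90.
#' @return integer reflection count.
#' @export
atrReflectionCount <- function(crystalLength, crystalThickness,
                               incidenceAngle) {
  if (!is.finite(incidenceAngle) || incidenceAngle <= 0 ||
      incidenceAngle >= 90)
    stop("validation error: incidenceAngle must be in (0, 90) degrees")
  if (crystalLength <= 0 || crystalThickness <= 0)
    stop("validation error: crystal dimensions must be > 0")
  as.integer(floor(crystalLength /
                     (2 * crystalThickness * tanpi(incidenceAngle / 180))))
}
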