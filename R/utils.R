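# internal helpers shared across modules

REGIONS <- c("uvvis", "nir", "mir")

#' @keywords internal
.axisKindFor <- function(region) {
  switch(region, uvvis = "wavelength_nm", nir = "wavelength_nm",
         mir = "wavenumber_cm1",
         stop("unknown region '", region, "'; expected one of ",
              paste(REGIONS, collapse = ", ")))
}

#' @keywords internal
.checkRegion <- function(region) {
  if (!is.character(region) || length(region) != 1L || !region %in% REGIONS)
    stop("region must be one of ", paste(REGIONS, collapse = ", "))
  region
}

# run expr with a fixed RNG seed, restoring the caller's RNG state afterwards
#' @keywords internal
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# full-precision number formatting so CSV round trips are bit-exact
#' @keywords internal
.fmtNum <- function(x) sprintf("%.17g", x)

#' @keywords internal
.isMonotoneIncreasing <- function(x) length(x) < 2L || all(diff(x) > 0)
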