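# Wide-CSV interchange: column 1 = axis, one column per sample, header row =
# reference concentrations (mmol/L). UTF-8, "." decimal separator.

#' Read a spectra set from wide CSV
#'
#' The expected layout is the one produced by [writeSpectraCsv()]: a header
#' row whose first cell names the axis and whose remaining cells are the
#' per-sample reference concentrations, followed by one numeric row per axis
#' point. A descending axis (native MIR ordering) is normalized to ascending.
#'
#' @param path CSV file path.
#' @param region \code{"uvvis"}, \code{"nir"} or \code{"mir"}.
#' @return a [SpectraSet-class].
#' @export
readSpectraCsv <- function(path, region) {
  region <- .checkRegion(region)
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) != 1L)
    stop("format error: ragged rows in ", path, " (rows with ",
         paste(unique(nf), collapse = ", "), " fields)")
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  if (length(header) < 2L)
    stop("format error: need an axis column and at least one sample column")
  conc <- suppressWarnings(as.numeric(header[-1]))
  if (any(is.na(conc)))
    stop("format error: header cell ", which(is.na(conc))[1] + 1L,
         " is not a parseable concentration")
  if (any(conc < 0)) stop("validation error: negative concentration in header")
  body <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                          colClasses = "character")
  mat <- matrix(NA_real_, nrow(body), ncol(body))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    if (any(is.na(v))) {
      i <- which(is.na(v))[1]
      stop("format error: non-numeric cell at data row ", i, ", column ", j,
           " ('", body[i, j], "')")
    }
    mat[, j] <- v
  }
  SpectraSet(axis = mat[, 1], absorbance = mat[, -1, drop = FALSE],
             concentrations = conc, region = region)
}

#' Write a spectra set to wide CSV
#'
#' Numbers are written with 17 significant digits so a write/read round trip
#' reproduces the set exactly.
#'
#' @param set a [SpectraSet-class] with at least one sample.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeSpectraCsv <- function(set, path) {
  stopifnot(is(set, "SpectraSet"))
  if (ncol(set) < 1L) stop("validation error: set has no samples")
  axisLabel <- axisKind(set)
  header <- paste(c(axisLabel, .fmtNum(concentrations(set))), collapse = ",")
  body <- cbind(.fmtNum(axisValues(set)),
                matrix(.fmtNum(absorbance(set)), nrow = nrow(set)))
  lines <- c(header, apply(body, 1L, paste, collapse = ","))
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e) stop("I/O error opening ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
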