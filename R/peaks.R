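# Peak detection, band assignment and linearity checks.

#' Detect absorption peaks in a spectrum
#'
#' Local extrema of the requested polarity whose prominence (height above the
#' higher of the two flanking valleys, the standard topographic definition)
#' reaches \code{minProminence}. Baseline-subtracted spectra show matrix
#' (water) bands as negative-going peaks, hence the polarity argument.
#'
#' @param spectrum a [Spectrum-class] (or a one-sample [SpectraSet-class]).
#' @param minProminence prominence threshold, AU. Default: 3 times the
#'   median absolute deviation of the differenced signal, a simple
#'   noise-floor estimate.
#' @param polarity \code{"positive"}, \code{"negative"} or \code{"both"}.
#' @return data.frame with one row per call: \code{position}, \code{height},
#'   \code{prominence}, \code{polarity}, plus empty assignment columns
#'   (filled by [assignBands()]), sorted by position.
#' @export
detectPeaks <- function(spectrum, minProminence = NULL,
                        polarity = c("positive", "negative", "both")) {
  polarity <- match.arg(polarity)
  if (is(spectrum, "SpectraSet")) {
    stopifnot(ncol(spectrum) == 1L)
    spectrum <- getSpectrum(spectrum, 1L)
  }
  stopifnot(is(spectrum, "Spectrum"))
  x <- spectrum@axis
  y <- spectrum@absorbance
  if (length(x) < 3L) stop("need at least 3 axis points")
  if (is.null(minProminence))
    minProminence <- 3 * stats::mad(diff(y))
  one <- function(sig, pol) {
    n <- length(sig)
    # >= on the right keeps one call per flat-topped (plateau) maximum
    idx <- which(sig[2:(n - 1)] > sig[1:(n - 2)] &
                   sig[2:(n - 1)] >= sig[3:n]) + 1L
    if (length(idx) == 0L) return(NULL)
    prom <- vapply(idx, function(i) .prominence(sig, i), numeric(1))
    keep <- prom >= minProminence
    if (!any(keep)) return(NULL)
    data.frame(position = x[idx[keep]],
               height = y[idx[keep]],
               prominence = prom[keep],
               polarity = pol,
               stringsAsFactors = FALSE)
  }
  out <- NULL
  if (polarity %in% c("positive", "both")) out <- one(y, "positive")
  if (polarity %in% c("negative", "both"))
    out <- rbind(out, one(-y, "negative"))
  if (is.null(out))
    out <- data.frame(position = numeric(), height = numeric(),
                      prominence = numeric(), polarity = character(),
                      stringsAsFactors = FALSE)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out$assignment <- NA_character_
  out$component <- NA_character_
  out$assignmentDistance <- NA_real_
  out
}

# topographic prominence of the local maximum at index i of signal sig
.prominence <- function(sig, i) {
  n <- length(sig)
  peak <- sig[i]
  leftMin <- peak
  j <- i - 1L
  while (j >= 1L && sig[j] <= peak) {
    if (sig[j] < leftMin) leftMin <- sig[j]
    j <- j - 1L
  }
  if (j < 1L) leftMin <- min(sig[1:i])
  rightMin <- peak
  j <- i + 1L
  while (j <= n && sig[j] <= peak) {
    if (sig[j] < rightMin) rightMin <- sig[j]
    j <- j + 1L
  }
  if (j > n) rightMin <- min(sig[i:n])
  peak - max(leftMin, rightMin)
}

#' Assign detected peaks to library bands
#'
#' Matches each peak to the nearest band of the library within
#' \code{tolerance}; unmatched peaks keep an empty assignment. A band may
#' match several peaks (such calls are flagged in the \code{note} column).
#'
#' @param calls data.frame from [detectPeaks()].
#' @param library a [BandLibrary-class].
#' @param tolerance maximum position-to-centre distance, axis units
#'   (default 10, narrower than any inter-band gap in the library).
#' @return \code{calls} with \code{assignment} (bond text),
#'   \code{component} and \code{assignmentDistance} filled where matched,
#'   plus a \code{note} column flagging shared bands.
#' @export
assignBands <- function(calls, library, tolerance = 10) {
  stopifnot(is(library, "BandLibrary"), tolerance > 0)
  tab <- bands(library)
  calls$note <- ""
  if (nrow(calls) == 0L) return(calls)
  matched <- integer(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    d <- abs(tab$center - calls$position[i])
    j <- which.min(d)
    if (d[j] <= tolerance) {
      calls$assignment[i] <- tab$bond[j]
      calls$component[i] <- tab$component[j]
      calls$assignmentDistance[i] <- d[j]
      matched[i] <- j
    }
  }
  dup <- matched[duplicated(matched) & matched > 0L]
  calls$note[matched %in% dup] <- "band shared by multiple calls"
  calls
}

#' Absorbance-versus-concentration linearity at a band
#'
#' Ordinary least-squares line of the maximum absorbance inside
#' \code{center +/- halfWindow} against the reference concentration, the
#' check used to confirm that identified peaks scale with analyte level.
#'
#' @param set a [SpectraSet-class] with at least 3 samples.
#' @param center band centre, axis units.
#' @param halfWindow half-width of the search window, axis units.
#' @return list with \code{slope} (AU per mmol/L), \code{intercept} (AU) and
#'   \code{r2}.
#' @export
linearityCheck <- function(set, center, halfWindow) {
  stopifnot(is(set, "SpectraSet"))
  if (ncol(set) < 3L)
    stop("validation error: need at least 3 samples")
  ax <- axisValues(set)
  keep <- which(ax >= center - halfWindow & ax <= center + halfWindow)
  if (length(keep) == 0L) stop("window lies outside the axis")
  amax <- apply(absorbance(set)[keep, , drop = FALSE], 2L, max)
  conc <- concentrations(set)
  fit <- stats::lm(amax ~ conc)
  ss <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = ss$r.squared)
}

#' Export a peak table as CSV
#'
#' @param calls data.frame from [detectPeaks()]/[assignBands()].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writePeakTableCsv <- function(calls, path) {
  utils::write.csv(calls, path, row.names = FALSE)
  invisible(path)
}
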