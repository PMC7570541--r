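# From-scratch PLS1 calibration: NIPALS extraction of latent variables,
# PRESS-based latent-variable selection, leave-one-out cross-validation.

# core NIPALS loop on already-centred X, y; returns W, P, q.
# strict = FALSE truncates at the achievable rank instead of erroring (used
# by PRESS computation, where a noiseless fold may exhaust before maxLv).
.nipals <- function(Xc, yc, nLv, strict = TRUE) {
  P <- ncol(Xc)
  W <- matrix(0, P, nLv)
  Pl <- matrix(0, P, nLv)
  q <- numeric(nLv)
  scale0 <- max(sqrt(sum(crossprod(Xc, yc)^2)), 1e-30)
  for (k in seq_len(nLv)) {
    w <- crossprod(Xc, yc)                      # X'y
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(scale0, 1)) {
      if (strict)
        stop("rank-exhausted error: X'y vanished at latent variable ", k,
             "; only ", k - 1L, " latent variable(s) are achievable")
      nLv <- k - 1L
      return(list(W = W[, seq_len(nLv), drop = FALSE],
                  P = Pl[, seq_len(nLv), drop = FALSE],
                  q = q[seq_len(nLv)]))
    }
    w <- w / nw
    t <- as.numeric(Xc %*% w)
    tt <- sum(t^2)
    if (tt < 1e-300)
      stop("rank-exhausted error: zero-variance score at latent variable ", k)
    p <- as.numeric(crossprod(Xc, t)) / tt
    qk <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, p)
    yc <- yc - qk * t
    W[, k] <- w
    Pl[, k] <- p
    q[k] <- qk
  }
  list(W = W, P = Pl, q = q)
}

#' Fit a PLS1 calibration model (NIPALS)
#'
#' Mean-centres \code{X} and \code{y} and extracts \code{nLv} latent
#' variables by the NIPALS recursion: \code{w = X'y/||X'y||},
#' \code{t = Xw}, \code{p = X't/t't}, \code{q = y't/t't}, then deflation
#' \code{X <- X - t p'}, \code{y <- y - q t}. The regression vector is
#' \code{W (P'W)^{-1} q}. Successive score vectors are mutually orthogonal.
#'
#' @param X numeric matrix, samples x channels (AU).
#' @param y numeric vector of reference concentrations, mmol/L.
#' @param nLv number of latent variables, \code{1 <= nLv <= min(N-1, P)}.
#' @return a [PLSModel-class].
#' @export
fitPls1 <- function(X, y, nLv) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  N <- nrow(X)
  if (N < 2L || length(y) != N)
    stop("X needs >= 2 rows and one y value per row")
  if (stats::var(y) == 0)
    stop("validation error: y has zero variance")
  nLv <- as.integer(nLv)
  if (nLv < 1L || nLv > min(N - 1L, ncol(X)))
    stop("validation error: nLv must be in [1, min(N-1, channels)] = [1, ",
         min(N - 1L, ncol(X)), "]")
  xMean <- colMeans(X)
  yMean <- mean(y)
  fit <- .nipals(sweep(X, 2L, xMean), y - yMean, nLv)
  b <- as.numeric(fit$W %*% solve(crossprod(fit$P, fit$W), fit$q))
  new("PLSModel", xMean = xMean, yMean = yMean, weights = fit$W,
      loadings = fit$P, yLoadings = fit$q, regressionVector = b, nLv = nLv)
}

setMethod("show", "PLSModel", function(object) {
  cat("PLSModel: ", object@nLv, " latent variable(s), ",
      length(object@xMean), " channels\n", sep = "")
})

#' Predict concentrations from a fitted PLS model
#'
#' \code{yhat = (X_new - xMean) . regressionVector + yMean}.
#'
#' @param object a [PLSModel-class].
#' @param newdata numeric matrix (samples x channels) or a single spectrum
#'   vector; the channel count must match the model.
#' @return numeric vector of predicted concentrations, mmol/L.
#' @export
setMethod("predict", "PLSModel", function(object, newdata) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object@xMean))
    stop("validation error: newdata has ", ncol(newdata),
         " channels; model expects ", length(object@xMean))
  as.numeric(sweep(newdata, 2L, object@xMean) %*% object@regressionVector +
               object@yMean)
})

# nested predictions for one new spectrum at every LV count 1..nLv of a
# fitted model, via the scores path (t-by-t accumulation)
.nestedPredictions <- function(model, xNew) {
  xr <- xNew - model@xMean
  preds <- numeric(model@nLv)
  pred <- model@yMean
  for (k in seq_len(model@nLv)) {
    tk <- sum(xr * model@weights[, k])
    pred <- pred + model@yLoadings[k] * tk
    xr <- xr - tk * model@loadings[, k]
    preds[k] <- pred
  }
  preds
}

#' PRESS curve over candidate latent-variable counts
#'
#' For each \code{k} in \code{1..maxLv},
#' \code{PRESS(k) = sum_i (y_i - yhat_i^(-i,k))^2} where the prediction of
#' sample \code{i} comes from a model fitted to the other \code{N-1} samples
#' (leave-one-out folds enumerated in index order). NIPALS latent variables
#' are nested, so each fold is fitted once at \code{maxLv} and truncated.
#'
#' @inheritParams fitPls1
#' @param maxLv largest candidate LV count (\code{<= min(N-2, channels)}).
#' @return numeric PRESS vector of length \code{maxLv} (mmol^2/L^2).
#' @export
pressCurve <- function(X, y, maxLv) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  N <- nrow(X)
  maxLv <- as.integer(maxLv)
  if (maxLv < 1L || maxLv > min(N - 2L, ncol(X)))
    stop("validation error: maxLv must be in [1, min(N-2, channels)]")
  press <- numeric(maxLv)
  for (i in seq_len(N)) {
    Xi <- X[-i, , drop = FALSE]
    yi <- y[-i]
    xMean <- colMeans(Xi)
    yMean <- mean(yi)
    fit <- .nipals(sweep(Xi, 2L, xMean), yi - yMean, maxLv, strict = FALSE)
    got <- length(fit$q)
    xr <- X[i, ] - xMean
    pred <- yMean
    preds <- numeric(maxLv)
    for (k in seq_len(maxLv)) {
      if (k <= got) {
        tk <- sum(xr * fit$W[, k])
        pred <- pred + fit$q[k] * tk
        xr <- xr - tk * fit$P[, k]
      }
      # past the achievable rank additional LVs contribute nothing
      preds[k] <- pred
    }
    press <- press + (y[i] - preds)^2
  }
  press
}

#' Select the latent-variable count from a PRESS curve
#'
#' Smallest \code{k} whose PRESS is within \code{tolerance} (default 5
#' percent) of the curve minimum; ties break toward smaller \code{k}. This
#' automates the usual visual rule of stopping where the PRESS chart
#' plateaus.
#'
#' @param press numeric PRESS curve.
#' @param tolerance fractional slack above the minimum.
#' @return integer LV count.
#' @export
selectNLv <- function(press, tolerance = 0.05) {
  if (length(press) == 0L) stop("empty PRESS curve")
  as.integer(min(which(press <= (1 + tolerance) * min(press))))
}

#' Leave-one-out cross-validation of a PLS1 calibration
#'
#' Each sample is predicted once by a model trained on the other \code{N-1};
#' the report carries the per-sample predictions,
#' \code{r2 = 1 - SS_res/SS_tot} and \code{rmsecv = sqrt(SS_res/N)}.
#'
#' @inheritParams fitPls1
#' @param nLv latent-variable count used in every fold.
#' @return a [CVReport-class] (with an empty PRESS slot; see
#'   [calibrateSpectra()] for the full report).
#' @export
loocvEvaluate <- function(X, y, nLv) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  N <- nrow(X)
  if (N < 3L) stop("validation error: LOOCV needs at least 3 samples")
  preds <- numeric(N)
  for (i in seq_len(N)) {
    model <- fitPls1(X[-i, , drop = FALSE], y[-i], nLv)
    preds[i] <- predict(model, X[i, ])
  }
  cvReport(predictions = preds, reference = y, chosenNLv = as.integer(nLv))
}

#' Assemble a CVReport from predictions
#'
#' @param predictions,reference numeric vectors, one value per sample.
#' @param chosenNLv LV count behind the predictions.
#' @param press optional PRESS curve to attach.
#' @return a [CVReport-class].
#' @export
cvReport <- function(predictions, reference, chosenNLv = 1L,
                     press = numeric()) {
  ssRes <- sum((reference - predictions)^2)
  ssTot <- sum((reference - mean(reference))^2)
  new("CVReport", press = press, chosenNLv = as.integer(chosenNLv),
      predictions = predictions, reference = reference,
      r2 = 1 - ssRes / ssTot, rmsecv = sqrt(ssRes / length(reference)))
}

setMethod("show", "CVReport", function(object) {
  cat("CVReport: ", length(object@predictions), " samples, ",
      object@chosenNLv, " LV; R2 = ", signif(object@r2, 4),
      ", RMSECV = ", signif(object@rmsecv, 4), " mmol/L\n", sep = "")
})

#' Calibrate a preprocessed spectra set
#'
#' Computes the PRESS curve, selects the latent-variable count with
#' [selectNLv()] and evaluates the leave-one-out predictions at that count.
#'
#' @param set a preprocessed [SpectraSet-class].
#' @param maxLv largest candidate LV count; default
#'   \code{min(15, N - 2)}.
#' @param pressTolerance slack passed to [selectNLv()].
#' @return a [CVReport-class] with the PRESS curve attached.
#' @export
calibrateSpectra <- function(set, maxLv = NULL, pressTolerance = 0.05) {
  stopifnot(is(set, "SpectraSet"))
  X <- t(absorbance(set))
  y <- concentrations(set)
  if (is.null(maxLv)) maxLv <- min(15L, nrow(X) - 2L)
  maxLv <- min(as.integer(maxLv), nrow(X) - 2L, ncol(X))
  press <- pressCurve(X, y, maxLv)
  k <- selectNLv(press, pressTolerance)
  rep <- loocvEvaluate(X, y, k)
  rep@press <- press
  rep
}

#' Accessors for CVReport slots
#'
#' @param report a [CVReport-class].
#' @return the corresponding slot value.
#' @export
cvPress <- function(report) report@press

#' @rdname cvPress
#' @export
cvPredictions <- function(report) report@predictions

#' @rdname cvPress
#' @export
cvReference <- function(report) report@reference

#' @rdname cvPress
#' @export
cvR2 <- function(report) report@r2

#' @rdname cvPress
#' @export
cvRmsecv <- function(report) report@rmsecv

#' @rdname cvPress
#' @export
cvChosenNLv <- function(report) report@chosenNLv

#' Export a CVReport
#'
#' \code{writeCvReportJson} writes the PRESS curve, chosen LV count,
#' per-sample predicted/reference pairs and the accuracy metrics as JSON;
#' \code{writePredictedVsReferenceCsv} writes the prediction pairs as CSV
#' (the data behind a predicted-vs-reference plot).
#'
#' @param report a [CVReport-class]; \code{path} a file path.
#' @return invisibly, \code{path}.
#' @export
writeCvReportJson <- function(report, path) {
  stopifnot(is(report, "CVReport"))
  jsonlite::write_json(list(
    press = report@press, chosenNLv = report@chosenNLv,
    r2 = report@r2, rmsecv = report@rmsecv,
    samples = data.frame(reference = report@reference,
                         predicted = report@predictions)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeCvReportJson
#' @export
writePredictedVsReferenceCsv <- function(report, path) {
  stopifnot(is(report, "CVReport"))
  utils::write.csv(data.frame(reference = report@reference,
                              predicted = report@predictions),
                   path, row.names = FALSE)
  invisible(path)
}
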