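# Independent oracles used to cross-check the from-scratch implementations.
# Each deliberately takes a different computational route than the package.

# Savitzky-Golay weights via lm.fit on unit-impulse signals: the weight of
# channel j is the filter response to e_j, obtained from an explicit local
# polynomial regression rather than the package's normal-equations formula.
sgOracleWeights <- function(window, polyorder, deriv, spacing = 1) {
  h <- (window - 1) / 2
  t <- (-h:h) * spacing
  X <- outer(t, 0:polyorder, `^`)
  vapply(seq_len(window), function(j) {
    e <- numeric(window); e[j] <- 1
    cf <- lm.fit(X, e)$coefficients
    factorial(deriv) * cf[deriv + 1]
  }, numeric(1))
}

# minimum-norm least squares via SVD pseudoinverse (full-rank PLS oracle)
pinvPredict <- function(X, y, Xnew) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  s <- svd(Xc)
  pos <- s$d > max(s$d) * 1e-10
  beta <- s$v[, pos, drop = FALSE] %*%
    ((t(s$u[, pos, drop = FALSE]) %*% (y - ym)) / s$d[pos])
  as.numeric(sweep(as.matrix(Xnew), 2, xm) %*% beta + ym)
}

# plain textbook PLS1, written independently (explicit loops, no deflated-y
# shortcut sharing with the package internals)
oraclePls1Predict <- function(X, y, nLv, Xnew) {
  xm <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2, xm); f <- y - ym
  Xn <- sweep(as.matrix(Xnew), 2, xm)
  pred <- rep(ym, nrow(Xn))
  for (k in seq_len(nLv)) {
    w <- as.numeric(t(E) %*% f)
    w <- w / sqrt(sum(w * w))
    tsc <- as.numeric(E %*% w)
    p <- as.numeric(t(E) %*% tsc) / sum(tsc * tsc)
    q <- sum(f * tsc) / sum(tsc * tsc)
    tn <- as.numeric(Xn %*% w)
    pred <- pred + q * tn
    E <- E - outer(tsc, p)
    f <- f - q * tsc
    Xn <- Xn - outer(tn, p)
  }
  pred
}

# brute-force PRESS: refit from scratch for every fold and every LV count
oraclePress <- function(X, y, maxLv) {
  vapply(seq_len(maxLv), function(k) {
    sum(vapply(seq_len(nrow(X)), function(i) {
      (y[i] - oraclePls1Predict(X[-i, , drop = FALSE], y[-i], k,
                                X[i, , drop = FALSE]))^2
    }, numeric(1)))
  }, numeric(1))
}

# small deterministic spectra set: channels = gaussian bands on a toy axis
makeToySet <- function(conc = c(0, 1, 2, 4), region = "nir") {
  ax <- regionGrid(region)[1:25]
  shape1 <- exp(-((ax - ax[8]) / 3)^2)
  shape2 <- exp(-((ax - ax[18]) / 4)^2)
  a <- vapply(conc, function(c) 0.5 * shape1 * (1 - c / 600) + 1e-3 * c * shape2,
              numeric(length(ax)))
  SpectraSet(axis = ax, absorbance = a, concentrations = conc, region = region)
}

noiselessInstrument <- function(seed = 1L) instrumentModel(seed = seed)
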