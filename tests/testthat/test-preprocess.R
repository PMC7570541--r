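test_that("noise-region masking drops closed intervals", {
  set <- generateSpectra(c(0, 2, 8), buildBandLibrary("nir"),
                         noiselessInstrument())
  expect_identical(maskNoiseRegions(set, list()), set)
  masked <- maskNoiseRegions(set, list(c(1900, 1960), c(2350, 2600)))
  expect_equal(nChannels(masked), 1801 - 61 - 251)  # inclusive endpoints
  expect_false(any(axisValues(masked) >= 1900 & axisValues(masked) <= 1960))
  mir <- generateSpectra(c(0, 2), buildBandLibrary("mir"),
                         noiselessInstrument())
  expect_equal(min(axisValues(maskNoiseRegions(mir, list(c(500, 700))))), 701)
  expect_error(maskNoiseRegions(set, list(c(800, 2600))), "every axis point")
})

test_that("baseline subtraction removes the 0 mmol/L spectrum", {
  s <- makeToySet(c(0, 0, 3))
  a <- absorbance(s)
  a[, 1] <- a[, 1] + 0.01   # two zero-level samples differing by an offset
  s <- SpectraSet(axisValues(s), a, concentrations(s), region(s))
  out <- baselineSubtract(s)
  base <- rowMeans(a[, 1:2])
  expect_equal(unname(absorbance(out)), unname(a - base))
  # the pair of zero samples becomes antisymmetric about zero
  expect_equal(unname(absorbance(out)[, 1]), -unname(absorbance(out)[, 2]))
  expect_equal(concentrations(out), concentrations(s))
  expect_error(baselineSubtract(makeToySet(c(1, 2, 3))), "precondition")
})

test_that("subtracted synthetic spectra show signed band polarity", {
  set <- generateSpectra(buildSamplePlan("main37"), buildBandLibrary("nir"),
                         noiselessInstrument())
  diffd <- baselineSubtract(set)
  ax <- axisValues(diffd)
  top <- absorbance(diffd)[, which.max(concentrations(diffd))]
  expect_lt(top[ax == 1450], 0)  # water band inverted by displacement
  expect_gt(top[ax == 2259], 0)  # lactate band positive-going
})

test_that("masking and subtraction commute on surviving channels", {
  set <- generateSpectra(c(0, 1, 6), buildBandLibrary("nir"),
                         defaultInstrumentModel("nir", 5))
  r <- list(c(1900, 1960))
  a <- maskNoiseRegions(baselineSubtract(set), r)
  b <- baselineSubtract(maskNoiseRegions(set, r))
  expect_equal(unname(absorbance(a)), unname(absorbance(b)))
})

test_that("rlmsc recovers exact affine transforms of the reference", {
  s <- makeToySet(c(0, 1, 2, 4))
  r <- rowMeans(absorbance(s))
  a <- cbind(r, 2 * r + 0.1)
  set <- SpectraSet(axisValues(s), a, c(0, 1), "nir")
  out <- rlmsc(set, reference = r)
  expect_equal(unname(absorbance(out)[, 1]), unname(r), tolerance = 1e-9)
  expect_equal(unname(absorbance(out)[, 2]), unname(r), tolerance = 1e-9)
  cf <- S4Vectors::metadata(out)$rlmscCoefficients
  expect_equal(unname(cf[2, ]), c(2, 0.1), tolerance = 1e-9)
})

test_that("rlmsc resists gross outliers where plain OLS fails", {
  set.seed(42)
  n <- 400
  r <- exp(-((seq_len(n) - 150) / 60)^2) + 0.5  # smooth reference, ~1 AU
  x <- 2 * r + 0.1
  bad <- sample(n, 0.05 * n)
  x[bad] <- x[bad] + 10                          # 5% gross spikes, +10 AU
  set <- SpectraSet(seq(800, 799 + n), cbind(x, x), c(0, 1), "nir")
  out <- rlmsc(set, reference = r)
  cf <- S4Vectors::metadata(out)$rlmscCoefficients[1, ]
  expect_lt(abs(cf["a"] - 2) / 2, 0.01)
  expect_lt(abs(cf["b"] - 0.1) / 0.1, 0.01)
  ols <- coef(lm(x ~ r))
  expect_gt(max(abs(ols[2] - 2) / 2, abs(ols[1] - 0.1) / 0.1), 0.05)
  # independent robust-fit oracle agrees
  rob <- MASS::rlm(x ~ r, psi = MASS::psi.bisquare, c = 4.685, maxit = 50)
  expect_equal(unname(cf["a"]), unname(coef(rob)[2]), tolerance = 1e-2)
})

test_that("rlmsc is idempotent for a fixed reference", {
  set <- generateSpectra(c(0, 3, 9), buildBandLibrary("nir"),
                         defaultInstrumentModel("nir", 8))
  r <- rowMeans(absorbance(set))
  once <- rlmsc(set, reference = r)
  twice <- rlmsc(once, reference = r)
  cf <- S4Vectors::metadata(twice)$rlmscCoefficients
  expect_equal(unname(cf[, "a"]), rep(1, 3), tolerance = 1e-6)
  expect_equal(unname(cf[, "b"]), rep(0, 3), tolerance = 1e-6)
})

test_that("SG weights match the explicit polynomial-fit oracle", {
  expect_equal(sgCoefficients(5, 2, 0, 1),
               c(-3, 12, 17, 12, -3) / 35, tolerance = 1e-12)
  for (case in list(c(5, 2, 0), c(21, 2, 1), c(31, 2, 1), c(11, 4, 2))) {
    w <- sgCoefficients(case[1], case[2], case[3], spacing = 1)
    expect_equal(w, sgOracleWeights(case[1], case[2], case[3]),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(sum(w), if (case[3] == 0) 1 else 0, tolerance = 1e-12)
  }
  # spacing scales derivative weights by spacing^-deriv
  expect_equal(sgCoefficients(21, 2, 1, spacing = 0.5),
               2 * sgCoefficients(21, 2, 1, spacing = 1), tolerance = 1e-12)
  expect_error(sgCoefficients(4, 2, 1), "odd")
  expect_error(sgCoefficients(3, 3, 1), "odd and > polyorder")
})

test_that("SG weights agree with the signal package's design", {
  skip_if_not_installed("signal")
  w <- sgCoefficients(21, 2, 0, 1)
  ref <- signal::sgolay(p = 2, n = 21, m = 0)
  expect_equal(w, as.numeric(ref[11, ]), tolerance = 1e-9)
})

test_that("SG derivative reproduces polynomials exactly, edges included", {
  ax <- seq(1000, 1100)
  quad <- matrix((ax - 1050)^2, ncol = 1)
  set <- SpectraSet(ax, quad, 1, "nir")
  cfg <- preprocessConfig("nir", sgWindow = 21L, sgPolyorder = 2L,
                          sgDeriv = 1L, doBaselineSubtract = FALSE)
  out <- applySavgol(set, cfg)
  h <- 10
  interior <- (h + 1):(length(ax) - h)
  expect_equal(unname(absorbance(out)[interior, 1]),
               2 * (ax[interior] - 1050), tolerance = 1e-9)
  # linear input: derivative is the slope everywhere, including edges
  lin <- SpectraSet(ax, matrix(3.5 * ax - 7, ncol = 1), 1, "nir")
  outLin <- applySavgol(lin, cfg)
  expect_equal(unname(absorbance(outLin)[, 1]), rep(3.5, length(ax)),
               tolerance = 1e-9)
  # deriv = 0 leaves a constant spectrum unchanged
  cfg0 <- preprocessConfig("nir", sgWindow = 21L, sgDeriv = 0L)
  cst <- SpectraSet(ax, matrix(2.2, length(ax), 1), 1, "nir")
  expect_equal(unname(absorbance(applySavgol(cst, cfg0))[, 1]),
               rep(2.2, length(ax)), tolerance = 1e-12)
})

test_that("filtering does not leak across masked gaps", {
  set <- generateSpectra(c(0, 4), buildBandLibrary("nir"),
                         defaultInstrumentModel("nir", 2))
  masked <- maskNoiseRegions(set, list(c(1900, 1960)))
  cfg <- defaultPreprocessConfig("nir")
  left <- axisValues(masked) < 1900
  a <- absorbance(masked)
  ref <- applySavgol(masked, cfg)
  a2 <- a
  a2[!left, ] <- a2[!left, ] + rnorm(sum(!left) * 2)  # perturb right of gap
  pert <- applySavgol(SpectraSet(axisValues(masked), a2,
                                 concentrations(masked), "nir"), cfg)
  expect_identical(absorbance(ref)[left, ], absorbance(pert)[left, ])
  expect_error(applySavgol(restrictToAxisWindow(set, 800, 830), cfg),
               "shorter than the SG window")
})

test_that("the pipeline honours stage switches and records a 4-stage log", {
  set <- generateSpectra(c(0, 2, 8), buildBandLibrary("mir"),
                         defaultInstrumentModel("mir", 4))
  idCfg <- preprocessConfig("mir", doBaselineSubtract = FALSE,
                            doRlmsc = FALSE, doSavgol = FALSE)
  out <- preprocessPipeline(set, idCfg)
  expect_equal(unname(absorbance(out$set)), unname(absorbance(set)))
  res <- preprocessPipeline(set, defaultPreprocessConfig("mir"))
  expect_length(res$log, 4)
  expect_equal(sub(" .*", "", res$log),
               c("mask_noise_regions", "baseline_subtract", "rlmsc",
                 "savitzky_golay"))
  expect_equal(concentrations(res$set), concentrations(set))
  nir <- generateSpectra(buildSamplePlan("main37"), buildBandLibrary("nir"),
                         defaultInstrumentModel("nir", 1))
  proc <- preprocessPipeline(nir, defaultPreprocessConfig("nir"))$set
  expect_equal(dim(t(absorbance(proc))), c(37, 1489))
  expect_error(preprocessPipeline(nir, defaultPreprocessConfig("mir")),
               "region")
})

test_that("preprocess config YAML round trips", {
  cfg <- defaultPreprocessConfig("nir")
  f <- withr::local_tempfile(fileext = ".yaml")
  writePreprocessConfigYaml(cfg, f)
  cfg2 <- readPreprocessConfigYaml(f)
  for (sl in slotNames(cfg)) expect_equal(slot(cfg2, sl), slot(cfg, sl))
})
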