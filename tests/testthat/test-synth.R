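test_that("sample plans reproduce the dilution design", {
  plan <- buildSamplePlan("main37")
  expect_length(plan, 37)
  expect_equal(range(plan), c(0, 20))
  expect_equal(plan[1:21], seq(0, 5, by = 0.25))
  expect_equal(plan[22:37], seq(5, 20, by = 1))
  expect_equal(sum(plan == 5), 2)  # 5 mmol/L sits in both sub-grids
  expect_equal(buildSamplePlan("hc6"), seq(100, 600, by = 100))
  expect_error(buildSamplePlan("custom", numeric()), "non-empty")
  expect_error(buildSamplePlan("custom", c(1, -2)), "validation")
  expect_equal(buildSamplePlan("custom", c(3, 1)), c(3, 1))
})

test_that("stock-mass arithmetic is linear and guarded", {
  expect_equal(stockMassFor(600, 1, 112.06), 67.236)
  expect_equal(stockMassFor(300, 2, 112.06), 67.236)  # halves x doubles
  expect_equal(stockMassFor(600, 1), 67.236)          # default molar mass
  expect_error(stockMassFor(0, 1, 112.06), "validation")
  expect_error(stockMassFor(600, -1, 112.06), "validation")
})

test_that("ATR reflection count follows the crystal geometry", {
  expect_identical(atrReflectionCount(80, 4, 45), 10L)
  t <- 3.7  # grazing identity: length 2*t at 45 degrees gives one reflection
  expect_identical(atrReflectionCount(2 * t, t, 45), 1L)
  expect_identical(atrReflectionCount(80, 4, 60), 5L)  # floor(5.77)
  expect_error(atrReflectionCount(80, 4, 90), "validation")
  expect_error(atrReflectionCount(-80, 4, 45), "validation")
})

test_that("band libraries carry the published centers per region", {
  nir <- bands(buildBandLibrary("nir"))
  expect_setequal(nir$center[nir$component == "lactate"],
                  c(1215, 1684, 1730, 2259, 2299))
  expect_true(all(c(970, 1180, 1450, 1920) %in%
                    nir$center[nir$component == "water"]))
  mir <- bands(buildBandLibrary("mir"))
  expect_equal(sum(mir$component == "lactate"), 14)  # 10 fingerprint + 4 diag
  expect_true(all(c(779, 854, 940, 1040, 1126, 1157, 1315, 1365, 1416, 1455,
                    2852, 2930, 2988, 3159) %in% mir$center))
  uv <- bands(buildBandLibrary("uvvis"))
  expect_true(all(c(742, 605) %in% uv$center[uv$component == "water"]))
  expect_true(747 %in% uv$center[uv$component == "lactate"])
  # the lactate band is orders of magnitude below the water bands
  expect_lt(max(uv$absorptivity[uv$component == "lactate"]) * 20,
            1e-3 * max(uv$absorptivity[uv$component == "water"]))
})

test_that("band library CSV dump/load round trips", {
  lib <- buildBandLibrary("mir")
  f <- withr::local_tempfile(fileext = ".csv")
  writeBandLibraryCsv(lib, f)
  lib2 <- readBandLibraryCsv(f, "mir")
  expect_equal(bands(lib2), bands(lib))
})

test_that("generation is deterministic for equal seeds and noise-free", {
  lib <- buildBandLibrary("nir")
  pure <- generateSpectra(0, lib, noiselessInstrument())
  pure2 <- generateSpectra(0, lib, noiselessInstrument())
  expect_identical(absorbance(pure), absorbance(pure2))
  noisy1 <- generateSpectra(c(0, 5), lib, defaultInstrumentModel("nir", 11))
  noisy2 <- generateSpectra(c(0, 5), lib, defaultInstrumentModel("nir", 11))
  expect_identical(absorbance(noisy1), absorbance(noisy2))
  noisy3 <- generateSpectra(c(0, 5), lib, defaultInstrumentModel("nir", 12))
  expect_false(identical(absorbance(noisy1), absorbance(noisy3)))
})

test_that("a zero-concentration noise-free sample is the pure matrix", {
  lib <- buildBandLibrary("nir")
  pure <- generateSpectra(0, lib, noiselessInstrument())
  tab <- bands(lib)
  w <- tab[tab$component == "water", ]
  ax <- axisValues(pure)
  expected <- Reduce(`+`, lapply(seq_len(nrow(w)), function(i)
    w$absorptivity[i] * exp(-4 * log(2) * ((ax - w$center[i]) / w$fwhm[i])^2)))
  expect_equal(unname(absorbance(pure)[, 1]), expected, tolerance = 1e-12)
})

test_that("noise-free absorbance at a lactate band is affine in concentration", {
  set <- generateSpectra(buildSamplePlan("hc6"), buildBandLibrary("nir"),
                         noiselessInstrument())
  a <- absorbance(set)[axisValues(set) == 2259, ]
  fit <- lm(a ~ concentrations(set))
  expect_gt(suppressWarnings(summary(fit))$r.squared, 1 - 1e-12)
  # slope equals the brute-force band-summation derivative wrt concentration
  lib <- bands(buildBandLibrary("nir"))
  contrib <- function(row, x) {
    amp <- lib$absorptivity[row]
    amp * exp(-4 * log(2) * ((x - lib$center[row]) / lib$fwhm[row])^2)
  }
  slopeOracle <- sum(vapply(which(lib$component == "lactate"),
                            contrib, numeric(1), x = 2259)) -
    sum(vapply(which(lib$component == "water"),
               contrib, numeric(1), x = 2259)) / 600
  expect_equal(unname(coef(fit)[2]), slopeOracle, tolerance = 1e-10)
})

test_that("water displacement makes the 1450 nm band strictly decreasing", {
  set <- generateSpectra(buildSamplePlan("main37"), buildBandLibrary("nir"),
                         noiselessInstrument())
  a1450 <- absorbance(set)[axisValues(set) == 1450, ]
  ord <- order(concentrations(set))
  expect_true(all(diff(a1450[ord][!duplicated(sort(concentrations(set)))]) < 0))
  expect_equal(waterDisplacement(600), 0)
  expect_equal(waterDisplacement(0), 1)
})

test_that("saturation regions carry inflated noise", {
  set <- generateSpectra(rep(0, 8), buildBandLibrary("nir"),
                         defaultInstrumentModel("nir", seed = 3))
  ax <- axisValues(set)
  resid <- absorbance(set) - rowMeans(absorbance(set))
  sdIn <- sd(resid[ax >= 1900 & ax <= 1960, ])
  sdOut <- sd(resid[ax >= 1300 & ax <= 1400, ])
  expect_gt(sdIn, 5 * sdOut)
})

test_that("different seeds agree in band structure after averaging", {
  # Monte-Carlo: replicate means of two seeds differ within 3 standard errors
  lib <- buildBandLibrary("nir")
  nRep <- 200
  chan <- function(seed0) {
    vals <- vapply(seq_len(nRep), function(r) {
      im <- defaultInstrumentModel("nir", seed = seed0 + r)
      s <- generateSpectra(10, lib, im)
      absorbance(s)[axisValues(s) == 1450, 1]
    }, numeric(1))
    c(mean = mean(vals), se = sd(vals) / sqrt(nRep))
  }
  a <- chan(1000); b <- chan(9000)
  expect_lt(abs(a["mean"] - b["mean"]),
            3 * sqrt(a["se"]^2 + b["se"]^2))
})

test_that("grid/region mismatch and invalid plans are rejected", {
  lib <- buildBandLibrary("nir")
  expect_error(generateSpectra(c(0, 5), lib, grid = regionGrid("mir")),
               "grid")
  expect_error(generateSpectra(numeric(), lib), "empty")
  expect_error(generateSpectra(-1, lib), "negative")
})
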