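---
title: "Methods: synthetic lactate spectra and PLS calibration"
author: "lactospec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic lactate spectra and PLS calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lactospec)
```

# The problem

Sodium lactate (NaLac) in isotonic phosphate-buffered saline is a
blood-analogous model system for developing an optical lactate assay: the
clinically relevant range is 0–20 mmol/L (hyperlactatemia starts near
2 mmol/L), and the spectra in all three optical windows — UV/visible
(300–800 nm), near-infrared (800–2600 nm) and mid-infrared
(4000–500 cm⁻¹) — are dominated not by lactate but by water. The analyte
signal is two effects at once:

1. **direct absorption** by lactate C–H, C–C, C–O and CH₃ vibrational
   bands, with amplitudes roughly three orders of magnitude below the water
   bands at the top of the range; and
2. **water displacement**: equivolume serial dilution from a 600 mmol/L
   stock replaces matrix with stock, so every water band scales by
   `w(c) = 1 − c/600`, i.e. the *matrix* signal is itself linear in the
   analyte concentration.

Multivariate calibration (PLS) is the standard way to extract a
concentration from such spectra, and this package implements the complete
workflow — simulation, preprocessing, calibration and validation — as
tested, reusable code.

# The synthetic-data generator

`generateSpectra()` renders, for each sample of concentration `c`,

```
A(x) = gain × [ Σ_water A_b(x)·w(c) + Σ_lactate ε_b(x)·c + baseline(x) ] + noise(x)
```

where each band is a Gaussian (optionally Lorentzian) profile with a
centre, full width at half maximum, and amplitude/absorptivity taken from
`buildBandLibrary()`. The band centres are the published assignments for
this system: seven water O–H harmonics across the visible range (401–742
nm) plus a lactate band at 747 nm; water overtone/combination bands at
970, 1180, 1450 and 1920 nm and lactate C–H bands at 1215, 1684, 1730,
2259 and 2299 nm in the NIR; water fundamentals at 1638 and 3283 cm⁻¹ and
fourteen lactate bands (ten fingerprint, 779–1455 cm⁻¹; four diagnostic,
2852–3159 cm⁻¹) in the MIR.

Widths and intensities are not tabulated in published peak lists, so the
library fixes them once, in one constants table per region, with two
anchors:

- the dominant water band of each region has an amplitude of order 1 AU
  (1.2 AU at 1450 nm, 2.6 AU at 1920 nm, 1.0 AU at 3283 cm⁻¹), and
- lactate absorptivities are set so that at 20 mmol/L a lactate band is
  ~10⁻³ of the dominant water band — the "barely noticeable by eye" regime
  in which univariate calibration fails and PLS is genuinely needed.

## Instrument model

`defaultInstrumentModel()` draws, per sample: additive white noise
(sd 5×10⁻⁴ AU), a constant baseline offset (sd 2×10⁻³ AU), a linear
baseline tilt (sd 10⁻⁶ AU/nm; 5×10⁻⁷ AU/cm⁻¹ for MIR), and a
multiplicative gain `1 + δ` with sd 10⁻³ — the sample-to-sample
photometric repeatability class of a baseline-corrected research dual-beam
spectrophotometer. Inside the detector-saturation regions (1900–1960 and
2350–2600 nm, where water absorption saturates the PbS detector; 500–700
cm⁻¹ at the MIR range edge) the white-noise sd is inflated to 5×10⁻² AU.
One integer seed drives a single generator stream; equal seeds give
bit-identical sets and the caller's RNG state is restored afterwards.

The gain term deserves a note: because the water bands dominate, gain
noise `δ × water` is nearly collinear with the water-displacement signal
`−water × c/600`, so the gain sd directly sets how much of the
displacement information survives. At 10⁻³ the sample-to-sample gain
spread corresponds to a displacement-equivalent uncertainty of
δ·600 ≈ 0.6 mmol/L, which is what places the default NIR problem in the
sub-millimolar RMSECV regime.

## What the generator does and does not emulate

It reproduces the statistical structure the analysis assumes: Beer–Lambert
linearity at every band, the water-displacement confound, region-specific
saturation noise, baseline drift, and multiplicative scatter. It does
**not** model band shifts or shape changes with temperature, pH or ionic
strength; nonlinear detector response; ATR evanescent-wave depth effects;
or chemical interactions between lactate and the phosphate buffer.
Noise-free synthetic difference spectra are therefore *exactly rank one*
in concentration — every band scales linearly with `c` — which is an
idealization real spectra never satisfy. Two consequences follow: passing
parameter-recovery tests here demonstrates the correctness of the
machinery, not field performance on laboratory spectra; and the PRESS
curve of synthetic data plateaus after very few latent variables, whereas
laboratory spectra typically support many more (the extra LVs model real
shape variation the generator deliberately omits).

# Preprocessing

`preprocessPipeline()` applies, in fixed order, with each stage recorded
in an auditable log:

1. **masking** — closed intervals (endpoints included, matching how such
   ranges are conventionally quoted) are removed from the axis; the NIR
   defaults 1900–1960 and 2350–2600 nm leave 1489 of 1801 channels;
2. **base-spectrum subtraction** — the mean of the 0 mmol/L samples is
   subtracted from every spectrum, turning water-dominated channels
   negative and lactate bands positive;
3. **RLMSC** (optional, off by default — see below) — each spectrum is
   robustly regressed on the set mean, `x ≈ a·r + b`, by iteratively
   reweighted least squares (Tukey bisquare, tuning constant 4.685, at
   most 50 iterations, convergence at coefficient change < 10⁻¹⁰,
   initialized at the ordinary-least-squares fit), then corrected to
   `(x − b)/a`;
4. **Savitzky–Golay filtering** — first-derivative, polynomial order 2,
   windows of 21/51/31 points for UV-Vis/NIR/MIR. Weights are computed
   from first principles by solving the local polynomial normal equations;
   the filter runs independently per contiguous uniformly spaced block so
   nothing leaks across masked gaps, and edges use one-sided local
   polynomial fits rather than padding, so polynomials up to the filter
   order are reproduced exactly everywhere, edges included.

## Why scatter correction is off by default

RLMSC is implemented, exported and tested exactly as specified, and the
pipeline applies it at its conventional position when enabled. The
default, however, is `doRlmsc = FALSE`, for a reason worth spelling out.

Multiplicative scatter correction rescales every spectrum to a common
reference by the fitted affine map `(x − b)/a`. That is the right
operation when `a` captures physical scatter (path-length or particle-size
variation) *uncorrelated with the analyte*. After base-spectrum
subtraction of Beer–Lambert mixture spectra, though, every difference
spectrum is (noise aside) the *same shape* scaled by the concentration:
`d_i ≈ (lactate − water/600) · c_i`. Regressing `d_i` on the mean
difference spectrum then estimates `a_i ≈ c_i/c̄` — the fitted
"scatter" coefficient *is* the analyte signal — and the correction maps
every sample onto the reference, erasing the information PLS needs. In the
noise-free limit the corrected set is exactly constant and no calibration
is possible at all. The same confound appears, more weakly, whenever the
correction is estimated on spectra whose overall scale carries
concentration information. For transmission/ATR spectra of clear,
non-scattering solutions the gain drift the correction would remove is
small (the instrument model's 0.1 %), so the safe default is off; the
switch remains for data with genuine scatter, where the robust fit's
outlier resistance (verified in the tests against a plain-OLS control on
5 %-contaminated channels) is the point of the R in RLMSC.

An automatic outlier-removal stage is deliberately not implemented: no
defensible rejection rule is available for this system, so the pipeline
records outlier handling as out of scope rather than guessing one.

# Calibration

`fitPls1()` is NIPALS PLS1 on mean-centred data (no unit-variance
scaling — channels share units, and variance scaling would amplify empty
spectral regions): weights `w = Xᵀy/‖Xᵀy‖`, scores `t = Xw`, loadings
`p = Xᵀt/tᵀt`, `q = yᵀt/tᵀt`, deflation of both `X` and `y`, regression
vector `b = W(PᵀW)⁻¹q`. At full rank the predictions coincide with
minimum-norm least squares (verified against an SVD pseudoinverse oracle
to 10⁻⁸), and successive scores are orthogonal to 10⁻⁸.

`pressCurve()` computes leave-one-out PRESS for every candidate LV count:
folds enumerate the samples in index order, each fold is fitted once at
the maximum count, and the nested NIPALS structure supplies the
predictions for every smaller count; a brute-force refit-per-fold oracle
confirms the shortcut. If a fold exhausts the data rank below the
requested maximum, further LVs contribute nothing and the curve continues
flat — rather than failing — so near-noiseless sets remain analysable.

`selectNLv()` automates the usual visual plateau rule: the smallest `k`
with `PRESS(k) ≤ 1.05 × min(PRESS)` (ties toward smaller `k`). The 5 %
tolerance is a package choice; in practice analysts pick the LV count by
inspecting the PRESS chart without a stated numeric rule, and automating
the plateau keeps runs reproducible. `maxLv` defaults
to `min(15, N − 2)`.

`loocvEvaluate()` reports `R² = 1 − SS_res/SS_tot` on the cross-validated
predictions and `RMSECV = √(SS_res/N)`. R² here is the coefficient of
determination of predictions against references, the stricter of the two
readings ("correlation coefficient" is sometimes used loosely for the same
chart); the definition is fixed and documented so reported numbers are
unambiguous.

# Numerical and design choices

- Axes are always stored ascending; descending MIR input (4000 → 500
  cm⁻¹) is reversed on ingestion, together with the sample rows. One
  convention keeps masking, block detection and filtering simple.
- CSV interchange writes 17 significant digits, so write → read round
  trips are bit-exact.
- The 37-sample plan keeps 5 mmol/L in both sub-grids (21 + 16 = 37
  distinct physical samples), the only reading consistent with the printed
  totals.
- The sodium lactate molar mass constant is 112.06 g/mol (standard atomic
  weights for C₃H₅NaO₃), reproducing the printed 67.236 g for a
  600 mmol/L, 1 L stock.
- Degenerate inputs fail loudly and specifically: ragged or non-numeric
  CSV cells are reported with row/column, masking everything is an error,
  RLMSC refuses samples whose fitted `|a| < 10⁻¹²`, Savitzky–Golay names
  any block shorter than its window, and PLS reports the achievable LV
  count on rank exhaustion.

# Problem sizes and verification scope

The test suite and the acceptance script run the full 37-sample design on
the real region grids (501 / 1801 / 3501 channels), with leave-one-out
PRESS up to 15 latent variables; small algebraic oracles (pseudoinverse
regression, brute-force PRESS, explicit polynomial-fit Savitzky–Golay
weights, a robust-regression cross-check against `MASS::rlm`) run on toy
instances of a few samples. On the default NIR conditions the suite
verifies LOOCV R² ≥ 0.97 and RMSECV ≤ 1.0 mmol/L, and that RMSECV
decreases to zero as the instrument noise is scaled to zero — a
parameter-recovery property of the machinery under the stated synthetic
conditions, not a reproduction of laboratory figures, which would require
the original undeposited spectra.

# Known limitations

- The UV/visible region carries almost no direct lactate information
  (one weak band at 747 nm under dominant water harmonics); whatever
  correlation a UV/Vis calibration achieves rides on water displacement,
  and under the default noise model it is markedly worse than NIR/MIR.
  This mirrors the physical situation; treat UV/Vis results accordingly.
- Synthetic spectra are near rank one, so selected LV counts are small;
  do not read them as guidance for laboratory data.
- No PLS2/multi-analyte support, no variable selection, no prediction
  intervals, and no automatic outlier removal, by design.
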