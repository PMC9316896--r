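---
title: "FTIR cleaning verification: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FTIR cleaning verification: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftirclean)
```

## The problem

After a pharmaceutical manufacturing campaign, equipment surfaces must be
verified clean. The classical approach swabs a 25 cm² patch at a
hard-to-clean location and quantifies the residue off-line. A hand-held
FTIR spectrometer in specular reflectance mode can do this in place, but
it interrogates only a 1.76 mm² spot per measurement — a minuscule
fraction of the swabbed area. Two questions then decide whether the
method is defensible:

1. **How many spots must be measured** at one location so that the mean
   of the spot readings is trustworthy, given that residue left by a
   cleaning process is spatially inhomogeneous?
2. **What is the smallest surface density the instrument can quantify**
   (the LOQ), below which the calibration model must not be used?

`ftirclean` implements both procedures, together with a coupon/spectrum
simulator rich enough to exercise every stage without laboratory data,
a PLS calibration, and a pass/fail verification layer. The numbered
scripts under `analysis/` run the whole study; every computational step
lives in the package and is unit-tested.

## Planning the number of measurement points

The planning inputs (`moe_params()`) are a mean surface residue equal to
the visual cleanliness limit (0.6 µg/cm²; any dirtier surface fails
visual inspection and is recleaned, never measured), a worst-case
spatial standard deviation of 0.3 µg/cm² — 50 % RSD, at the top of the
27–53 % band observed for hand-deposited surfaces — a residue acceptance
limit (RAL) of 1 µg/cm², and a two-sided confidence of 99.73 % (the
3σ convention).

For `n` spot measurements the margin of error is

$$\mathrm{MOE}(n) = t_{1-(1-c)/2,\,n-1}\; \frac{s}{\sqrt{n}},$$

and the mean of the `n` readings is expected inside
`mean ± MOE(n)`. The Student-t quantile — not the normal 3.0
multiplier — is essential: at `n = 10` it gives

```{r}
iv <- mean_interval(moe_params(), 10)
round(c(lower = iv$lower, upper = iv$upper, moe = iv$moe), 3)
```

i.e. the interval 0.212–0.988 µg/cm². A normal quantile would give an
upper bound near 0.885, which is not the interval the procedure is built
around. Because surface residue cannot be negative, a negative lower
bound is floored at zero for reporting and the raw value is kept for
diagnostics (`lower_raw`).

Method capability uses the CpK index with σ taken as the margin of
error:

$$\mathrm{CpK}(n) = \frac{\mathrm{USL} - \mathrm{mean}}{3\,\mathrm{MOE}(n)},$$

classified as Poor (< 1.33), Acceptable (1.33–1.67), Good
(1.67–2.00) or Excellent (> 2.00). Values exactly on 1.33 and 1.67 are
classified Acceptable and 2.00 Good; the bands are conventionally quoted
with open edges, so the tie-break had to be decided here.

### A documented discrepancy

Externally reported applications of this procedure quote 7 samples for
CpK ≥ 1.33 and 10 samples for CpK ≥ 1.67. Composing the two formulas
above with the stated planning inputs gives minima of 86 and 133
samples instead — at `n = 10` the capability is only ≈ 0.34. No quantile
convention (t or z) closes that gap. The package therefore computes the
curve honestly and `compare_reported_sample_sizes()` sets the computed
minima against the quoted ones, emitting an explicit discrepancy note
rather than forcing agreement. The 0.212–0.988 interval itself — the
quantity the verification verdicts actually use — is reproduced exactly.

## The coupon and spectrum simulator

The simulator emulates the laboratory set-up that the procedures assume;
its defaults are the study conditions, not tuning knobs.

* **Coupon**: 40 × 40 mm flat plate (the physical coupons' dimensions
  are not critical; 16 cm² comfortably holds the ≤ 5200-droplet pattern
  while leaving room for 1.76 mm² spots).
* **Deposition** (`deposition_profile()`): droplets of 4–10 nL at
  0.5–1 mm pitch, at most 5200 of them. Each droplet spreads its mass as
  a uniform disc of 0.4 mm diameter — the simplest footprint that
  conserves mass exactly while creating spot-scale variance; real spread
  is not documented. `mode = "printer"` tiles the coupon edge-to-edge
  with randomized-pitch cells and one droplet per cell centre
  (cell-centred placement keeps the spatial mass density uniform;
  droplets on cell boundaries would over-weight the coupon edges).
  `mode = "by-hand"` scatters 5000 droplets around 150 uniformly placed
  cluster centres with 8 mm Gaussian spread; these values were fixed
  once so that 1.76 mm² spot sampling of a 0.6 µg/cm² coupon lands in
  the observed 27–53 % RSD band for hand deposition (typically
  40–50 %, the worst-case region the 50 % planning assumption reflects),
  and the printer stays well below it (≈ 25 %).
* **Concentration**: by default the solution concentration is solved
  from the drawn droplet volumes so the coupon's area-averaged density
  hits the target exactly; with a user-fixed concentration the droplet
  count is solved instead, and a target that would need more than 5200
  droplets raises an infeasibility error.
* **Spot measurement** (`sample_spot()`): mass inside a circular
  1.76 mm² footprint divided by the footprint area, computed from exact
  circle–circle intersection areas. Footprints crossing the coupon edge
  are rejected. A droplet disc centred near the coupon edge may overhang
  it; the overhang keeps its mass (physically the liquid stays on the
  plate), which keeps interior spot sampling unbiased to well under 1 %.
* **Spectrum** (`simulate_measurement()`): Gaussian API bands scaling
  linearly with density, one random baseline offset + tilt per
  measurement (coupon-roughness model, σ = 0.01 AU), and white noise of
  0.01 AU per scan averaged over 16 scans (effective σ = 0.0025 AU).
  "16 scans" is modelled as averaging 16 i.i.d. noise realizations;
  interferogram-level co-addition is not modelled. The grid is
  650–4000 cm⁻¹ in 2 cm⁻¹ steps — a typical hand-held sampling interval;
  the true instrument resolution is not documented and the step is
  configurable.
* **API signature** (`default_api_signature()`): a synthetic stand-in
  (bands at 1230 and 2940 cm⁻¹) since the real API spectra are not
  public; every calibration window must contain at least one band.
* **Pseudo blanks** (`generate_pseudo_blank_replicates()`): all
  replicates share one true density *and one baseline realization* —
  the instrument and sample are not moved and the detector temperature
  is constant — while scan noise is drawn independently per replicate.
  This is why the replicate SD isolates the instrument's measurement
  noise rather than surface inhomogeneity.

What the simulator deliberately does **not** model: physical optics of
specular reflectance (no Kramers–Kronig correction), vendor file
formats, non-Gaussian band shapes, drift, or operator effects. Passing
tests therefore demonstrate the statistical machinery under the stated
noise model, not instrument-specific behaviour on real spectra.

## The PLS calibration

Calibration restricts spectra to narrow windows holding the analyte's
strong bands (default 1200.20–1259.84 cm⁻¹; closed intervals at both
endpoints), subtracts a two-point straight line per window (the minimal
correction that removes the roughness-induced offset and tilt — after
it, predictions are exactly invariant to constant spectral offsets), and
mean-centres.

`fit_pls()` is a univariate-response NIPALS recursion: per component the
weight vector is iterated to a relative change below 1e-10 (at most 500
iterations; for a single response the iteration converges immediately,
but the loop keeps the contract uniform), scores and loadings are
extracted, and the predictor block and response are deflated. The
regression vector is `b = W (PᵀW)⁻¹ q`. With full rank the fit equals
ordinary least squares, which the tests exploit as an independent
oracle. Degenerate inputs (constant responses, zero-variance predictor
block, component counts beyond `min(n−1, p)`) raise typed errors.

The component count is chosen by cross-validation with contiguous blocks
of *levels* — all replicates of a calibration level stay in one fold, so
replicate noise never leaks between training and validation — and the
parsimony rule: the smallest count whose CV RMSE is within 5 % of the
minimum. Folds that exhaust their data rank simply drop larger counts
from the comparison.

Models serialize to a self-describing JSON document at full double
precision and round-trip losslessly (`write_pls_model()` /
`read_pls_model()`).

## LOQ and the calibration floor

Ten fixed-point pseudo-blank spectra are predicted through the fitted
model; the sample SD of the ten predicted densities gives
`LOD = 3.3 s` and `LOQ = 10 s`. The multipliers follow the ICH Q2
standard-deviation convention (the exact multiplier used in external
reports is unstated; both are configurable, and the LOQ/LOD ratio is
always `loq_k/lod_k` exactly). Using prediction-space replicates rather
than raw absorbances makes the LOQ reflect the whole measurement chain.
Fewer than 10 replicates gives an error in strict mode or a flagged
exploratory estimate otherwise.

`apply_calibration_floor()` then enforces the rule that a calibration
must not be developed below the LOQ: a model whose training range starts
below the floor is rejected, and predictions below the floor carry a
`below_floor` flag while still returning the numeric value.

## Verification verdicts

`verify_location()` applies the decision logic: a failed visual
inspection short-circuits everything (`not-evaluated-visual-fail`, no
statistics computed); a wrong measurement count is `inconclusive` with a
reason rather than an exception; otherwise the mean of the 10 readings
is compared against the RAL (`pass`/`fail`) and flagged against the
expected 0.212–0.988 interval. The four-way verdict taxonomy is this
package's design; only the pass behaviour and the visual gate are
externally specified. Simulated measurement locations are uniform random
with no overlap constraint ("random locations" leaves overlap
unspecified). Reports round densities to three decimals, matching how
such results are tabulated, and serialize deterministically.

## Problem sizes and numerical choices

Chosen once as the package's own test design:

* Calibration: 5–6 levels spanning 0.5/0.6–3.0 µg/cm², 5 replicates.
* Spot-sampling Monte Carlo: 500–1000 spots per coupon; scan-averaging
  checks use 8000 replicate spectra on a narrow grid.
* The interval-coverage property simulates 300 complete
  coupon → 10-spot → predict → mean cycles and requires < 5 % of means
  outside 0.212–0.988 (the nominal rate is far lower).
* Stochastic assertions run under fixed seeds with 3-standard-error
  bounds; exact identities (mass conservation, window bookkeeping,
  PLS–OLS equivalence) use tolerances of 1e-8 to 1e-12.
* Seeds derived inside the pipeline stay below 2³¹ and every stage of
  `run_pipeline()` draws from its own derived stream, so bundles are
  bit-identical under a repeated seed.

## Limitations

* The simulator's noise model is Gaussian and stationary; real
  hand-held measurements drift and their roughness baseline need not be
  linear across a window.
* The capability procedure treats the planning SD as known; it is a
  worst-case assumption, not an estimate with its own uncertainty.
* The LOQ depends on the simulated noise amplitudes, which stand in for
  an instrument characterization; absolute LOQ values from the pipeline
  characterize the simulator, not any physical spectrometer.
* The 7/10-sample capability claims could not be reproduced from the
  stated formulas (see above); users should treat the computed curve as
  authoritative for these inputs.
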