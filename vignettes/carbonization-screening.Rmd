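---
title: "Screening carbonaceous matter on the carbonization continuum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening carbonaceous matter on the carbonization continuum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carbscreen)
library(dplyr)
```

## The model

First-order Raman spectra of disordered carbonaceous matter (CM) show two
broad envelopes: the defect band D near 1350 cm⁻¹ and the graphite band G
near 1580 cm⁻¹. Following the usual five-band scheme for such spectra, the
baseline-corrected curve over 1000–1800 cm⁻¹ is modelled as the sum of

| band | shape | centre (cm⁻¹) | assignment |
|------|-----------|------|------------------------------------|
| G  | Lorentzian | 1580 | graphitic in-plane E₂g stretch |
| D1 | Lorentzian | 1350 | defect band (disordered graphitic lattice) |
| D2 | Lorentzian | 1620 | shoulder on G (surface graphene layers) |
| D3 | Gaussian   | 1500 | amorphous carbon |
| D4 | Lorentzian | 1200 | disordered aliphatic/ionic impurity band |

with the standard peak forms: a Lorentzian `h / (1 + ((x−c)/(w/2))²)` and a
Gaussian `h·exp(−4·ln 2·(x−c)²/w²)`, each parameterised by height `h`,
centre `c` and full width at half maximum `w`. The shape assignment is
configurable per band.

The screening coordinates are the height ratio **R1 = h(D1)/h(G)** and the
widths **FWHM-D1** and **FWHM-G**. Through carbonization R1 rises (defects
accumulate inside aromatic planes faster than the planes grow) while both
widths fall; through graphitization R1 falls again at already-narrow
widths. That asymmetry is what lets a two-parameter diagram separate the
two processes.

## Fitting: constraints, bounds and numerical choices

`fit_bands()` minimises the residual by bounded Levenberg–Marquardt least
squares (`minpack.lm::nls.lm`, cost tolerance 1e-10, at most 5000 residual
evaluations). Three constraint families matter:

* **Centres** move at most ±10 cm⁻¹ (default) from their canonical
  positions. This is deliberately tight: G and D2 are 40 cm⁻¹ apart and
  both Lorentzian, so with loose centre bounds the two bands can exchange
  intensity along a residual valley — the fit looks perfect while h(G), and
  with it R1, is badly determined. We measured R1 errors above 100% at 2%
  noise with ±40 cm⁻¹ centre freedom, against ~2% with the tight default.
  The slack is a parameter (`center_slack`) for spectra with genuinely
  shifted bands.
* **Widths** live in per-band windows (G 40–120, D1 40–380, D2 20–90,
  D3 60–250, D4 40–200 cm⁻¹) that cover the ranges reported for natural CM
  from immature kerogen to greenschist-facies samples. A single global
  (5, 400) window re-creates the same identifiability problem through D3.
* **Heights** are non-negative and bounded by three times the spectrum
  maximum.

The optimizer is started from the canonical seed of `initial_guess()`
(heights read from the spectrum, widths G 70 / D1 150 / D2 50 / D3 150 /
D4 100 cm⁻¹) and additionally from an immature-type (G 100, D1 280) and a
mature-type (G 55, D1 60) width seed; the lowest-residual solution wins.
The extra starts are deterministic, so fits remain pure functions of their
input; they remove the start-dependence we otherwise observed at the
immature end of the trend, where D1 is broad and shallow. Ties in peak
detection break deterministically (lowest wavenumber in the D window,
highest in the G window).

### Pinning the D1 height

The conventional protocol fixes the D1 height to the observed height of the
D band and lets the remaining parameters adjust. `pin_d1 = TRUE` (default)
implements this with the pin level taken as the Savitzky–Golay-smoothed
curve height at the detected D peak — the local maximum nearest 1350 cm⁻¹,
or the value at 1350 cm⁻¹ when the D band is only a shoulder. Using the raw
window maximum instead would, on immature CM, pin D1 to a point on the
rising D3/G flank plus a positive noise excursion.

The pin equates the observed D maximum with D1 alone. That is accurate when
the D3 + D4 contribution under the D peak is small (mature CM: it is a few
percent), and our tests require pinned R1 within 5% of truth in that
regime. On very immature synthetic spectra the premise fails — D3/D4 tails
reach ~25% of the D1 height — and the pinned fit inherits that bias. For
parameter-accuracy work, and for the graphical-method validation below, the
unconstrained fit (`pin_d1 = FALSE`) is the reference; it recovers noiseless
synthetic bands to better than 1% and keeps the median R1 error near 2% at
2% noise.

## The graphical procedure

When only a plotted spectrum is available (literature figures), R1 and
FWHM-D1 are read directly off the curve. `graphical_params()` smooths with
a Savitzky–Golay filter (window 11 points, order 3 — chosen to perturb
noiseless peak heights by < 0.5%; window 1 disables smoothing), takes the D
height at the local maximum nearest 1350 cm⁻¹ and the G height at the
1560–1640 cm⁻¹ maximum, and measures the D half-width by linear
interpolation between grid points. Two conventions handle band overlap:

* the G search window deliberately admits an unresolved G + D2 envelope, so
  a well-defined D2 drags the apparent G height up and the graphical R1
  down — the documented direction of this bias;
* the right half-width is only sought up to the D/G valley; if the curve
  never falls to half height before the valley, the mirrored left
  half-width is used instead (`overlap_capped` in the output).

Because the whole curve is measured, D3/D4 fill-in widens the apparent D
band: graphical FWHM-D1 overestimates, most strongly on immature CM. Both
bias directions are asserted as one-sided inequalities in the test suite.

`validate_graphical()` runs both procedures over a spectrum collection and
reports the OLS R² per parameter. On a 50-spectrum seeded synthetic series
(below) both R² values land near 0.97–0.98, comfortably above the 0.96/0.94
benchmarks reported for literature-spectrum validations of this shortcut.

## The continuum screen

`classify_maturity()` is a total, deterministic function of (R1, FWHM-D1)
given a `screen_thresholds()` object:

* stage 1 below `stage2_r1` (default 0.9, the midpoint of the reported
  0.8–1 onset range for the second carbonization stage);
* stage 2 up to `altered_r1` (default 2.5, the reported cutoff above which
  CM is unusually altered and unsuitable for biomarker work);
* the carbonization box defaults to R1 0.4–2.5 × FWHM-D1 50–300 cm⁻¹. The
  upper R1 edge is 2.5 rather than the ~2 sometimes quoted for the trend so
  that observed on-trend samples with R1 up to 2.17 stay on-continuum while
  the ≥2.5 group is flagged;
* the graphitization-suspect corner (FWHM-D1 ≤ 60 cm⁻¹ *and* R1 ≤ 0.7) is
  an operational reading of where partially graphitized samples leave the
  continuum; no published numeric criterion exists, so these two numbers
  are defaults, not facts, and suspects are never counted on-continuum or
  as candidates;
* best-preserved candidates are Archean samples (age ≥ 2.5 Ga, or an
  explicit `is_archean` flag) with R1 in 0.72–1, the window where old CM
  demonstrably underwent milder carbonization;
* R1 ≥ 1 attaches a note that published Raman-maturity calibrations place
  R1 = 1 near 300 °C. This is an annotation only; no temperature is ever
  computed — thermometry calibrations are out of scope.

Whether the stage boundary should involve FWHM-D1 jointly with R1 is not
settled; R1 alone is implemented, with FWHM-D1 available in the output for
user-supplied rules. The threshold snapshot rides along in every output row
(`thr_*` columns) so a screened table is self-describing.

## Companion indices

**Atomic H/C** is `(h_wt/m_H)/(c_wt/m_C)` with IUPAC masses 1.008/12.011 by
default; the integer 1/12 convention is selectable because published H/C
tables round inconsistently between the two — neither convention reproduces
every printed value at two decimals, but one of the two always lands within
±0.02.

**NMR aromaticity** splits a baseline-corrected ¹³C spectrum at 90 ppm and
reports the aromatic share (90–240 ppm) of the total trapezoidal area
(−10–240 ppm), clipped to [0, 100]. Window edges are interpolated onto the
grid, making the result invariant under grid refinement and intensity
scaling. Spinning side bands are not removed automatically — their handling
is instrument-specific — but `exclude` windows are bridged by linear
interpolation.

**HRTEM fringe length La.** The published fringe-analysis pipelines for
disordered carbons are proprietary in their details; `carbscreen`
implements a deliberately simple, fully parameterised chain: inverted
difference-of-Gaussians bandpass (σ 1 and 4 px) → binarization (adaptive
Otsu threshold by default; a fixed percentile is available, but must then
match the unknown fringe coverage) → 3×3 morphological closing →
Zhang–Suen thinning → pruning of components under 5 px. `measure_la()`
splits arms at junction pixels (detected by the Rutovitz crossing number;
the whole 3×3 junction neighbourhood is cleared so arms do not reconnect
diagonally), measures each path as its weighted geodesic diameter (straight
steps 1 px, diagonal √2 px), discards fringes under 2 Å (about one aromatic
ring) and reports the number-weighted mean — whether published La values
are number- or length-weighted is unstated; number-weighting is the choice
here. Closed loops would be under-measured by the diameter convention;
they are vanishingly rare in thinned fringe skeletons.

On synthetic images the chain is quantitative for sparse, locally parallel
fringes (mean recovered within ~10%, ≥ 45 of 50 fixed-length fringes
detected) and ordinal at realistic densities: end erosion loses the
shortest fringes and crossings split long ones, so absolute means carry a
density-dependent bias while the ranking of longer- vs shorter-fringed
samples is preserved. La from this pipeline should be read as a relative
maturity index, which is how it is used alongside R1.

## What the synthetic generators emulate

`sim_maturity_series()` parameterises the carbonization trend by a maturity
index m ∈ [0, 1]: R1 interpolates 0.4 → 2.2 (G height fixed at 1), FWHM-D1
280 → 55 cm⁻¹, FWHM-G 100 → 55 cm⁻¹, and the D2/D3/D4 heights fall from
25% to 5% of G, with widths D2 60→40, D3 160→90, D4 120→70 cm⁻¹. The
endpoints bracket the ranges measured on real Phanerozoic-to-Archean
kerogens; the trend deliberately spans slightly beyond them on both sides.
Noise is additive Gaussian with sd a fixed fraction of the D1 height
(default 2%, a typical high-quality accumulation); an optional linear
baseline stands in for fluorescence. All generators are pure functions of
(parameters, seed).

What the synthetics do **not** contain: wavelength-dependent band
dispersion, shot noise, cosmic-ray spikes, curved fluorescence backgrounds,
mineral bands from incomplete demineralisation, or precursor-dependent band
shapes. Passing the recovery and validation suites therefore demonstrates
the estimators are correct and stable under the stated noise model, not
that any real spectrum will fit this well; on instrument data the fit
diagnostics (`residual_rms`, `converged`, the per-band table) are the guide.

Problem sizes used by the test suite and the acceptance script — 50-spectrum
series for validation, 30 for recovery, images up to 448² px — were chosen
as the smallest sets at which the checked statistics are stable.

## Known limitations

* Comparability of R1/FWHM-D1 across instruments is established for
  514.5/532 nm excitation only; other lasers require an explicit override
  and invalidate cross-study comparison.
* The five-band model is a convention: no sixth band is fitted, area-based
  ratios are not computed, and the second-order region is ignored.
* The pinned fit and the graphical reading both lean on the D ≈ D1 premise;
  on very immature CM both carry known biases (documented above), and the
  free fit is the accurate reference.
* The screen ranks thermal maturity. It says nothing about biogenicity —
  carbonized abiotic CM falls on the same continuum.
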