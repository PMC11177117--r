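---
title: "Models and methods behind mesowide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mesowide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesowide)
```

`mesowide` processes recordings from a single-camera widefield mesoscope
that interleaves four illumination wavelengths — 470-nm and 565-nm
fluorescence excitation plus 525-nm and 625-nm reflectance — one per
camera frame. This vignette explains the models the package implements,
the parameters that matter, the numerical choices made, and what the
bundled phantom generator does and does not emulate.

## Data model

An acquisition is a height × width × frames stack in detector counts with
a wavelength cycle (e.g. `c(470, 565, 525, 625)`). `demultiplex()` sends
frame *k*, *k*+L, *k*+2L, … of an L-label cycle to channel *k*, so every
channel samples the scene once per cycle: with the typical 100-ms cycle,
each channel runs at 10 Hz. Frames within one cycle are at most ~100 ms
apart and are treated as simultaneous everywhere downstream; this skew is
negligible against the hemodynamic timescales of interest (seconds) and
acceptable for the fluorescence channels at the signal bandwidths the
instrument targets. Incomplete trailing cycles are trimmed with a warning
rather than rejected, because acquisitions routinely stop mid-cycle.
Pixel coordinates are 0-based, row-major, origin top-left in every
module; polygon and ellipse ROIs use pixel-center inclusion.

Vendor metadata dialects are deliberately not parsed; a documented JSON or
YAML sidecar (`dtype`, `height`, `width`, `n_frames`, `cycle_nm`,
`exposure_ms`, `cycle_period_ms`, `pixel_size_um`) accompanies either a
multipage TIFF or a flat, frame-major raw binary file.

## Hemoglobin estimation

The two-wavelength modified Beer–Lambert model treats the change in
optical density per unit pathlength at each reflectance wavelength as a
linear combination of oxy- and deoxyhemoglobin concentration changes:

$$\Delta OD_\lambda(t) = -\frac{1}{X_\lambda}\log_{10}
\frac{I_\lambda(t)}{I^0_\lambda}
= \varepsilon^{HbO}_\lambda \Delta[HbO](t)
+ \varepsilon^{HbR}_\lambda \Delta[HbR](t).$$

*Units.* ε in cm⁻¹ M⁻¹ (base-10 convention), pathlengths X in cm,
concentrations in mol/L (display in µM). The log base is 10 throughout so
tabulated molar extinction coefficients apply directly; it is a single
shared constant (`log_base`), and the forward model in the generator uses
the same constant, so round trips are exact in either base.

*Explicit solution.* Rather than a per-sample 2×2 solve,
`precompute_constants()` folds the extinction coefficients, pathlengths
and baseline images into four scalars (`c525_hbo`, `c625_hbo`,
`c525_hbr`, `c625_hbr`) and two per-pixel offset images (`a0_hbo`,
`a0_hbr`), after which `estimate_hemodynamics()` is two multiply-adds per
pixel and frame. `solve_bruteforce()` keeps the direct linear solve as an
independent reference; the test suite requires agreement to 1e−10
relative on random inputs. The determinant
ε₆₂₅^HbO ε₅₂₅^HbR − ε₆₂₅^HbR ε₅₂₅^HbO must be nonzero; proportional
extinction rows raise a degeneracy error naming it.

*Baselines.* I⁰ is the pixelwise temporal mean over the full record or a
configured frame range. Zero or negative baselines, and nonpositive
intensities at otherwise valid pixels, mask the pixel (NA) with a warning
instead of being clipped — clipping would silently bias the logarithm.
With a full-record mean baseline the estimated concentration changes
average to approximately zero over the record; this is exact only in the
small-ΔOD limit and is tested at |ΔOD| ≤ 1e−3.

*Pathlengths.* X₅₂₅, X₆₂₅ and the fluorescence-path X_ex, X_em are
inputs, normally taken from published Monte-Carlo photon-transport
estimates for the species and geometry at hand. The defaults in
`pathlength_set()` (0.06, 0.4, 0.056, 0.057 cm) are representative
placeholders so that examples and simulations run; quantitative analysis
of real data must supply measured values. Because the generator and the
inversion share whatever values are configured, validation results do not
depend on their accuracy.

*Extinction table.* The bundled
`hemoglobin_extinction_synthetic.csv` is a constructed, smooth,
representative spectrum (correct band structure and magnitudes,
near-isosbestic behavior around 525 nm, HbR ≫ HbO above 600 nm), labelled
synthetic because it is not measured data. Supply a measured compilation
via `read_extinction_table()` for real work. Coefficients at intermediate
wavelengths are interpolated linearly in wavelength; queries outside the
tabulated range are errors.

## Fluorescence chain

ΔF/F is stored as ratio-minus-one (0 at baseline) for both channels.
Linear detrending removes the per-pixel OLS line (mean and slope); it is
idempotent and linear, and is implemented as one shared projection over
all pixels.

*Hemodynamic correction.* Rising hemoglobin darkens the green channel on
both the excitation and emission paths. With
$\Delta\mu_a(\lambda,t) = \ln(10)[\varepsilon_{HbO}(\lambda)\Delta[HbO] +
\varepsilon_{HbR}(\lambda)\Delta[HbR]]$, the measured ratio is the
artifact-free ratio times $e^{-\Delta\mu_a(\lambda_{ex})X_{ex}
-\Delta\mu_a(\lambda_{em})X_{em}}$, and `correct_hemodynamics()`
multiplies by the inverse factor. The correction is applied to the green
channel by default; red-channel correction is available but off, since
red excitation and emission fall where hemoglobin absorption is far
weaker. λ_em defaults to 523 nm, the center of a typical 500–540-nm green
detection band, and is configurable because a detection band has no
unique single wavelength.

*Operation order.* The pipeline follows the conventional order ΔF/F →
detrend → hemodynamic correction. For validation round trips the package
applies the correction *before* detrending: the correction is a
pointwise multiplicative inverse of the forward attenuation, so
correct-then-detrend recovers the detrended true signal to machine
precision, whereas detrend-then-correct leaves a small residual of order
(fitted trend) × (attenuation amplitude) — typically 1e−4 of the signal —
because detrending and the multiplicative correction do not commute. Both
orders are available; the difference is documented here so users can
choose deliberately.

*Crosstalk.* Off-peak excitation of the red fluorophore contributes a
fraction C of its fluorescence to the 470-nm measurement. Correction
subtracts C × F₅₆₅ frame-by-frame on raw intensities, before ΔF/F, since
the mixing is linear in intensity. The pipeline default is C = 0 — under
typical expression levels and illumination the benefit is marginal and
the subtraction adds red-channel noise into the green trace — with the
correction opt-in via `crosstalk_c`.

## Crosstalk calibration

The in-vitro procedure images purified green- and red-fluorophore
solutions under alternating 470/565-nm illumination across a grid of LED
powers and exposure times. Radiant energy E = power × exposure collapses
the grid; the illumination ratio R = E_off/E_on collapses pairs of
conditions. For each target R, up to 20 measurement pairs whose energy
ratio matches R within a relative tolerance (default 1%, configurable —
no tolerance is inherent to the method) are selected deterministically by
closeness to R, and C is the OLS slope of F_off against F_on. The
intercept is fitted freely rather than forced through zero because blank
subtraction is never perfect; the fit reports slope SE and R². The
resulting C(R) curve is interpolated piecewise-linearly in log R (R spans
decades) and never extrapolated.

With fluorescence strictly linear in E, the analytic curve is
C(R) = (eff_off/eff_on)·R; fits on noiseless synthetic series recover it
to numerical precision, and to ~1–2% under 1% multiplicative noise. Note
that multiplicative noise affects both fit axes, so the plain OLS slope
(kept because the method is defined as a linear fit) carries an
errors-in-variables error dominated by the highest-energy pairs;
occasional deviations slightly above 2% at unlucky noise draws are
expected behavior, not a defect.

*Overcorrection diagnostic.* For independent green and red source
signals, the zero-lag correlation of (F₄₇₀ − c·F₅₆₅) with F₅₆₅ is
positive when c is below the true mixing ratio, near zero at it, and
negative beyond it. The test suite verifies this sign pattern on
generator scenes driven by exactly orthogonal sinusoids; on real data the
diagnostic is only indicative, because the two indicators covary
physiologically.

## Trials, ratio maps, pupil

`align_trials()` interpolates each trial linearly onto a fixed relative
grid (default 0.1-s step) around stimulus onset, dropping trials whose
window leaves the record. `ratio_map()` normalizes each trial to its
pre-stimulus window — subtracting the window mean for fractional-change
inputs (dividing is available for raw intensities), with the full
pre-stimulus span as the default window since no single convention is
canonical — averages across trials, and reads out the frame at the
requested latency (1.7 s for hemodynamic and neuromodulator maps, 0.1 s
for fast calcium maps, interpolating between grid frames as needed).

Pupil size is the count of pixels inside a manually drawn ellipse whose
intensity falls below a manual threshold — an area proxy;
`equivalent_diameter()` converts to 2√(count/π). The trace is normalized
to its own min/max within the recording, which makes it invariant to
affine rescaling of the raw counts. Illumination-transition analysis
computes, per transition, the ratio of mean normalized size 2–3 s after
the transition to 1.5–0.5 s before it, and compares groups with a
two-sample t test. The equal-variance (Student) test is the default, with
Welch optional; `transition_analysis()` compares the on- and
off-transition groups of one recording, and
`compare_transition_groups()` compares two recordings (e.g. illumination
shielding present versus absent). The comparison is unpaired, since
transitions in different recordings do not correspond.

## Trigger-schedule simulation

`build_schedule()` emulates the camera/LED gating logic: a rolling-shutter
sensor exposes rows with staggered timing; the FIRE-ALL signal is high
only while all rows expose simultaneously (exposure minus the row-readout
span); each LED is driven by the AND of FIRE-ALL with its
wavelength-selection window, so the sample is never illuminated during
partial-row exposure. Gate and driver latencies (ns–µs) are modeled as
zero, being negligible against 2–8-ms exposures. Frame slots are spaced
uniformly at cycle_period/L; the true intra-cycle spacing of the original
control scripts is not public, and uniform spacing preserves every
invariant that matters (containment, non-overlap, per-channel rate).
`validate_schedule()` checks all invariants and is fuzz-tested against an
independent pairwise interval-overlap oracle. The photoswitching protocol
variant interleaves cycles that illuminate at 470 nm without capturing
(FIRE-ALL bypass) with cycles that omit 470-nm illumination entirely.

Stimulus trains are defined by duration, rate, repetitions and
interstimulus interval; a 2-s, 3-Hz train holds ⌊duration·rate⌋ = 6
pulses.

## The phantom generator

`generate_scene()` runs the full forward model: reflectance channels are
attenuated by Beer–Lambert absorption of programmed hemoglobin
transients, the green channel is darkened by the corresponding
excitation/emission absorption and mixed with a programmable fraction of
the red channel, channels are interleaved per cycle, and noise (Gaussian
or Poisson on detector counts) is applied last. Defaults emulate the
study conditions: a 64-pixel-scale field at 20 µm/pixel, a 100-ms
four-wavelength cycle, micromolar hemoglobin transients
(Δ[HbO] ≈ +1 µM, Δ[HbR] ≈ −0.4 µM at peak) in a Gaussian activation
blob, a few-percent green signal and up to tens-of-percent red calcium
transients, and detector counts in the thousands. The first 20% of
cycles are quiescent, providing an exact baseline window; stimulus
scenes instead use the pre-stimulus period. Stimulus-evoked hemodynamics
are a difference-of-gamma kernel (peak 1.7 s, undershoot ~5.5 s)
convolved with the stimulus envelope — pure test scaffolding, since the
processing chain never fits a response model; one calcium transient per
stimulus pulse and a slower filtered envelope drive the red and green
signals.

What the generator does *not* emulate: optical blur and scattering,
vascular geometry, heartbeat/respiration physiological noise, motion,
photobleaching, photoswitching, spatially varying pathlengths, and the
physiological covariance between indicators. Passing round-trip tests
therefore demonstrates correctness of the implemented transformations
and their inverses, not robustness to every artifact of real
recordings.

## Numerical choices and problem sizes

Degenerate inputs fail loudly: singular extinction systems name the
determinant, infeasible schedules name the exposure/readout conflict,
out-of-range interpolation (wavelength or R) is an error, and masked
pixels propagate as NA rather than fabricated values. Determinism is
bitwise for a fixed seed in the generator and exact in schedule
construction.

The validation suite exercises the inversion at 64×64×400 frames
(100 cycles), the solver/oracle agreement at 10⁴ random samples,
schedule fuzzing at 10³ parameter sets, and 20 transitions per pupil
condition — sizes chosen to match the documented study conditions while
keeping a full run in seconds on one CPU. Results at these sizes are
scale-free: every assertion is a relative error, a sign, or exact
arithmetic, none of which depend on the image dimensions.

## Known limitations

Three-wavelength or spectrally resolved fitting, scattering corrections
and absolute (non-differential) concentrations are out of scope, as are
isosbestic-excitation correction, automated pupil tracking, atlas
registration and any hardware control. The hemodynamic correction
assumes hemoglobin dominates dynamic absorption and that the configured
pathlengths are valid for the preparation; both assumptions should be
revisited for preparations other than adult mouse cortex under a glass
window.
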