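# mesowide

Processing of single-camera, four-wavelength widefield mesoscope
recordings of mouse cortex.

Widefield ("mesoscopic") imaging systems record the whole dorsal cortex by
strobing one LED per camera frame: two fluorescence excitation wavelengths
(470 nm for a green indicator such as an EGFP-based neuromodulator sensor,
565 nm for a red mApple-based calcium indicator) and two reflectance
wavelengths (525 and 625 nm) for hemoglobin absorption, all on one sCMOS
detector. A four-frame cycle of typically 100 ms gives an effective 10-Hz
sampling rate per channel. `mesowide` implements the offline processing
chain for such recordings, for experimenters who need hemoglobin
concentration maps, hemodynamics-corrected fluorescence, trial-averaged
response maps, pupil-diameter statistics, and simulated trigger schedules.

## The core computation

Changes in optical density at the two reflectance wavelengths relate
linearly to oxy- and deoxyhemoglobin concentration changes through the
modified Beer–Lambert law:

    ΔOD_λ = −log₁₀(I_λ(t) / I_λ⁰) / X_λ = ε_λ^HbO Δ[HbO] + ε_λ^HbR Δ[HbR],
    λ ∈ {525, 625}

with molar extinction coefficients ε (cm⁻¹ M⁻¹), effective photon
pathlengths X (cm, from published Monte-Carlo estimates), and the baseline
intensity I⁰ taken as the temporal average per pixel. Instead of solving
the 2×2 system per pixel and timepoint, the package folds everything
constant over time and space into four scalar coefficients and two
per-pixel offset images,

    Δ[HbO] = A₀^HbO + C₅₂₅^HbO* log(I₅₂₅(t)) − C₆₂₅^HbO* log(I₆₂₅(t))

(and analogously for Δ[HbR]), which reduces the per-frame work to two
multiply-adds per pixel. A brute-force per-sample linear solve is included
as an independent oracle.

The measured green fluorescence is darkened by time-varying hemoglobin
absorption on the excitation and emission paths; with
Δμa(λ,t) = ln(10)·[ε_HbO(λ)Δ[HbO] + ε_HbR(λ)Δ[HbR]], the correction is

    1 + ΔF/F_corr = (1 + ΔF/F_meas) · exp(Δμa(λ_ex)X_ex + Δμa(λ_em)X_em).

Spectral crosstalk of the red fluorophore into the 470-nm channel is
removed by subtracting a calibrated fraction C of the 565-nm frame; C is
estimated from an in-vitro dilution series as the slope of off-peak
versus on-peak fluorescence over measurement pairs matched to a common
illumination ratio R (radiant-energy ratio), yielding a C-versus-R curve.

All of it is exercised against a bundled forward-model phantom generator
whose scenes are exactly invertible when noiseless.

## Worked example

```r
library(mesowide)

# a synthetic 32x32, 100-cycle acquisition with ~1 uM hemoglobin transients
sc <- generate_scene(scene_params(height = 32, width = 32, n_cycles = 100), seed = 1)
ch <- demultiplex(sc$acq)

eps   <- default_extinction_table()
paths <- pathlength_set()                     # replace for quantitative work
k <- precompute_constants(eps, paths,
       compute_baseline(ch[["525"]], sc$truth$baseline_cycles),
       compute_baseline(ch[["625"]], sc$truth$baseline_cycles))
m <- estimate_hemodynamics(ch[["525"]], ch[["625"]], k)
max(m$hbo) * 1e6                              # peak dHbO in uM
#> [1] 0.9912494
max(abs(m$hbo - sc$truth$hbo)) / max(abs(sc$truth$hbo))
#> [1] 1.887108e-12                            # exact inversion (noiseless)

d  <- compute_dff(ch[["470"]], compute_baseline(ch[["470"]], sc$truth$baseline_cycles))
dc <- correct_hemodynamics(d, m, eps, paths)  # undo hemodynamic darkening
max(abs(dc$data - sc$truth$s_green))
#> [1] 9.027501e-15                            # artifact-free signal recovered

s <- build_schedule(c(470, 565, 525, 625), c(5, 5, 3, 3),
                    cycle_period_ms = 100, readout_ms = 2, n_cycles = 10)
effective_channel_rate(s)                     # Hz per channel
#> [1] 10
validate_schedule(s)                          # no violations
#> character(0)
```

The peak Δ[HbO] of ~1 µM is the generator's programmed transient; the
~1e−12 and ~1e−14 errors show that the explicit solver and the
fluorescence correction invert the forward model to numerical precision.
`run_pipeline()` chains all stages from a single config (YAML/JSON or
`pipeline_config()`) and writes HDF5 maps, CSV traces, ratio maps and a
JSON manifest with content hashes.

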