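# ionorange

Proton-therapy range verification from the acoustic resonance of an
implanted gold fiducial marker — a simulation pipeline.

## The problem

Spot-scanning proton therapy concentrates dose at the Bragg peak, but the
peak's depth (the *range*, R0) carries a few-percent uncertainty from CT
calibration and anatomy. Ionoacoustics offers an in-vivo probe: a pulsed
beam deposits energy, the deposit becomes an initial pressure
p0 = Γ·E (Grüneisen conversion), and the pressure propagates to a
transducer. This package implements and analyses a marker-based variant:
a spherical gold fiducial (already implanted for image guidance) is both a
strong thermoacoustic source (protons transfer ~9.5× more energy per mm in
gold; Γ_gold/Γ_water ≈ 32) and an acoustic resonator — the gold/water
impedance mismatch traps ~95% of the pressure amplitude, and only the
sphere's eigenmodes

    f_res = v_gold · n / φ_m      (1.62 MHz and 3.24 MHz for φ_m = 2.0 mm)

leak out as a slow ringdown. Every proton that enters the marker while
stopping inside it deposits its full residual kinetic energy, so the
ringdown amplitude A tracks the residual range R_res = R0 − Z_m (Z_m =
marker depth), and over 0 < R_res ≤ 9 mm a per-spot linear calibration

    R_res = C1 · A + C0

turns a single-transducer amplitude into a range estimate.

## What the package provides

* `stopping_power`, `csda_range`, `bragg_curve`, `build_dose_grid`,
  `marker_deposited_energy` — analytic Bethe/CSDA pencil-beam dose on a
  voxel grid, with the marker hot spot and downstream cold shadow.
* `build_source`, `pulse_derivatives` — Grüneisen source conversion and the
  Gaussian pulse factor.
* `propagate` — 3-D k-space pseudospectral acoustic solver (staggered FFT
  derivatives, k-space dispersion correction, split-field PML),
  heterogeneous density/sound speed.
* `ringdown`, `resonance_frequency`, `amplitude_factor`,
  `radial_eigenmode` — fast spherically symmetric solver for the marker
  ringdown plus the closed-form resonator theory.
* `trace_spectrum`, `resonance_amplitude`, `bipolar_metrics`,
  `trace_difference` — fixed-policy spectral analytics.
* `range_calibration` (a classed model with `coef`/`predict`/`plot`/
  `residuals` methods), `estimate_range`, `required_particles`,
  `attenuation_factor`, `spot_position_sensitivity` — the calibration and
  its error budget.
* `simulate_spot` — the hybrid end-to-end run (coarse 3-D beam waveform +
  radial marker component on one detector line).

See the vignette (`vignettes/ionoacoustic-range-verification.Rmd`) for the
models, assumptions and numerical choices.

## Worked example

```r
library(ionorange)

water <- ia_material("water"); gold <- ia_material("gold")

# theory: eigenfrequencies of the 2.0 mm marker, beam range at 60 MeV
resonance_frequency(gold$v, 2e-3, n = 1:2) / 1e6
#> [1] 1.62 3.24
csda_range(60, water)
#> [1] 30.86524

# a marker 9 mm short of the Bragg peak: deposited energy and ringdown
beam <- beam_spec(60, 5, 100)          # 60 MeV, sigma = 5 mm, 100 ns pulse
marker <- marker_spec(2, 22)           # 2.0 mm gold sphere at 22 mm depth
ed <- marker_deposited_energy(beam, marker, r_res = 9)
ed
#> [1] 0.5360945
tr <- ringdown(marker, ed, 100e-9, r_detector = 20.6e-3)
ra <- resonance_amplitude(trace_spectrum(tr), 1.62e6)
ra$frequency / 1e6
#> [1] 1.62323
```

The simulated ringdown of the 2 mm sphere peaks at 1.623 MHz, 0.2% above
the v/φ prediction. Calibrating amplitude against residual range over the
case-2 window (eight radial-solver runs, ~20 s):

```r
sweep <- amplitude_sweep(beam, marker_diameter = 2, r_res = 1:8)
cal <- range_calibration(sweep$amplitude, sweep$r_res)
cal
#> Amplitude-to-residual-range calibration  R_res = C1 * A + C0
#>   C1 = 4.466e+10 mm/amplitude-unit, C0 = -5.236 mm
#>   window: 1..8 mm, R^2 = 0.9629, relative slope 9.89 %/mm
predict(cal, newdata = sweep$amplitude[5])  # r_res was 5
#>      r_res delta_r extrapolated
#> 1 5.411413       0        FALSE

# noise budget: protons per pulse for 1 mm precision at the quoted
# transducer noise density and calibration slope
required_particles(0.03, 1.62e6, 2.3e6, delta_r = 1)
#> [1] 80500000
```

The R² of 0.96 and the ~10 %/mm whole-window slope reflect the concavity
of A(R_res) — the local growth rate is ~16 %/mm in the lower half of the
window and flattens towards the case boundary (see the vignette).

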