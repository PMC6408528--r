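---
title: "Ionoacoustic range verification with a resonant gold marker: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ionoacoustic range verification with a resonant gold marker: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The physical picture

A pulsed proton pencil beam deposits energy `E(r)` in tissue; under stress
and thermal confinement the deposit converts instantaneously into an initial
pressure `p0 = Gamma E` (Grueneisen conversion, `Gamma = beta v^2 / Cp`),
which then propagates as an acoustic wave. An implanted spherical gold
fiducial marker changes this picture in two ways. First, gold is a far
stronger source than water: protons lose ~9.5x more energy per unit path in
gold, and gold's Grueneisen coefficient (3.47) is ~32x water's (0.11).
Second, the acoustic impedance mismatch (6.3e7 vs 1.5e6 N s/m^3) reflects
~95% of the pressure amplitude back into the sphere at each encounter with
the surface, so the deposited energy cannot leave as a simple pulse.
Non-resonant components cancel under repeated reflection; what survives are
the eigenmodes of the sphere, which leak out slowly. The marker rings at

    f_res = v_gold * n / phi_m        (n = 1, 2, ...)

i.e. 1.62 MHz and 3.24 MHz for the 2.0 mm marker -- frequencies that depend
only on the marker, not on the beam or the detector position. Because every
proton that enters the marker and stops inside it deposits its full residual
kinetic energy, the amplitude of this ringdown tracks the residual range
`R_res = R0 - Z_m` (proton range minus marker depth), and a per-spot linear
calibration `R_res = C1 A + C0` turns one transducer measurement into a
range estimate.

## Pipeline and models

The package is organised as the simulation chain below; each stage is exchangeable
through plain-text containers.

**Dose (`stopping_power`, `csda_range`, `bragg_curve`,
`build_dose_grid`, `marker_deposited_energy`).** Monte Carlo transport is
replaced by an analytic model: Bethe electronic stopping power with ICRU 49
mean excitation energies (water 75 eV, gold 790 eV), CSDA ranges by
integrating `1/S(E)` from a 0.5 MeV floor, and Gaussian range straggling of
width `sigma_R = 0.012 R^0.935` (R in cm; Bortfeld's parametrisation). The
model reproduces reference stopping-power tables for water to better than
2% between 10 and 100 MeV and gives a 60 MeV range of 30.9 mm. Nuclear
interactions and secondary transport are neglected; this biases absolute
dose at the few-percent level but not the resonance physics. On the voxel
grid the pencil beam is the separable product of the straggled depth-dose
and the lateral Gaussian (sigma fixed at its surface value of 5 mm by
default; a linear-growth option exists but the reference configuration does
not use it). A marker is voxelised by centre inclusion; each beam column
crossing the sphere is ray-traced: gold stopping inside the chord (protons
that exhaust their energy deposit the remainder on the spot -- the hot
spot), and a water curve shifted by the chord's water-equivalent thickness
downstream (the cold shadow).

**Source (`build_source`, `pulse_derivatives`).** Per-voxel energy (MeV per
proton) becomes an energy density (J/m^3) and then an initial pressure
amplitude via the medium's Grueneisen coefficient. The beam's time structure
is Gaussian: `dG/dt` is the unit-area Gaussian of width `sigma_p`, and its
Fourier magnitude `exp(-(2 pi f sigma_p)^2/2)` is exactly the pulse-width
envelope of the resonance amplitude. By default the energy landing in gold
is redistributed uniformly over the sphere before conversion
(`uniformise_marker_energy = TRUE`): gold's thermal diffusivity is ~850x
water's, so the marker thermalises quickly and acts as a
spherically-symmetric source.

**3-D propagation (`propagate`).** A first-order pressure/particle-velocity
k-space pseudospectral scheme: FFT spatial derivatives on staggered grids
with the `sinc(c_ref k dt / 2)` dispersion correction (reference speed =
water). At the desk-scale 1 mm grid a finite-difference stencil would be
useless at the beam waveform's ~5 points per wavelength; the k-space scheme
is exact for homogeneous media at the reference speed, and the solver
reproduces the closed-form free-field solution of a Gaussian-ball source to
0.1% in L2 (3% is asserted in tests). The source enters as additive
pressure increments `p0 * dG/dt * dt`, sampled half a time step early so the
staggered (leapfrog) injection is centred -- without this the whole
waveform arrives half a step early, a first-order error in `dt`. A
split-field perfectly matched layer (10 voxels, quartic grading, 1e-6
target reflection) absorbs outgoing waves; the layer lives in a padded
margin outside the physical phantom (`pad_source`) so it never overlaps the
dose region. Heterogeneous density is handled by averaging onto the
staggered faces. The CFL number is capped at 0.3 (the reference runs use
dt = 100 ns at 1 mm, CFL 0.15).

**Radial marker solver (`ringdown`).** The marker ringdown needs ~10 um
resolution, hopeless in 3-D but trivial in the spherically symmetric
reduction: a staggered first-order update in `r` with the `1/r^2` geometric
terms, the gold/water interface exactly at `phi_m/2` (cell-centred gold,
interface on a face, inverse-density averaging), a characteristic
impedance condition plus a 2 mm damping sponge at the outer boundary, and
the same uniform Grueneisen source. Gold is treated as a fluid (no shear),
consistent with the scalar wave equation used throughout. The simulated
2.0 mm marker peaks at 1.6232 MHz, 0.2% above `v/phi_m`; diameters 1-3 mm
all sit within 0.2% of the `v n/phi_m` line; peak amplitudes across
`sigma_p` = 30-500 ns follow the analytic envelope (relative agreement
better than 2% wherever the envelope exceeds 1% of its 100 ns value; below
that the comparison is absolute, since the 500 ns amplitude is ~4e-6 of the
normalisation and sits at the numerical floor of the spectrum).

**Hybrid superposition (`simulate_spot`).** The observed waveform
decomposes into the wave from the pencil-beam dose outside the marker and
the wave from the marker itself. The coarse 3-D run carries the first
(the cold shadow's effect on it is small and slow); the radial solver
carries the second, scaled by the fluence-weighted deposited energy and
superposed on the common time base. By construction the with/without
difference trace equals the marker component exactly, which is also how a
measurement would isolate it (with- minus without-marker differencing).

**Analysis (`trace_spectrum`, `resonance_amplitude`, `bipolar_metrics`).**
One fixed spectral policy everywhere: Tukey(0.1) window, zero-padding to at
least 4x the record (next power of two), one-sided magnitude `2 dt |FFT|`.
Absolute spectral units are internal; every scientific claim uses ratios or
slopes. The "no signal" gate for a resonance peak is 5x the median spectral
magnitude in the 2.5-4 MHz sideband.

**Calibration and error budget (`range_calibration`,
`estimate_range`, `required_particles`, `attenuation_factor`,
`spot_position_sensitivity`).** `range_calibration` is an ordinary
least-squares fit of `R_res = C1 A + C0` over at least four case-2 points,
returned as a fitted-model object with `coef`/`predict`/`plot`/`residuals`
methods and first-order uncertainty propagation (`delta_R = |C1| delta_A`).
The noise budget converts a transducer noise density (0.03 mPa/sqrt(Hz))
over a bandwidth (default `(35/0.03)^2` Hz, i.e. ~1.36 MHz, chosen to
reproduce the 35 mPa noise level quoted for a 1.62 MHz resonance; the
bandwidth is exposed because it is otherwise unstated) into the particle
count needed per pulse for a target precision: ~8.0e7 protons for 1 mm with
C1 = 2.3e6 mm proton/mPa. Tissue attenuation is applied analytically
(`10^(-0.54 f_MHz path_cm / 20)`); the propagation grids themselves are
lossless water; the propagation media themselves carry no absorption.

## Numerical and design choices

* **Units.** SI inside the solvers (kg/m^3, Pa, s, m); table units
  (g/cm^3, mm, ns, mPa) at the interfaces. Traces are mPa per proton.
* **Time origin.** `t = 0` is the incident pulse peak everywhere; solvers
  start 5 `sigma_p` early so the pulse ramps from ~0.
* **Confinement margin.** "Much smaller than the relaxation times" is
  operationalised as a factor-of-10 ratio. Note that at `sigma_p` = 500 ns
  the stress margin in water is only 6.7, so the flag reports
  non-confinement there even though the waveform consequences are
  negligible (the envelope, not confinement, is what suppresses the
  signal).
* **Arrival-time convention.** The marker component's onset matches the
  *surface*-to-detector distance over the water sound speed
  ((20.6 - 1.0) mm / 1.5 mm/us = 13.07 us for the reference geometry);
  a centre-to-centre convention would predict 13.7 us and does not match
  the observed timing.
* **Case-2 boundary.** `classify_case` uses the canonical 9 mm boundary for
  the 60 MeV / 2 mm configuration. The energy model's own turnover
  (`case2_boundary`, the argmax of deposited energy vs `R_res`) sits near
  12 mm: rim chords are shorter than the axial chord, so pass-through
  begins gradually rather than at a sharp threshold.
* **Amplitude slope.** The deposited energy -- and hence the resonance
  amplitude -- grows with `R_res` like the residual energy at the marker
  entrance, roughly `(R_res + 1 mm)^0.56`, flattened further at the top of
  the window by rim pass-through. The *local* growth rate therefore falls
  from ~26 %/mm at `R_res` = 1.5 mm through ~16 %/mm near 3 mm to ~10 %/mm
  at the case boundary; a single linear fit over the whole 1-8 mm window,
  divided by the mid-window amplitude, gives 9.9 %/mm. Both statistics are
  reported; the often-quoted "~15% per mm" corresponds to the local rate in
  the lower half of the window, not to the whole-window fit.
* **Consequence for round-trip accuracy.** Because `A(R_res)` is concave, a
  3-point linear calibration interpolates a held-out interior position to
  ~0.5 mm but extrapolating to a held-out window edge errs by 1-1.6 mm.
  Calibrations should span the window they will be used on.
* **Spot-position sensitivity.** The worst case is taken over nominal
  beam-centre placements within one lateral sigma of the marker (the field
  extent is otherwise unspecified); for sigma = 5 mm and a 0.2 mm error
  this gives 4.0%, in line with the quoted 3.9%, but the geometric
  assumption behind that figure is not stated, so equality is not asserted.
* **Problem sizes.** The package's reference ("desk-scale") configuration
  uses a 1 mm propagation grid (48 x 32 x 48 mm phantom plus a 12-voxel
  absorbing margin, dt = 100 ns, 35 us records) and a 10 um radial grid to
  25 mm; these were chosen so the full acceptance pipeline and test suite
  run on a single CPU in minutes while keeping every headline observable
  grid-converged (halving either step changes the resonance estimate by
  <1% and the oracle error by half).

## What the synthetic data do and do not emulate

The generator reproduces the reference conditions: a 60 MeV pencil beam
(sigma = 5 mm at the surface, Gaussian pulses of 30-500 ns, range ~31 mm),
a 2.0 mm gold sphere at depths 16-38 mm in a water phantom, and detectors
on a line 20.6 mm from the beam axis. It does *not* emulate nuclear
interactions, secondary-electron transport, MCS growth of the spot with
depth (off by default), shear waves in the gold, tissue heterogeneity or
transducer response. Passing tests therefore demonstrate the resonance
mechanism and its scalings under the stated model, not dosimetric accuracy
in patients.

## Known limitations

Absolute pressures depend on the dose model at the ~10% level (the
reference no-marker peak, 3.9e-5 mPa/proton on the detector line, is within
10% of the value obtained with full Monte Carlo dose input, but this is
partly fortuitous). The calibration constant `C1` depends on the spectral
normalisation and is meaningful only within one fixed analysis policy.
The 3-D solver's coarse preset cannot carry the 1.62 MHz marker wave
(0.9 mm wavelength in water); marker physics must go through the radial
solver (hybrid mode), which assumes spherical symmetry of the marker source
and ignores the beam-marker cross term in the wave field (exact in linear
acoustics for superposed sources).
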