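# Thermoacoustic source: convert a dose grid into the driven-wave-equation
# source p0 = Gamma * E (energy density), with the separable Gaussian time
# factor G(t) whose derivative is the unit-area pulse shape.

#' Build the pressure source field from a dose grid
#'
#' Converts per-voxel transferred energy (MeV per proton) into the initial
#' pressure amplitude p0 = Gamma * E_density, in Pa per proton, using each
#' voxel's medium (gold voxels use gold's Grueneisen coefficient, water
#' voxels water's). Unit chain: MeV/voxel -> J/m^3 -> Pa.
#'
#' @param dose A [build_dose_grid()] result (must carry a medium map).
#' @param materials A [read_materials()] database.
#' @param uniformise_marker_energy If `TRUE` (default, matching the
#'   spherically-symmetric-source analysis: gold thermalises quickly), the
#'   energy deposited in gold voxels is redistributed uniformly over the
#'   marker before conversion.
#' @return A list of class `pressure_source`: `p0` (3-D array, Pa/proton),
#'   `spacing`, `x`, `y`, `z` (mm), `sigma_pulse` (s), `n_protons`.
#' @export
build_source <- function(dose, materials = read_materials(),
                         uniformise_marker_energy = TRUE) {
  if (is.null(dose$medium)) stop("build_source: dose grid lacks a medium map")
  w <- ia_material("water", materials)
  voxel_m3 <- (dose$spacing * 1e-3)^3
  energy <- dose$energy
  gold_vox <- dose$medium == 1L
  if (uniformise_marker_energy && any(gold_vox)) {
    energy[gold_vox] <- sum(energy[gold_vox]) / sum(gold_vox)
  }
  p0 <- energy * (MEV_TO_J / voxel_m3) * w$gamma
  if (any(gold_vox)) {
    g <- ia_material("gold", materials)
    p0[gold_vox] <- p0[gold_vox] / w$gamma * g$gamma
  }
  structure(list(p0 = p0, spacing = dose$spacing,
                 x = dose$x, y = dose$y, z = dose$z,
                 sigma_pulse = dose$beam$sigma_pulse * 1e-9,
                 n_protons = dose$beam$n_protons),
            class = "pressure_source")
}

#' @export
print.pressure_source <- function(x, ...) {
  cat(sprintf("<pressure_source> %dx%dx%d @ %g mm, max p0 = %.3g Pa/proton, sigma_p = %g ns\n",
              length(x$x), length(x$y), length(x$z), x$spacing,
              max(x$p0), x$sigma_pulse * 1e9))
  invisible(x)
}

#' Construct a pressure source field directly
#'
#' Low-level constructor for a `pressure_source` from an explicit initial
#' pressure array (Pa per proton), used for synthetic sources in validation
#' against closed-form solutions. Coordinates are voxel centres; x and y are
#' centred on the grid, z starts at half a voxel (depth convention).
#'
#' @param p0 3-D array of initial pressure amplitude, Pa per proton.
#' @param spacing Isotropic voxel edge, mm.
#' @param sigma_pulse Pulse width sigma_p, s.
#' @param n_protons Protons per pulse.
#' @param centred_z If `TRUE`, centre the z axis like x and y.
#' @return A `pressure_source`.
#' @export
pressure_source_field <- function(p0, spacing, sigma_pulse = 100e-9,
                                  n_protons = 1, centred_z = FALSE) {
  d <- dim(p0)
  ax <- function(n) (seq_len(n) - (n + 1) / 2) * spacing
  z <- if (centred_z) ax(d[3]) else (seq_len(d[3]) - 0.5) * spacing
  structure(list(p0 = p0, spacing = spacing,
                 x = ax(d[1]), y = ax(d[2]), z = z,
                 sigma_pulse = sigma_pulse, n_protons = n_protons),
            class = "pressure_source")
}

#' Gaussian pulse time factor and derivatives
#'
#' The beam's temporal factor G(t) has a unit-area Gaussian derivative
#' dG/dt = exp(-t^2 / 2 sigma_p^2) / sqrt(2 pi sigma_p^2); the driven wave
#' equation's source term uses d2G/dt2, its analytic derivative. The Fourier
#' magnitude of dG/dt at frequency f is exp(-(2 pi f sigma_p)^2 / 2), the
#' resonance-amplitude envelope.
#'
#' @param sigma_p Pulse width sigma_p, s.
#' @param t Times, s (vectorised), measured from the pulse peak.
#' @return List with `dG` (1/s) and `d2G` (1/s^2).
#' @export
#' @examples
#' pulse_derivatives(100e-9, 0)
pulse_derivatives <- function(sigma_p, t) {
  if (sigma_p <= 0) stop("pulse_derivatives: sigma_p must be positive")
  dG <- exp(-t^2 / (2 * sigma_p^2)) / sqrt(2 * pi * sigma_p^2)
  list(dG = dG, d2G = -t / sigma_p^2 * dG)
}
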