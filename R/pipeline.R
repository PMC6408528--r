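# End-to-end spot simulation. Desk-scale preset: a coarse (1 mm) 3-D k-space
# run carries the low-frequency pencil-beam waveform, while the marker's
# high-frequency resonance is delegated to the radial solver and superposed
# (hybrid mode). This mirrors the decomposition of the observed waveform
# into components originating outside and inside the marker; the cold-shadow
# distortion of the beam component is neglected (it is small and slow).

#' Embed a source field in a PML-padded propagation domain
#'
#' Pads the physical grid with `pad` voxels of background water on every
#' side so the absorbing layer sits outside the phantom, and shifts the
#' coordinate axes accordingly.
#' @param source A `pressure_source`.
#' @param pad Padding, voxels.
#' @return A padded `pressure_source`.
#' @export
pad_source <- function(source, pad) {
  d <- dim(source$p0)
  p0 <- array(0, d + 2 * pad)
  p0[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- source$p0
  s <- source
  s$p0 <- p0
  ext <- function(ax) {
    dx <- ax[2] - ax[1]
    c(ax[1] - dx * (pad:1), ax, ax[length(ax)] + dx * (1:pad))
  }
  s$x <- ext(source$x); s$y <- ext(source$y); s$z <- ext(source$z)
  s
}

#' Simulate one pencil-beam spot
#'
#' Runs the full pipeline for one spot: analytic dose grid, thermoacoustic
#' source, coarse 3-D propagation to a line of detectors and -- when a
#' marker is present -- the radial marker ringdown scaled by the
#' fluence-weighted deposited energy, superposed on the beam waveform
#' (hybrid mode). Detectors lie on a line parallel to the beam axis at
#' `lateral` mm (the reference geometry uses 20.6 mm).
#'
#' @param beam A [beam_spec()].
#' @param marker A [marker_spec()] or `NULL` for the no-marker run.
#' @param detector_z Detector depths, mm.
#' @param lateral Lateral distance of the detector line from the beam axis, mm.
#' @param spacing Propagation voxel size, mm (desk-scale default 1 mm).
#' @param extent Physical grid extents (lx, ly, lz), mm.
#' @param duration Recording length after the pulse peak, s.
#' @param dt 3-D solver time step, s.
#' @param pml_size PML thickness, voxels (padding adds `pml_size + 2`).
#' @param beam_trace Optional precomputed no-marker beam trace on the same
#'   geometry (reused across marker positions; the beam component does not
#'   depend on the marker in hybrid mode).
#' @param ringdown_args Extra arguments passed to [ringdown()].
#' @return List of class `spot_simulation`: `trace` (total), `beam_trace`,
#'   `marker_trace` (`NULL` without marker), `deposited_energy` (MeV/proton),
#'   `r_res` (mm), `beam`, `marker`.
#' @export
simulate_spot <- function(beam, marker = NULL,
                          detector_z = seq(6, 40, by = 2), lateral = 20.6,
                          spacing = 1, extent = c(48, 32, 48),
                          duration = 35e-6, dt = 1e-7, pml_size = 10,
                          beam_trace = NULL, ringdown_args = list()) {
  detectors <- cbind(x = lateral, y = 0, z = detector_z)
  if (is.null(beam_trace)) {
    dose <- suppressWarnings(
      build_dose_grid(beam, marker = NULL, spacing = spacing, extent = extent))
    src <- pad_source(build_source(dose), pml_size + 2)
    med <- medium_grid(src) # homogeneous water: marker physics is radial
    beam_trace <- propagate(src, med, detectors, duration, dt = dt,
                            pml_size = pml_size)
  }
  marker_trace <- NULL
  e_dep <- NULL
  r_res <- NULL
  total <- beam_trace
  if (!is.null(marker)) {
    water <- ia_material("water")
    r_res <- residual_range(csda_range(beam$energy, water), marker$depth)
    e_dep <- marker_deposited_energy(beam, marker, r_res)
    r_det <- sqrt(lateral^2 + (detector_z - marker$depth)^2) * 1e-3
    if (is.null(ringdown_args$r_max))
      ringdown_args$r_max <- max(r_det) + 4e-3
    rd <- do.call(ringdown, c(list(marker = marker, deposited_energy = e_dep,
                                   sigma_p = beam$sigma_pulse * 1e-9,
                                   r_detector = r_det,
                                   duration = duration), ringdown_args))
    # superpose on the beam trace's time base
    pm <- vapply(seq_along(r_det), function(j) {
      stats::approx(rd$times, rd$pressure[, j], xout = beam_trace$times,
                    yleft = 0, yright = 0)$y
    }, numeric(length(beam_trace$times)))
    marker_trace <- pressure_trace(beam_trace$times,
                                   pm * beam$n_protons,
                                   detectors = detectors,
                                   units = beam_trace$units)
    total <- pressure_trace(beam_trace$times,
                            beam_trace$pressure + marker_trace$pressure,
                            detectors = detectors, units = beam_trace$units)
  }
  structure(list(trace = total, beam_trace = beam_trace,
                 marker_trace = marker_trace,
                 deposited_energy = e_dep, r_res = r_res,
                 beam = beam, marker = marker),
            class = "spot_simulation")
}

#' @export
print.spot_simulation <- function(x, ...) {
  cat(sprintf("<spot_simulation> %s marker; max |p| = %.3g %s\n",
              if (is.null(x$marker)) "no" else
                sprintf("phi=%g mm at Z=%g mm (R_res=%g mm)",
                        x$marker$diameter, x$marker$depth, x$r_res),
              max(abs(x$trace$pressure)), x$trace$units))
  invisible(x)
}

#' Resonance amplitude versus residual range
#'
#' For each case-2 marker depth, computes the fluence-weighted deposited
#' energy and runs the radial ringdown to the co-depth detector, then
#' extracts the resonance amplitude from the windowed zero-padded spectrum.
#' The backbone of the calibration (and of the ~15 %/mm amplitude slope).
#'
#' @param beam A [beam_spec()].
#' @param marker_diameter Marker diameter, mm.
#' @param r_res Residual ranges to sweep, mm.
#' @param lateral Detector distance from the marker centre, mm (detector at
#'   the marker depth).
#' @param duration Ringdown recording length, s.
#' @param dr Radial step, m.
#' @return Data frame: `r_res`, `z_m`, `deposited_energy` (MeV/proton),
#'   `amplitude`, `frequency` (Hz), `flagged`.
#' @export
amplitude_sweep <- function(beam, marker_diameter = 2,
                            r_res = 1:8, lateral = 20.6,
                            duration = 30e-6, dr = 10e-6) {
  water <- ia_material("water")
  r0 <- csda_range(beam$energy, water)
  f1 <- resonance_frequency(ia_material("gold")$v, marker_diameter * 1e-3, 1)
  rows <- lapply(r_res, function(rr) {
    mk <- marker_spec(marker_diameter, r0 - rr)
    ed <- marker_deposited_energy(beam, mk, rr)
    if (ed <= 0) {
      return(data.frame(r_res = rr, z_m = r0 - rr, deposited_energy = ed,
                        amplitude = 0, frequency = NA_real_, flagged = TRUE))
    }
    tr <- ringdown(mk, ed, beam$sigma_pulse * 1e-9, lateral * 1e-3,
                   duration = duration, dr = dr)
    ra <- resonance_amplitude(trace_spectrum(tr), f1)
    data.frame(r_res = rr, z_m = r0 - rr, deposited_energy = ed,
               amplitude = ra$amplitude, frequency = ra$frequency,
               flagged = ra$flagged)
  })
  do.call(rbind, rows)
}
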