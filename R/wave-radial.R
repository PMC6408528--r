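# Spherically symmetric acoustics of the marker: closed-form resonator theory
# (eigenmodes of the sphere under a pressure-release boundary, pulse-width
# amplitude envelope) and a fast staggered-grid radial solver for the
# ringdown of the gold sphere embedded in water. The gold is treated as a
# fluid (no shear), consistent with the scalar wave equation.

#' Resonance frequencies of a spherical marker
#'
#' Eigenfrequencies of the scalar wave equation inside a sphere of diameter
#' phi_m with zero pressure at the surface (the large gold/water impedance
#' mismatch makes the boundary nearly perfectly reflecting):
#' `f_res = v * n / phi_m`.
#'
#' @param v_marker Speed of sound in the marker, m/s.
#' @param diameter Marker diameter phi_m, m.
#' @param n Mode index, positive integer (vectorised).
#' @return Frequency, Hz. 1.62 MHz for the 2.0 mm gold marker (n = 1).
#' @export
#' @examples
#' resonance_frequency(3240, 2e-3, 1:2) / 1e6 # 1.62, 3.24 MHz
resonance_frequency <- function(v_marker, diameter, n = 1) {
  if (v_marker <= 0 || diameter <= 0)
    stop("resonance_frequency: v and diameter must be positive")
  if (any(n < 1) || any(n != round(n)))
    stop("resonance_frequency: n must be a positive integer")
  v_marker * n / diameter
}

#' Pulse-width amplitude envelope
#'
#' Relative resonance amplitude for a Gaussian pulse of width sigma_p:
#' `A(sigma_p) = exp(-(2 pi f_res sigma_p)^2 / 2)`, the Fourier magnitude of
#' the pulse derivative at the resonance frequency. Optionally normalised to
#' a reference pulse width.
#'
#' @param sigma_p Pulse width(s), s (vectorised); zero gives 1.
#' @param f_res Resonance frequency, Hz.
#' @param normalise_at Optional reference sigma_p, s; when given the envelope
#'   is divided by its value there (plots are normalised at 100 ns).
#' @return Dimensionless amplitude factor.
#' @export
#' @examples
#' amplitude_factor(c(30, 100, 200) * 1e-9, 1.62e6, normalise_at = 100e-9)
amplitude_factor <- function(sigma_p, f_res, normalise_at = NULL) {
  if (any(sigma_p < 0)) stop("amplitude_factor: sigma_p must be >= 0")
  a <- exp(-(2 * pi * f_res * sigma_p)^2 / 2)
  if (!is.null(normalise_at))
    a <- a / exp(-(2 * pi * f_res * normalise_at)^2 / 2)
  a
}

#' Radial eigenmode profile
#'
#' Zero-order spherical Bessel profile `p(r') = sin(r')/r'` in the scaled
#' radial coordinate `r' = 2 pi f r / v`; the pressure-release boundary
#' condition p(pi f phi_m / v) = 0 places the surface at r' = n pi, which is
#' the origin of the `v n / phi_m` eigenfrequencies.
#'
#' @param r_prime Scaled radial coordinate(s), >= 0.
#' @return Profile value; 1 at the origin (sinc limit).
#' @export
#' @examples
#' radial_eigenmode(c(0, pi / 2, pi))
radial_eigenmode <- function(r_prime) {
  if (any(r_prime < 0)) stop("radial_eigenmode: r_prime must be >= 0")
  out <- rep(1, length(r_prime))
  nz <- r_prime > 0
  out[nz] <- sin(r_prime[nz]) / r_prime[nz]
  out
}

#' Marker ringdown (spherically symmetric solver)
#'
#' First-order pressure/radial-velocity update on a staggered radial grid
#' with the gold/water interface exactly at phi_m/2 and 1/r^2 geometric
#' terms. The thermoacoustic source is a uniform pressure rise inside the
#' marker, p0 = Gamma_gold * energy density, injected with the unit-area
#' Gaussian time factor dG/dt. The outer boundary combines a characteristic
#' (plane-wave impedance) condition with a damping sponge so outgoing waves
#' are absorbed. The trace shows the marker's decaying resonant oscillation;
#' its spectral peak sits at `resonance_frequency(n = 1)`.
#'
#' @param marker A [marker_spec()].
#' @param deposited_energy Energy deposited in the marker per proton, MeV.
#' @param sigma_p Pulse width, s.
#' @param r_detector Detector radii from the marker centre, m (vectorised).
#' @param duration Recording length, s (t = 0 at the pulse peak).
#' @param dr Radial step, m; must resolve the marker (<= phi_m/200).
#' @param r_max Domain radius, m (a sponge of `sponge` m sits inside it).
#' @param cfl Courant number (v_max dt / dr), must be < 1.
#' @param sponge Sponge-layer thickness, m.
#' @param allow_interior Permit detector radii at or inside the marker
#'   surface (used to compare the confined interior pressure with the
#'   radiated wave).
#' @return A [pressure_trace] with one column per detector, mPa per proton.
#' @export
#' @examples
#' \donttest{
#' tr <- ringdown(marker_spec(2, 22), 0.5, 100e-9, 10e-3, 30e-6)
#' }
ringdown <- function(marker, deposited_energy, sigma_p, r_detector,
                     duration = 30e-6, dr = 10e-6, r_max = 25e-3,
                     cfl = 0.3, sponge = 2e-3, allow_interior = FALSE) {
  gold <- marker$material
  water <- ia_material("water")
  a <- marker$diameter / 2 * 1e-3 # m
  if (!allow_interior && any(r_detector <= a))
    stop("ringdown: detector must sit outside the marker")
  if (any(r_detector > r_max - sponge))
    stop("ringdown: detector inside the sponge; enlarge r_max")
  if (dr > marker$diameter * 1e-3 / 200)
    stop("ringdown: dr must be <= phi_m/200 to resolve the marker")
  if (cfl >= 1) stop("ringdown: CFL must be < 1")

  n <- ceiling(r_max / dr)
  r_c <- (seq_len(n) - 0.5) * dr      # cell centres (pressure)
  r_f <- seq_len(n) * dr              # faces (velocity), face i at i*dr
  in_gold <- r_c < a
  rho <- ifelse(in_gold, gold$rho, water$rho)
  v <- ifelse(in_gold, gold$v, water$v)
  # inverse density at interior faces (average of adjacent cells)
  inv_rho_f <- c((1 / rho[-n] + 1 / rho[-1]) / 2)

  dt <- cfl * dr / max(v)
  nt_pre <- ceiling(5 * sigma_p / dt) # lead-in so the pulse ramps from ~0
  nt <- ceiling(duration / dt) + nt_pre
  times <- (seq_len(nt) - nt_pre) * dt

  # uniform source amplitude inside the sphere, Pa per proton
  e_density <- deposited_energy * MEV_TO_J / (4 / 3 * pi * a^3)
  p0 <- gold$gamma * e_density
  g <- pulse_derivatives(sigma_p, times - dt / 2)$dG # centre the leapfrog injection
  src_cells <- which(in_gold)

  # sponge damping profile (on cells and faces), quartic ramp
  damp_prof <- function(r) {
    d <- pmax(r - (r_max - sponge), 0) / sponge
    exp(-8 * d^4 * max(v) / sponge * dt)
  }
  damp_c <- damp_prof(r_c)
  damp_f <- damp_prof(r_f[-n])

  rhoc2 <- rho * v^2
  r2f <- r_f^2
  r2c <- r_c^2
  det_idx <- vapply(r_detector, function(rd) which.min(abs(r_c - rd)), integer(1))

  p <- numeric(n)
  u <- numeric(n - 1) # interior faces 1..n-1; face at r=0 carries u=0
  rec <- matrix(0, nt, length(det_idx))
  ci <- dt / dr
  z_out <- water$rho * water$v
  for (it in seq_len(nt)) {
    u <- (u - ci * inv_rho_f * (p[-1] - p[-n])) * damp_f
    # outer characteristic boundary: outgoing u at the last face
    u_out <- p[n] / z_out
    flux <- c(r2f[-n] * u, r_f[n]^2 * u_out)
    dive <- (flux - c(0, flux[-n])) / (r2c * dr)
    p <- (p - dt * rhoc2 * dive) * damp_c
    p[src_cells] <- p[src_cells] + p0 * g[it] * dt
    rec[it, ] <- p[det_idx]
  }
  keep <- times >= 0
  pressure_trace(times = times[keep], pressure = rec[keep, , drop = FALSE] * 1e3,
                 detectors = cbind(x = r_detector * 1e3, y = 0, z = marker$depth),
                 units = "mPa/proton")
}
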