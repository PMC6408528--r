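# Analytic stand-in for Monte Carlo proton transport: Bethe stopping power,
# CSDA range with Gaussian range straggling, pencil-beam dose on a voxel grid
# with an embedded gold sphere (hot spot + downstream cold shadow).
# Nuclear interactions and secondary-particle transport are neglected.

#' Beam specification
#'
#' @param energy Incident kinetic energy, MeV (validated to (1, 250)).
#' @param sigma_lateral Lateral Gaussian sigma at the water surface, mm.
#' @param sigma_pulse Temporal Gaussian pulse width sigma_p, ns (30-500 for
#'   confinement-validated use; values outside give a warning, not an error).
#' @param n_protons Protons per pulse.
#' @param axis_offset Lateral (x, y) offset of the beam axis, mm.
#' @return A list of class `beam_spec`.
#' @export
#' @examples
#' beam_spec(60, 5, 100)
beam_spec <- function(energy = 60, sigma_lateral = 5, sigma_pulse = 100,
                      n_protons = 1, axis_offset = c(0, 0)) {
  if (energy <= 1 || energy >= 250)
    stop("beam_spec: energy must lie in (1, 250) MeV")
  if (sigma_lateral <= 0) stop("beam_spec: sigma_lateral must be positive")
  if (sigma_pulse < 30 || sigma_pulse > 500)
    warning("sigma_pulse outside the confinement-validated band [30, 500] ns")
  structure(list(energy = energy, sigma_lateral = sigma_lateral,
                 sigma_pulse = sigma_pulse, n_protons = n_protons,
                 axis_offset = rep_len(axis_offset, 2)),
            class = "beam_spec")
}

#' Marker specification
#'
#' @param diameter Sphere diameter phi_m, mm.
#' @param depth Centre depth Z_m along the beam axis, mm.
#' @param material A [ia_material()] record; defaults to gold.
#' @return A list of class `marker_spec`.
#' @export
#' @examples
#' marker_spec(2, 22)
marker_spec <- function(diameter = 2, depth = 22, material = ia_material("gold")) {
  if (diameter <= 0) stop("marker_spec: diameter must be positive")
  structure(list(diameter = diameter, depth = depth, material = material),
            class = "marker_spec")
}

#' Linear proton stopping power (Bethe model)
#'
#' Electronic stopping power -dE/dx from the Bethe formula with the medium's
#' density, Z/A and mean excitation energy (water I = 75 eV, gold I = 790 eV,
#' ICRU 49). Valid for proton energies of roughly 0.5-250 MeV; shell and
#' density-effect corrections are omitted (sub-percent here).
#'
#' @param energy Proton kinetic energy, MeV (vectorised).
#' @param medium A [ia_material()] record.
#' @return Linear stopping power, MeV/mm.
#' @export
#' @examples
#' stopping_power(60, ia_material("water"))
stopping_power <- function(energy, medium) {
  if (any(energy < 0.5) || any(energy > 250))
    stop("stopping_power: energy outside Bethe validity window (0.5, 250) MeV")
  gam <- 1 + energy / PROTON_MASS_MEV
  beta2 <- 1 - 1 / gam^2
  wmax_ev <- 2 * ELECTRON_MASS_MEV * beta2 * gam^2 * 1e6 # max energy transfer, eV
  s_mass <- K_BETHE * medium$z_over_a / beta2 *
    (log(wmax_ev / medium$i_ev) - beta2) # MeV cm^2/g
  s_mass * medium$rho_g_cm3 / 10 # MeV/mm
}

# Shared energy grid for range integration / inverse lookup (0.5 MeV floor),
# cached per medium.
.range_cache <- new.env(parent = emptyenv())
.range_table <- function(medium, e_max = 249, n = 4000) {
  key <- paste(medium$name, medium$i_ev, medium$rho_g_cm3, sep = "|")
  hit <- .range_cache[[key]]
  if (!is.null(hit)) return(hit)
  e <- seq(0.5, e_max, length.out = n)
  inv_s <- 1 / stopping_power(e, medium)
  r <- c(0, cumsum((inv_s[-1] + inv_s[-n]) / 2 * diff(e))) # mm, trapezoid
  tab <- list(e = e, r = r)
  .range_cache[[key]] <- tab
  tab
}

#' CSDA range
#'
#' Continuous-slowing-down range, the integral of 1/S(E) from a 0.5 MeV floor
#' (the sub-floor residual path is ~0.008 mm in water) up to the given energy.
#'
#' @param energy Proton kinetic energy, MeV (vectorised).
#' @param medium A [ia_material()] record.
#' @return Range, mm. About 31 mm for 60 MeV protons in water.
#' @export
#' @examples
#' csda_range(60, ia_material("water"))
csda_range <- function(energy, medium) {
  if (any(energy < 0.5) || any(energy > 249))
    stop("csda_range: energy outside validity window")
  tab <- .range_table(medium)
  stats::approx(tab$e, tab$r, xout = energy)$y
}

#' Residual energy from a CSDA range (inverse lookup)
#'
#' @param range Residual CSDA range, mm; values at or below zero return 0.5
#'   MeV (the integration floor, effectively stopped).
#' @param medium A [ia_material()] record.
#' @return Proton kinetic energy, MeV.
#' @export
residual_energy <- function(range, medium) {
  tab <- .range_table(medium)
  out <- stats::approx(tab$r, tab$e, xout = pmax(range, 0), rule = 2)$y
  out[range <= 0] <- 0.5
  out
}

# Bortfeld's range-straggling width, sigma_R = 0.012 * R^0.935 (R in cm).
.straggling_sigma <- function(range_mm) {
  0.012 * (range_mm / 10)^0.935 * 10
}

#' Central-axis Bragg curve
#'
#' CSDA depth-dose dE/dz per proton on a depth grid, convolved with a Gaussian
#' range-straggling kernel of width sigma_R = 0.012 R^0.935 (Bortfeld's
#' parametrisation, R in cm). Energy not deposited on the grid (the sub-floor
#' residual) is the only loss; the depth integral conserves energy to <1%.
#'
#' @param beam A [beam_spec()].
#' @param depth_grid Depths, mm, uniform spacing, covering at least
#'   `[0, csda_range + 10]`.
#' @param medium Medium, default water.
#' @return Numeric vector: deposited energy per mm per proton at each depth.
#' @export
#' @examples
#' z <- seq(0, 45, by = 0.2)
#' d <- bragg_curve(beam_spec(60, 5, 100), z)
#' z[which.max(d)] # Bragg peak near 31 mm
bragg_curve <- function(beam, depth_grid, medium = ia_material("water")) {
  r0 <- csda_range(beam$energy, medium)
  sig <- .straggling_sigma(r0)
  dz <- diff(depth_grid)
  if (max(abs(dz - dz[1])) > 1e-9 * dz[1])
    stop("bragg_curve: depth_grid must be uniform")
  dz <- dz[1]
  if (max(depth_grid) < r0 + 10)
    stop("bragg_curve: depth_grid must cover [0, csda_range + 10 mm]")
  if (dz > sig / 2)
    warning("bragg_curve: grid coarser than sigma_R/2; straggling under-resolved")
  # Straggling = Gaussian distribution of the proton's range: average the
  # sharp CSDA curve over range perturbations u ~ N(0, sig).
  nodes <- seq(-4, 4, length.out = 33)
  w <- stats::dnorm(nodes); w <- w / sum(w)
  d <- numeric(length(depth_grid))
  for (k in seq_along(nodes)) {
    res <- (r0 + nodes[k] * sig) - depth_grid
    dk <- numeric(length(res))
    live <- res > 0
    dk[live] <- stopping_power(residual_energy(res[live], medium), medium)
    d <- d + w[k] * dk
  }
  d
}

#' Voxelized pencil-beam dose grid
#'
#' Builds the per-proton transferred-energy grid E(r) for a Gaussian pencil
#' beam along +z (z = depth from the water surface), optionally with a gold
#' sphere on the beam axis. Without a marker the grid is the separable product
#' of the straggled Bragg curve and the (depth-constant) lateral Gaussian.
#' With a marker, each (x, y) column intersecting the sphere is ray-traced:
#' inside the gold chord the proton loses energy at the gold stopping power
#' (stopping protons deposit all residual energy), and the downstream water
#' curve is shifted by the chord's water-equivalent thickness, producing the
#' cold shadow.
#'
#' @param beam A [beam_spec()].
#' @param marker A [marker_spec()] or `NULL`.
#' @param spacing Isotropic voxel edge, mm.
#' @param extent Length-3 vector (lx, ly, lz), mm: lateral half-extents are
#'   lx/2 and ly/2 about the beam axis; depth runs 0..lz.
#' @param sigma_growth Optional Highland-style lateral growth coefficient
#'   (mm of added sigma per mm of depth); default 0 (sigma constant with
#'   depth, as specified only at the surface).
#' @return A list of class `dose_grid`: `spacing`, `x`, `y`, `z` (voxel-centre
#'   coordinates, mm), `energy` (3-D array, MeV per voxel per proton),
#'   `medium` (3-D array, 0 = water, 1 = gold), `beam`, `marker`.
#' @export
#' @examples
#' g <- build_dose_grid(beam_spec(60, 5, 100), marker_spec(2, 22),
#'                      spacing = 0.5, extent = c(24, 24, 45))
build_dose_grid <- function(beam, marker = NULL, spacing = 0.2,
                            extent = c(30, 30, 45), sigma_growth = 0) {
  water <- ia_material("water")
  nx <- round(extent[1] / spacing); ny <- round(extent[2] / spacing)
  nz <- round(extent[3] / spacing)
  x <- (seq_len(nx) - (nx + 1) / 2) * spacing
  y <- (seq_len(ny) - (ny + 1) / 2) * spacing
  z <- (seq_len(nz) - 0.5) * spacing
  if (!is.null(marker)) {
    a <- marker$diameter / 2
    if (marker$depth - a < 0 || marker$depth + a > max(z) + spacing / 2 ||
        a > max(x) || a > max(y))
      stop("build_dose_grid: marker extends outside the grid")
    if (spacing > marker$diameter / 8)
      stop("build_dose_grid: spacing too coarse to resolve the marker (need >= 8 voxels across)")
  }
  r0 <- csda_range(beam$energy, water)
  if (max(z) < r0 + 5)
    stop("build_dose_grid: z extent must cover the proton range")
  dcurve <- bragg_curve(beam, z, water) # MeV/mm per proton, straggled

  sig_z <- beam$sigma_lateral + sigma_growth * z
  # lateral fluence fraction per voxel column at (x, y): product of 1-D
  # Gaussian voxel integrals (exact for the separable Gaussian)
  gauss_frac <- function(u, sig) {
    stats::pnorm(u + spacing / 2, 0, sig) - stats::pnorm(u - spacing / 2, 0, sig)
  }
  energy <- array(0, c(nx, ny, nz))
  medium <- array(0L, c(nx, ny, nz))
  xo <- x - beam$axis_offset[1]
  yo <- y - beam$axis_offset[2]
  colfrac <- outer(gauss_frac(xo, sig_z[1]), gauss_frac(yo, sig_z[1]))
  if (sigma_growth == 0) {
    fxy <- outer(gauss_frac(xo, sig_z[1]), gauss_frac(yo, sig_z[1]))
    for (k in seq_len(nz)) energy[, , k] <- fxy * (dcurve[k] * spacing)
  } else {
    for (k in seq_len(nz)) {
      fxy <- outer(gauss_frac(xo, sig_z[k]), gauss_frac(yo, sig_z[k]))
      energy[, , k] <- fxy * (dcurve[k] * spacing)
    }
  }

  if (!is.null(marker)) {
    gold <- marker$material
    a <- marker$diameter / 2
    zm <- marker$depth
    sig_r <- .straggling_sigma(r0)
    nodes <- seq(-3, 3, length.out = 13)
    wq <- stats::dnorm(nodes); wq <- wq / sum(wq)
    for (i in seq_len(nx)) for (j in seq_len(ny)) {
      b2 <- x[i]^2 + y[j]^2
      if (b2 >= a^2) next
      h <- sqrt(a^2 - b2)
      z_in <- zm - h; z_out <- zm + h
      col_frac <- colfrac[i, j] # fluence fraction of this column
      # voxel-centre classification along the chord
      in_chord <- z > z_in & z < z_out
      medium[i, j, in_chord] <- 1L
      dep <- numeric(nz)
      for (q in seq_along(nodes)) {
        r0q <- r0 + nodes[q] * sig_r
        res_in <- r0q - z_in # residual water range at marker entrance
        if (res_in <= 0) { # beam stops upstream of the marker
          depq <- numeric(nz)
          live <- !in_chord & z < z_out & (r0q - z) > 0
          depq[live] <- stopping_power(residual_energy(r0q - z[live], water),
                                       water) * spacing
          dep <- dep + wq[q] * depq
          next
        }
        e_in <- residual_energy(res_in, water)
        depq <- numeric(nz)
        up <- z <= z_in
        resu <- r0q - z[up]
        liveu <- resu > 0
        depq[up][liveu] <- stopping_power(residual_energy(resu[liveu], water),
                                          water) * spacing
        # march through the gold chord voxel by voxel
        e_cur <- e_in
        for (k in which(in_chord)) {
          if (e_cur <= 0.5) { depq[k] <- depq[k] + 0; next }
          seg <- min(z[k] + spacing / 2, z_out) - max(z[k] - spacing / 2, z_in)
          de <- stopping_power(e_cur, gold) * seg
          if (de >= e_cur - 0.5) { # stops inside this voxel
            depq[k] <- depq[k] + e_cur
            e_cur <- 0
          } else {
            depq[k] <- depq[k] + de
            e_cur <- e_cur - de
          }
        }
        if (e_cur > 0.5) { # survived the chord: shifted water curve downstream
          r_rem <- csda_range(e_cur, water)
          down <- z >= z_out
          resd <- r_rem - (z[down] - z_out)
          lived <- resd > 0
          depq[down][lived] <- stopping_power(residual_energy(resd[lived], water),
                                              water) * spacing
        }
        dep <- dep + wq[q] * depq
      }
      energy[i, j, ] <- col_frac * dep
    }
  }
  structure(list(spacing = spacing, x = x, y = y, z = z,
                 energy = energy, medium = medium,
                 beam = beam, marker = marker),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %dx%dx%d voxels @ %g mm, total %.3g MeV/proton%s\n",
              length(x$x), length(x$y), length(x$z), x$spacing,
              sum(x$energy),
              if (is.null(x$marker)) "" else
                sprintf(", marker phi=%g mm at Z=%g mm",
                        x$marker$diameter, x$marker$depth)))
  invisible(x)
}

#' Energy deposited in the marker per proton
#'
#' Fluence-weighted energy transferred to the gold sphere as a function of the
#' residual range `r_res = R0 - Z_m` at the marker centre. For each lateral
#' impact parameter the proton either stops inside the gold chord (case 2:
#' deposits all residual kinetic energy) or traverses it (case 1: deposits the
#' chord-integrated gold energy loss); a Gaussian range-straggling smear makes
#' the transition continuous, and markers beyond the range (case 3) receive
#' ~nothing.
#'
#' @param beam A [beam_spec()].
#' @param marker A [marker_spec()].
#' @param r_res Residual range(s) at the marker centre, mm (vectorised).
#' @return Energy per proton, MeV.
#' @export
#' @examples
#' marker_deposited_energy(beam_spec(60, 5, 100), marker_spec(2, 22), 9)
marker_deposited_energy <- function(beam, marker, r_res) {
  water <- ia_material("water")
  gold <- marker$material
  a <- marker$diameter / 2
  sig <- beam$sigma_lateral
  r0 <- csda_range(beam$energy, water)
  sig_r <- .straggling_sigma(r0)
  # radial fluence quadrature over the marker disc
  nb <- 40
  b <- (seq_len(nb) - 0.5) / nb * a
  db <- a / nb
  wb <- (b / sig^2) * exp(-b^2 / (2 * sig^2)) * db # Gaussian ring weights
  h <- sqrt(a^2 - b^2)
  # straggling quadrature
  nodes <- seq(-3, 3, length.out = 13)
  wq <- stats::dnorm(nodes); wq <- wq / sum(wq)
  vapply(r_res, function(rr) {
    tot <- 0
    for (q in seq_along(nodes)) {
      res_in <- rr + h + nodes[q] * sig_r # residual water range at entrance
      e_in <- residual_energy(res_in, water)
      e_in[res_in <= 0] <- 0
      dep <- numeric(nb)
      live <- e_in > 0.5
      if (any(live)) {
        r_au <- csda_range(pmax(e_in[live], 0.6), gold)
        chord <- 2 * h[live]
        stops <- r_au <= chord
        d <- numeric(sum(live))
        d[stops] <- e_in[live][stops]
        if (any(!stops)) {
          e_out <- residual_energy(r_au[!stops] - chord[!stops], gold)
          d[!stops] <- e_in[live][!stops] - e_out
        }
        dep[live] <- d
      }
      tot <- tot + wq[q] * sum(wb * dep)
    }
    tot
  }, numeric(1))
}

#' Gold/water stopping-power ratio at a given energy
#'
#' Pointwise ratio of linear stopping powers S_Au/S_w and its average over a
#' gold traversal of given thickness (the local ratio as the proton slows
#' through the chord). Protons transfer roughly 9.5 times more energy per
#' unit path in gold than in water at 60 MeV.
#'
#' @param energy Entrance proton energy, MeV.
#' @param traversal_mm Gold path length over which to average (0 gives the
#'   pointwise entrance ratio only).
#' @return List with `at_entrance` and `traversal_mean`.
#' @export
#' @examples
#' stopping_ratio(60, 2)
stopping_ratio <- function(energy, traversal_mm = 2) {
  water <- ia_material("water"); gold <- ia_material("gold")
  entr <- stopping_power(energy, gold) / stopping_power(energy, water)
  if (traversal_mm <= 0) return(list(at_entrance = entr, traversal_mean = entr))
  nstep <- 200
  dx <- traversal_mm / nstep
  e <- energy; rs <- numeric(nstep)
  for (i in seq_len(nstep)) {
    s_au <- stopping_power(e, gold)
    rs[i] <- s_au / stopping_power(e, water)
    e <- max(e - s_au * dx, 0.6)
  }
  list(at_entrance = entr, traversal_mean = mean(rs))
}
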