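# Unit conversions used throughout; SI internally, table units at the boundary.
MEV_TO_J <- 1.602176634e-13
PROTON_MASS_MEV <- 938.27208816
ELECTRON_MASS_MEV <- 0.51099895
K_BETHE <- 0.307075 # MeV cm^2 / mol (4 pi N_A r_e^2 m_e c^2)

#' Read a material database
#'
#' Reads a plain-text tab-separated material table (one row per medium) into a
#' data frame of class `material_db`. The packaged database carries the two
#' media of the simulated system -- water (27 degC) and gold -- with their mass
#' density, volumetric thermal expansion coefficient, speed of sound, heat
#' capacity, Grueneisen coefficient, acoustic impedance and thermal
#' diffusivity, plus the atomic data (Z/A and mean excitation energy, ICRU 49)
#' used by the Bethe stopping-power model.
#'
#' @param path Path to a tab-separated table with the packaged column layout.
#'   Defaults to the database shipped with the package.
#' @return A data frame of class `material_db`.
#' @export
#' @examples
#' read_materials()
read_materials <- function(path = system.file("extdata", "materials.tsv",
                                              package = "ionorange")) {
  db <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("name", "rho_g_cm3", "beta_per_K", "v_m_s", "cp_J_K_kg",
              "gamma", "z_Ns_m3", "alpha_th_m2_s")
  missing <- setdiff(needed, names(db))
  if (length(missing))
    stop("material table lacks columns: ", paste(missing, collapse = ", "))
  class(db) <- c("material_db", class(db))
  db
}

#' Look up one material
#'
#' Returns a single-medium record as a `material` object with fields in SI
#' units (`rho` kg/m^3) alongside the tabulated ones, validated for internal
#' consistency: all properties positive, the stored acoustic impedance within
#' 2% of rho*v, and the stored Grueneisen coefficient within 3% of
#' beta*v^2/Cp (the published table rounds Gamma for water to two decimals,
#' which is a 2.8% rounding error; the stored values remain canonical).
#'
#' @param name Medium name, e.g. `"water"` or `"gold"`.
#' @param db A `material_db`; defaults to the packaged database.
#' @return A list of class `material`: `name`, `rho` (kg/m^3),
#'   `rho_g_cm3`, `beta` (1/K), `v` (m/s), `cp` (J/K/kg), `gamma`,
#'   `z_acoustic` (N s/m^3), `alpha_th` (m^2/s), `z_over_a`, `i_ev`.
#' @export
#' @examples
#' ia_material("gold")$gamma
ia_material <- function(name, db = read_materials()) {
  i <- match(name, db$name)
  if (is.na(i)) stop("unknown material: ", name)
  row <- db[i, ]
  m <- list(name = row$name,
            rho = row$rho_g_cm3 * 1000, # kg/m^3
            rho_g_cm3 = row$rho_g_cm3,
            beta = row$beta_per_K,
            v = row$v_m_s,
            cp = row$cp_J_K_kg,
            gamma = row$gamma,
            z_acoustic = row$z_Ns_m3,
            alpha_th = row$alpha_th_m2_s,
            z_over_a = row$z_over_a,
            i_ev = row$i_ev)
  num <- vapply(m[-1], as.numeric, numeric(1))
  if (any(!is.finite(num)) || any(num <= 0))
    stop("material '", name, "' has non-positive or missing properties")
  if (abs(m$z_acoustic - m$rho * m$v) / m$z_acoustic > 0.02)
    stop("material '", name, "': stored impedance inconsistent with rho*v")
  if (abs(m$gamma - gruneisen(m$beta, m$v, m$cp)) / m$gamma > 0.03)
    stop("material '", name, "': stored Grueneisen inconsistent with beta*v^2/Cp")
  class(m) <- "material"
  m
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s: rho=%g g/cm^3, v=%g m/s, Gamma=%g, Z=%g Ns/m^3\n",
              x$name, x$rho_g_cm3, x$v, x$gamma, x$z_acoustic))
  invisible(x)
}

#' Grueneisen coefficient
#'
#' Dimensionless conversion factor from deposited thermal energy density to
#' initial pressure, `Gamma = beta * v^2 / Cp`.
#'
#' @param beta Volumetric thermal expansion coefficient, 1/K (may be zero:
#'   no expansion, no pressure).
#' @param v Speed of sound, m/s.
#' @param cp Heat capacity at constant pressure, J/K/kg.
#' @return Dimensionless Grueneisen coefficient.
#' @export
#' @examples
#' gruneisen(42.6e-6, 3240, 128.8) # gold, ~3.47
#' gruneisen(210e-6, 1500, 4180)   # water, ~0.11
gruneisen <- function(beta, v, cp) {
  if (any(beta < 0) || any(v <= 0) || any(cp <= 0))
    stop("gruneisen: arguments must be positive (beta may be zero)")
  beta * v^2 / cp
}

#' Normal-incidence pressure transmission coefficient
#'
#' Fraction of the pressure amplitude transmitted across a planar interface at
#' normal incidence, `T = 2 Z_r / (Z_s + Z_r)`. For the gold-to-water
#' interface of the marker this is about 5%: the impedance mismatch traps the
#' acoustic energy inside the sphere.
#'
#' @param z_source Acoustic impedance of the source-side medium, N s/m^3.
#' @param z_receiver Acoustic impedance of the receiving medium, N s/m^3.
#' @return Transmission coefficient in (0, 2); 1 for matched media.
#' @seealso [pressure_reflection()] with which it satisfies `T = 1 + R`.
#' @export
#' @examples
#' pressure_transmission(6.3e7, 1.5e6) # ~0.047
pressure_transmission <- function(z_source, z_receiver) {
  if (any(z_source <= 0) || any(z_receiver <= 0))
    stop("pressure_transmission: impedances must be positive")
  2 * z_receiver / (z_source + z_receiver)
}

#' Normal-incidence pressure reflection coefficient
#'
#' Signed reflection coefficient `R = (Z_r - Z_s) / (Z_s + Z_r)`; negative
#' when the wave meets a softer medium (gold to water: R ~ -0.953).
#'
#' @inheritParams pressure_transmission
#' @return Reflection coefficient in (-1, 1).
#' @export
pressure_reflection <- function(z_source, z_receiver) {
  if (any(z_source <= 0) || any(z_receiver <= 0))
    stop("pressure_reflection: impedances must be positive")
  (z_receiver - z_source) / (z_source + z_receiver)
}

#' Stress and thermal confinement times
#'
#' Relaxation times of the heated region: acoustic (stress) relaxation
#' `t_s = d_c / v` and thermal relaxation `t_th = d_c^2 / alpha_th`. A proton
#' pulse is confined when its width is much smaller than both; "much smaller"
#' is operationalised as a factor-of-10 margin.
#'
#' @param d_c Characteristic size of the heated region, m (e.g. the lateral
#'   beam size, ~5 mm).
#' @param v Speed of sound, m/s.
#' @param alpha_th Thermal diffusivity, m^2/s.
#' @param sigma_pulse Optional temporal pulse width sigma_p, s; when supplied
#'   a `confined` flag is returned.
#' @return List with `t_s` (s), `t_th` (s) and, when `sigma_pulse` is given,
#'   logical `confined`.
#' @export
#' @examples
#' confinement_times(5e-3, 1500, 0.15e-6, sigma_pulse = 100e-9)
confinement_times <- function(d_c, v, alpha_th, sigma_pulse = NULL) {
  if (any(d_c <= 0) || any(v <= 0) || any(alpha_th <= 0))
    stop("confinement_times: arguments must be positive")
  out <- list(t_s = d_c / v, t_th = d_c^2 / alpha_th)
  if (!is.null(sigma_pulse)) {
    if (any(sigma_pulse <= 0)) stop("confinement_times: sigma_pulse must be positive")
    out$confined <- (out$t_s / sigma_pulse >= 10) & (out$t_th / sigma_pulse >= 10)
  }
  out
}
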