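# Shared fixtures. Reference proton data for liquid water from the NIST
# PSTAR tables (electronic stopping power, MeV cm^2/g; CSDA range, g/cm^2).
pstar_water <- data.frame(
  energy_mev = c(10, 50, 60, 100),
  stopping = c(45.67, 12.45, NA, 7.289),
  csda_range = c(0.1230, NA, 3.093, 7.718)
)

ref_beam <- function(...) beam_spec(60, 5, 100, ...)
ref_marker <- function(depth = 22) marker_spec(2, depth)

# small homogeneous-water medium grid matching a source field
water_medium <- function(source) {
  w <- ia_material("water")
  structure(list(rho = array(w$rho, dim(source$p0)),
                 v = array(w$v, dim(source$p0))),
            class = "medium_grid")
}

# memoised slow simulations shared across test files
.sim_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}

# reference-geometry hybrid runs (detector line at 20.6 mm lateral)
spot_no <- function() cached("spot_no",
  simulate_spot(ref_beam(), NULL, detector_z = seq(6, 40, by = 2)))
spot_wi <- function() cached("spot_wi",
  simulate_spot(ref_beam(), ref_marker(22), detector_z = seq(6, 40, by = 2),
                beam_trace = spot_no()$beam_trace))
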