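# Plain-text readers/writers for pipeline objects: self-describing headers
# (key: value comment lines) followed by delimited data. Everything is
# re-buildable from code; these formats exist for exchange and inspection.

.write_header <- function(con, kv) {
  for (k in names(kv))
    writeLines(sprintf("# %s: %s", k, paste(kv[[k]], collapse = " ")), con)
}

.read_header <- function(path) {
  lines <- readLines(path, n = 50)
  lines <- lines[startsWith(lines, "# ")]
  kv <- list()
  for (l in lines) {
    m <- regmatches(l, regexec("^# ([^:]+): (.*)$", l))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- m[3]
  }
  kv
}

#' Write / read a dose grid
#'
#' Self-describing text container: header with grid metadata, then the flat
#' per-voxel energy and medium arrays (column-major) as two columns.
#'
#' @param dose A [build_dose_grid()] result.
#' @param path Output file.
#' @export
write_dose_grid <- function(dose, path) {
  con <- file(path, "w")
  on.exit(close(con))
  .write_header(con, list(
    format = "ionorange dose_grid v1",
    dims = dim(dose$energy),
    spacing_mm = dose$spacing,
    origin_mm = c(dose$x[1], dose$y[1], dose$z[1]),
    energy_units = "MeV/voxel/proton",
    beam_energy_mev = dose$beam$energy,
    sigma_mm = dose$beam$sigma_lateral,
    sigma_pulse_ns = dose$beam$sigma_pulse,
    marker_diameter_mm = if (is.null(dose$marker)) NA else dose$marker$diameter,
    marker_depth_mm = if (is.null(dose$marker)) NA else dose$marker$depth))
  utils::write.table(data.frame(energy = as.vector(dose$energy),
                                medium = as.vector(dose$medium)),
                     con, row.names = FALSE, quote = FALSE, sep = "\t")
}

#' @rdname write_dose_grid
#' @param path Input file.
#' @return `read_dose_grid`: a `dose_grid` (beam/marker restored from the
#'   header metadata).
#' @export
read_dose_grid <- function(path) {
  h <- .read_header(path)
  stopifnot(identical(h$format, "ionorange dose_grid v1"))
  dims <- as.integer(strsplit(h$dims, " ")[[1]])
  spacing <- as.numeric(h$spacing_mm)
  org <- as.numeric(strsplit(h$origin_mm, " ")[[1]])
  tab <- utils::read.table(path, header = TRUE, comment.char = "#")
  beam <- beam_spec(as.numeric(h$beam_energy_mev), as.numeric(h$sigma_mm),
                    as.numeric(h$sigma_pulse_ns))
  marker <- if (identical(h$marker_diameter_mm, "NA")) NULL else
    marker_spec(as.numeric(h$marker_diameter_mm), as.numeric(h$marker_depth_mm))
  structure(list(spacing = spacing,
                 x = org[1] + (seq_len(dims[1]) - 1) * spacing,
                 y = org[2] + (seq_len(dims[2]) - 1) * spacing,
                 z = org[3] + (seq_len(dims[3]) - 1) * spacing,
                 energy = array(tab$energy, dims),
                 medium = array(as.integer(tab$medium), dims),
                 beam = beam, marker = marker),
            class = "dose_grid")
}

#' Write / read a pressure trace
#'
#' Delimited text with a header carrying detector coordinates, time step and
#' units, then one time column and one pressure column per detector.
#'
#' @param trace A [pressure_trace()].
#' @param path Output file.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  det <- trace$detectors
  .write_header(con, list(
    format = "ionorange trace v1",
    units = trace$units,
    dt_s = trace$dt,
    n_detectors = ncol(trace$pressure),
    detectors_mm = if (is.null(det)) NA else as.vector(t(det))))
  df <- data.frame(time_s = trace$times, trace$pressure)
  names(df) <- c("time_s", paste0("p", seq_len(ncol(trace$pressure))))
  utils::write.table(df, con, row.names = FALSE, quote = FALSE, sep = "\t")
}

#' @rdname write_trace
#' @return `read_trace`: a `pressure_trace`.
#' @export
read_trace <- function(path) {
  h <- .read_header(path)
  stopifnot(identical(h$format, "ionorange trace v1"))
  tab <- utils::read.table(path, header = TRUE, comment.char = "#")
  det <- if (identical(h$detectors_mm, "NA")) NULL else
    matrix(as.numeric(strsplit(h$detectors_mm, " ")[[1]]), ncol = 3,
           byrow = TRUE, dimnames = list(NULL, c("x", "y", "z")))
  pressure_trace(tab$time_s, as.matrix(tab[, -1, drop = FALSE]),
                 detectors = det, units = h$units)
}

#' Write a spectrum as two-column text
#'
#' @param spec An [trace_spectrum()] result.
#' @param path Output file.
#' @param fmax Optional frequency cut, Hz.
#' @export
write_spectrum <- function(spec, path, fmax = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  .write_header(con, list(format = "ionorange spectrum v1",
                          window = spec$window, taper = spec$taper,
                          pad = spec$pad))
  sel <- if (is.null(fmax)) TRUE else spec$freqs <= fmax
  utils::write.table(data.frame(freq_hz = spec$freqs[sel],
                                amplitude = spec$amplitude[sel]),
                     con, row.names = FALSE, quote = FALSE, sep = "\t")
}

#' Write / read a range calibration as JSON
#'
#' Serialises the calibration constants (C1, C0), validity window, amplitude
#' span and condition metadata as plain JSON.
#'
#' @param cal A [range_calibration()].
#' @param path Output file.
#' @param condition Optional named list of condition metadata (beam energy,
#'   pulse width, geometry ...).
#' @export
write_calibration <- function(cal, path, condition = list()) {
  jsonlite::write_json(list(format = "ionorange calibration v1",
                            c1 = cal$c1, c0 = cal$c0,
                            window_mm = cal$window,
                            amplitude_span = cal$amplitude_span,
                            r_squared = cal$r_squared,
                            relative_slope_pct_mm = cal$relative_slope_pct_mm,
                            condition = condition),
                       path, auto_unbox = TRUE, digits = NA)
}

#' @rdname write_calibration
#' @return `read_calibration`: a `range_calibration` (without the underlying
#'   `lm` object and data).
#' @export
read_calibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(j$format, "ionorange calibration v1"))
  structure(list(c1 = j$c1, c0 = j$c0, window = j$window_mm,
                 amplitude_span = j$amplitude_span, r_squared = j$r_squared,
                 relative_slope_pct_mm = j$relative_slope_pct_mm,
                 fit = NULL, data = NULL, condition = j$condition),
            class = "range_calibration")
}
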