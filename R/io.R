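# Delimited-text readers and writers for the package's file dialects.

#' Read and write extrusion traces
#'
#' Trace files are comma-delimited with header
#' `time_s,pressure_kPa,displacement_mm,extruded_mass_g,temperature_C`;
#' the optional channels may be absent.
#'
#' @param trace An `extrusion_trace`.
#' @param path File path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` an
#'   `extrusion_trace`.
#' @export
write_trace <- function(trace, path) {
  validate_trace(trace)
  df <- data.frame(time_s = trace$time, pressure_kPa = trace$pressure,
                   displacement_mm = trace$displacement)
  if (!is.null(trace$extruded_mass)) df$extruded_mass_g <- trace$extruded_mass
  if (!is.null(trace$temperature_C)) df$temperature_C <- trace$temperature_C
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- read.csv(path)
  need <- c("time_s", "pressure_kPa", "displacement_mm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("trace file %s missing column(s): %s", path,
          paste(miss, collapse = ", "))
  n <- nrow(df)
  tr <- new_extrusion_trace(
    time = df$time_s, pressure = df$pressure_kPa,
    displacement = df$displacement_mm,
    extruded_mass = df$extruded_mass_g %||% rep(NA_real_, n),
    temperature_C = df$temperature_C %||% rep(NA_real_, n),
    internal_pressure = NULL,
    sampling_rate = if (n > 1) 1 / median(diff(df$time_s)) else NA_real_)
  validate_trace(tr)
  tr
}

#' Read and write oscillatory sweeps
#'
#' Sweep files carry header `control,G_prime_Pa,G_double_prime_Pa`.
#'
#' @param sweep Data frame `control`, `G_prime`, `G_double_prime`.
#' @param path File path.
#' @export
write_sweep <- function(sweep, path) {
  df <- data.frame(control = sweep$control, G_prime_Pa = sweep$G_prime,
                   G_double_prime_Pa = sweep$G_double_prime)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sweep
#' @export
read_sweep <- function(path) {
  df <- read.csv(path)
  out <- data.frame(control = df$control, G_prime = df$G_prime_Pa,
                    G_double_prime = df$G_double_prime_Pa)
  validate_sweep(out)
  out
}

#' Read and write creep traces
#'
#' Creep files carry header `time_s,strain`; cycle boundaries travel in a
#' sidecar attribute written into comment-free companion columns
#' `on_start_s,off_start_s` (recycled rows, NA-padded).
#'
#' @param trace A `creep_trace`.
#' @param path File path.
#' @export
write_creep <- function(trace, path) {
  cyc <- attr(trace, "cycles")
  n <- nrow(trace)
  pad <- function(v) c(v, rep(NA, n - length(v)))
  df <- data.frame(time_s = trace$time, strain = trace$strain,
                   on_start_s = pad(cyc$on_start), off_start_s = pad(cyc$off_start))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_creep
#' @export
read_creep <- function(path) {
  df <- read.csv(path)
  cyc <- data.frame(on_start = df$on_start_s[!is.na(df$on_start_s)],
                    off_start = df$off_start_s[!is.na(df$off_start_s)])
  structure(data.frame(time = df$time_s, strain = df$strain),
            class = c("creep_trace", "data.frame"), cycles = cyc)
}

#' Write extrudability profiles as delimited text
#'
#' Columns follow the standard reporting order: yield point, yield time,
#' maximum pressure, pressure at flow cessation, Young modulus, steady
#' shear stress, apparent viscosity, dynamic viscosity.
#'
#' @param profiles Data frame of stacked [extract_profile()] rows (with
#'   any leading label columns).
#' @param path File path.
#' @export
write_profiles <- function(profiles, path) {
  write.csv(profiles, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundled reference extrudability measurements
#'
#' Reference characterization tables for four hydrochlorothiazide
#' semi-solid formulations (F1-F4): yield points at 40 degC measured by a
#' rotational rheometer (Pa) and by the instrumented printhead (kPa), and
#' full extrudability profiles at 25 degC and 10/20/30 mm/s from a
#' texture analyzer and from the instrumented printhead. Used as fixture
#' inputs for instrument-comparison statistics; the raw runs behind them
#' are not available.
#'
#' @param which One of `"yield_points"`, `"profiles_ta"`,
#'   `"profiles_printhead"`.
#' @return A data frame.
#' @export
#' @examples
#' head(reference_data("yield_points"))
reference_data <- function(which = c("yield_points", "profiles_ta",
                                     "profiles_printhead")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("reference_", which, ".csv"),
                      package = "ssepat", mustWork = TRUE)
  read.csv(path)
}
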