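#' Fluid parameters of the semi-solid mass
#'
#' Herschel-Bulkley description of the paste driving the extrusion
#' simulator and recovered (as derived features) by [extract_profile()].
#' The default mass is a yield-dominated shear-thinning gel: the plunger
#' pressure needed to sustain flow is dominated by the yield pressure, with
#' a modest rate-dependent contribution on top, which is the regime where a
#' pressure trace shows a clean ramp/yield/plateau shape.
#'
#' @param yield_pressure Plunger pressure at flow onset, kPa. The
#'   corresponding nozzle wall yield stress is
#'   `yield_pressure * r / (2 L)`.
#' @param consistency_K Herschel-Bulkley consistency, Pa*s^n.
#' @param flow_index_n Dimensionless shear-thinning exponent, in (0, 1.5].
#' @param density Paste density, g/mm^3 (default 1.25 g/cm^3).
#' @return An object of class `fluid_params`.
#' @export
#' @examples
#' fluid_params(yield_pressure = 400, consistency_K = 6, flow_index_n = 0.4)
fluid_params <- function(yield_pressure = 400, consistency_K = 6,
                         flow_index_n = 0.4, density = 0.00125) {
  check_nonneg(yield_pressure, "yield_pressure")
  check_positive(consistency_K, "consistency_K")
  check_positive(flow_index_n, "flow_index_n")
  if (flow_index_n > 1.5) stopf("`flow_index_n` must be <= 1.5")
  check_positive(density, "density")
  structure(list(yield_pressure = yield_pressure, consistency_K = consistency_K,
                 flow_index_n = flow_index_n, density = density),
            class = "fluid_params")
}

#' System (syringe + nozzle + sensor) parameters
#'
#' Geometry and instrument characteristics of the motor-driven printhead:
#' a 20 mL Luer-lock syringe with a 20-gauge (0.61 mm) tapered nozzle. The
#' default syringe inner diameter (19.3 mm) is the value for which the
#' plunger-speed relation reproduces a 0.010 mm/s plunger speed at a
#' 10 mm/s target print speed and 0.61 mm layer height. Compliance lumps
#' the elastic storage of the paste and syringe; its default is set so the
#' pre-yield pressurization ramp at 10 mm/s takes on the order of two
#' minutes, as observed for soft pharmaceutical gels.
#'
#' @param syringe_inner_diameter mm.
#' @param nozzle_inner_diameter mm.
#' @param nozzle_length mm.
#' @param compliance Volumetric compliance of mass + syringe, mm^3/kPa.
#' @param friction_force Plunger-barrel sliding force, N (constant baseline).
#' @param noise_sd Additive Gaussian pressure noise, kPa.
#' @param temperature_C Set temperature label, degrees C.
#' @return An object of class `system_params`.
#' @export
system_params <- function(syringe_inner_diameter = 19.3,
                          nozzle_inner_diameter = 0.61,
                          nozzle_length = 25,
                          compliance = 0.78,
                          friction_force = 8,
                          noise_sd = 5,
                          temperature_C = 25) {
  check_positive(syringe_inner_diameter, "syringe_inner_diameter")
  check_positive(nozzle_inner_diameter, "nozzle_inner_diameter")
  check_positive(nozzle_length, "nozzle_length")
  check_positive(compliance, "compliance")
  check_nonneg(friction_force, "friction_force")
  check_nonneg(noise_sd, "noise_sd")
  structure(list(syringe_inner_diameter = syringe_inner_diameter,
                 nozzle_inner_diameter = nozzle_inner_diameter,
                 nozzle_length = nozzle_length, compliance = compliance,
                 friction_force = friction_force, noise_sd = noise_sd,
                 temperature_C = temperature_C),
            class = "system_params")
}

#' Plunger motion protocol
#'
#' An ordered list of plunger steps, each either a constant-speed travel
#' (`speed`, signed mm/s, over `distance` mm) or a stationary hold
#' (`hold` seconds), sampled at `sampling_rate` Hz.
#'
#' @param steps List of steps; each a list with either `speed` and
#'   `distance`, or `hold`.
#' @param sampling_rate Samples per second, Hz.
#' @return An object of class `plunger_protocol`.
#' @seealso [extrusion_protocol()] for the standard compression/shrinkage
#'   characterization cycle.
#' @export
plunger_protocol <- function(steps, sampling_rate = 5) {
  check_positive(sampling_rate, "sampling_rate")
  if (!is.list(steps) || length(steps) == 0L)
    stopf("`steps` must be a non-empty list")
  for (i in seq_along(steps)) {
    s <- steps[[i]]
    has_move <- !is.null(s$speed) || !is.null(s$distance)
    has_hold <- !is.null(s$hold)
    if (has_move == has_hold)
      stopf("step %d must have exactly one of speed/distance or hold", i)
    if (has_move) {
      if (is.null(s$speed) || is.null(s$distance))
        stopf("step %d needs both `speed` and `distance`", i)
      if (s$speed == 0) stopf("step %d: use `hold` for a stationary step", i)
      check_positive(s$distance, sprintf("steps[[%d]]$distance", i))
    } else {
      check_positive(s$hold, sprintf("steps[[%d]]$hold", i))
    }
  }
  structure(list(steps = steps, sampling_rate = sampling_rate),
            class = "plunger_protocol")
}

#' Standard compression/shrinkage extrudability cycle
#'
#' The four-step characterization protocol used to profile a filled
#' syringe at a given target print speed: (1) compress 5 mm at the plunger
#' speed corresponding to `tps`, (2) hold 60 s, (3) retract 5 mm at ten
#' times the plunger speed, (4) hold 60 s.
#'
#' @param tps Target print speed, mm/s.
#' @param layer_height Layer height, mm.
#' @param syringe_diameter Syringe inner diameter, mm.
#' @param distance Compression travel, mm.
#' @param hold Hold duration after each travel, s.
#' @param sampling_rate Hz.
#' @return A [plunger_protocol()].
#' @export
#' @examples
#' p <- extrusion_protocol(10)
#' p$steps[[1]]$speed  # 0.010 mm/s
extrusion_protocol <- function(tps, layer_height = 0.61, syringe_diameter = 19.3,
                               distance = 5, hold = 60, sampling_rate = 5) {
  pds <- plunger_speed(print_settings(tps, layer_height), syringe_diameter)
  plunger_protocol(list(
    list(speed = pds, distance = distance),
    list(hold = hold),
    list(speed = -10 * pds, distance = distance),
    list(hold = hold)
  ), sampling_rate = sampling_rate)
}

#' Process-upset event specification
#'
#' Describes a transient upset injected into a simulated run: a `clog`
#' (fractional reduction of the nozzle radius, raising pressure) or a
#' `bubble` (fractional increase of the system compliance from entrained
#' air, dropping pressure).
#'
#' @param kind `"clog"` or `"bubble"`.
#' @param onset_time s.
#' @param magnitude Fractional nozzle-radius reduction in (0, 1] for a
#'   clog; fractional compliance increase (> 0) for a bubble.
#' @param duration s.
#' @return An object of class `event_spec`.
#' @export
event_spec <- function(kind = c("clog", "bubble"), onset_time, magnitude,
                       duration) {
  kind <- match.arg(kind)
  check_nonneg(onset_time, "onset_time")
  check_positive(duration, "duration")
  check_positive(magnitude, "magnitude")
  if (kind == "clog" && magnitude > 1)
    stopf("clog `magnitude` must be in (0, 1]")
  structure(list(kind = kind, onset_time = onset_time, magnitude = magnitude,
                 duration = duration), class = "event_spec")
}

#' @export
print.fluid_params <- function(x, ...) {
  cat("Herschel-Bulkley fluid: yield", x$yield_pressure, "kPa, K =",
      x$consistency_K, "Pa*s^n, n =", x$flow_index_n,
      ", density", x$density, "g/mm^3\n")
  invisible(x)
}

#' @export
print.system_params <- function(x, ...) {
  cat(sprintf(
    "Printhead system: syringe D %.3g mm, nozzle %.3g x %.3g mm, compliance %.3g mm^3/kPa,\n  friction %.3g N, noise sd %.3g kPa, %.4g degC\n",
    x$syringe_inner_diameter, x$nozzle_inner_diameter, x$nozzle_length,
    x$compliance, x$friction_force, x$noise_sd, x$temperature_C))
  invisible(x)
}
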