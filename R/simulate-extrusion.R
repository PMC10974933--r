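# Extrusion-trace simulator: the package's stand-in for the instrumented
# printhead. The model is deliberately minimal: a single lumped compliance
# pressurized by the plunger, discharging through the nozzle as a
# Herschel-Bulkley capillary once the yield pressure is exceeded. It
# reproduces the four features of a real trace - friction baseline, elastic
# pressurization ramp, yield event, shear-thinning steady plateau, and
# relaxation after retraction - from known ground-truth parameters.

# per-sample outflow coefficient (see src/sim_core.cpp)
outflow_coefficient <- function(radius, fluid, nozzle_length) {
  n <- fluid$flow_index_n
  pi * radius^3 * n / (3 * n + 1) *
    (1000 * radius / (2 * nozzle_length * fluid$consistency_K))^(1 / n)
}

protocol_speed_vector <- function(protocol) {
  rate <- protocol$sampling_rate
  unlist(lapply(protocol$steps, function(s) {
    if (!is.null(s$hold)) {
      rep(0, max(1L, round(s$hold * rate)))
    } else {
      dur <- s$distance / abs(s$speed)
      rep(s$speed, max(1L, round(dur * rate)))
    }
  }))
}

new_extrusion_trace <- function(time, pressure, displacement, extruded_mass,
                                temperature_C, internal_pressure,
                                sampling_rate, metadata = list()) {
  df <- data.frame(time = time, pressure = pressure,
                   displacement = displacement,
                   extruded_mass = extruded_mass,
                   temperature_C = temperature_C)
  structure(df, class = c("extrusion_trace", "data.frame"),
            internal_pressure = internal_pressure,
            sampling_rate = sampling_rate, metadata = metadata)
}

validate_trace <- function(trace) {
  need <- c("time", "pressure", "displacement")
  miss <- setdiff(need, names(trace))
  if (length(miss))
    stopf("trace is missing channel(s): %s", paste(miss, collapse = ", "))
  if (any(diff(trace$time) <= 0)) stopf("trace time must be strictly increasing")
  if (!is.null(trace$extruded_mass) &&
      any(diff(trace$extruded_mass) < -1e-9))
    stopf("extruded_mass must be non-decreasing")
  invisible(trace)
}

# shared driver for protocol- and timeline-based runs
run_sim_core <- function(speed, dt, fluid, system, events, seed,
                         metadata = list()) {
  n <- length(speed)
  area <- syringe_area(system$syringe_inner_diameter)
  radius <- rep(system$nozzle_inner_diameter / 2, n)
  compliance <- rep(system$compliance, n)
  pscale <- rep(1, n)
  tt <- seq_len(n) * dt
  if (length(events)) {
    for (ev in events) {
      if (!inherits(ev, "event_spec")) stopf("events must be event_spec objects")
      win <- which(tt >= ev$onset_time & tt < ev$onset_time + ev$duration)
      if (!length(win)) next
      if (ev$kind == "clog") {
        radius[win] <- radius[win] * (1 - ev$magnitude)
      } else {
        compliance[win] <- compliance[win] * (1 + ev$magnitude)
        pscale[win[1]] <- 1 / (1 + ev$magnitude)
      }
    }
  }
  if (is.null(fluid)) {
    internal <- numeric(n)
    outflow <- numeric(n)
    mass <- numeric(n)
  } else {
    qc <- outflow_coefficient(radius, fluid, system$nozzle_length)
    res <- sim_core(speed, dt, area, compliance, qc, fluid$yield_pressure,
                    1 / fluid$flow_index_n, pscale, fluid$density)
    internal <- res$pressure
    outflow <- res$outflow
    mass <- res$extruded_mass
  }
  noise <- with_seed(seed, rnorm(n, 0, system$noise_sd))
  measured <- internal + force_to_kPa(system$friction_force, area) + noise
  tr <- new_extrusion_trace(
    time = tt, pressure = measured, displacement = cumsum(speed * dt),
    extruded_mass = mass, temperature_C = rep(system$temperature_C, n),
    internal_pressure = internal, sampling_rate = 1 / dt,
    metadata = c(metadata, list(seed = seed)))
  attr(tr, "outflow") <- outflow
  tr
}

#' Simulate a plunger-driven extrusion pressure trace
#'
#' Integrates the quasi-static compliance model: plunger inflow
#' `speed * A_syringe` charges the lumped compliance; once the internal
#' pressure exceeds the fluid's yield pressure the nozzle discharges as a
#' Herschel-Bulkley capillary (excess wall stress `(P - Py) r / (2L)`,
#' power-law Rabinowitsch flow). Measured pressure adds the constant
#' plunger-friction baseline and seeded Gaussian noise. With
#' `fluid = NULL` the run is an empty-syringe friction baseline.
#'
#' @param fluid A [fluid_params()] object, or `NULL` for a friction-only
#'   baseline run.
#' @param system A [system_params()] object.
#' @param protocol A [plunger_protocol()] (see [extrusion_protocol()]).
#' @param events List of [event_spec()] process upsets.
#' @param seed Integer seed for the pressure noise.
#' @param metadata Optional named list (speed label, formulation label, ...)
#'   stored on the trace.
#' @return An `extrusion_trace`: a data frame with channels `time` (s),
#'   `pressure` (kPa), `displacement` (mm), `extruded_mass` (g),
#'   `temperature_C`, plus attributes `internal_pressure` (the noise- and
#'   friction-free diagnostic channel) and `sampling_rate`.
#' @export
#' @examples
#' tr <- simulate_extrusion_trace(fluid_params(), system_params(),
#'                                extrusion_protocol(10), seed = 1)
#' max(tr$pressure)
simulate_extrusion_trace <- function(fluid = NULL, system = system_params(),
                                     protocol, events = list(), seed = 1,
                                     metadata = list()) {
  if (!is.null(fluid) && !inherits(fluid, "fluid_params"))
    stopf("`fluid` must be a fluid_params object or NULL")
  if (!inherits(system, "system_params"))
    stopf("`system` must be a system_params object")
  if (!inherits(protocol, "plunger_protocol"))
    stopf("`protocol` must be a plunger_protocol object")
  speed <- protocol_speed_vector(protocol)
  run_sim_core(speed, 1 / protocol$sampling_rate, fluid, system, events, seed,
               metadata = c(metadata, list(protocol = protocol)))
}

#' Simulate the pressure trace of a whole batch print
#'
#' Drives the extrusion model with the plunger-speed profile implied by a
#' [motion_timeline()]: during extruding moves the plunger advances at the
#' plunger displacement speed corresponding to the commanded print speed
#' (see [plunger_speed()]); during travel moves it is stationary.
#'
#' @param timeline A [motion_timeline()] of the batch gcode.
#' @param fluid,system,events,seed,metadata As in
#'   [simulate_extrusion_trace()].
#' @param layer_height Layer height used for the plunger-speed conversion;
#'   defaults to the value recorded in the timeline's gcode header.
#' @return An `extrusion_trace` on the timeline's sample grid.
#' @export
simulate_print_run <- function(timeline, fluid = fluid_params(),
                               system = system_params(), events = list(),
                               seed = 1, layer_height = NULL,
                               metadata = list()) {
  if (!inherits(timeline, "motion_timeline"))
    stopf("`timeline` must be a motion_timeline object")
  lh <- layer_height %||% timeline$layer_height
  if (is.null(lh))
    stopf("layer height not recorded in timeline; supply `layer_height`")
  sm <- timeline$samples
  spd <- ifelse(sm$extruding,
                sm$commanded_speed * (lh / system$syringe_inner_diameter)^2,
                0)
  dt <- 1 / timeline$sampling_rate
  run_sim_core(spd, dt, fluid, system, events, seed,
               metadata = c(metadata, list(layer_height = lh)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analytic steady-state pressure of the extrusion model
#'
#' Closed-form steady operating point for a constant plunger speed: the
#' internal pressure at which nozzle outflow balances plunger inflow,
#' `Py + 2L/r * tau_p` with `tau_p = K * gamma_wall^n` the excess
#' (power-law) wall stress. For a Newtonian fluid (`n = 1`,
#' `yield_pressure = 0`) this is the Hagen-Poiseuille pressure drop.
#'
#' @param fluid A [fluid_params()] object.
#' @param system A [system_params()] object.
#' @param plunger_speed mm/s.
#' @return Internal (friction-free) steady pressure, kPa.
#' @export
steady_state_pressure <- function(fluid, system, plunger_speed) {
  check_positive(plunger_speed, "plunger_speed")
  r <- system$nozzle_inner_diameter / 2
  L <- system$nozzle_length
  n <- fluid$flow_index_n
  q_in <- plunger_speed * syringe_area(system$syringe_inner_diameter)
  gamma_wall <- q_in * (3 * n + 1) / (n * pi * r^3)
  tau_excess_Pa <- fluid$consistency_K * gamma_wall^n
  fluid$yield_pressure + 2 * L / r * tau_excess_Pa / 1000
}

#' @export
print.extrusion_trace <- function(x, ...) {
  cat(sprintf(
    "Extrusion trace: %d samples at %.3g Hz, %.1f s, pressure %.1f-%.1f kPa, extruded %.3f g\n",
    nrow(x), attr(x, "sampling_rate"), max(x$time), min(x$pressure),
    max(x$pressure), max(x$extruded_mass)))
  invisible(x)
}

#' @export
plot.extrusion_trace <- function(x, ...) {
  graphics::plot(x$time, x$pressure, type = "l", xlab = "time (s)",
                 ylab = "pressure (kPa)", ...)
  invisible(x)
}
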