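# Extrudability profiling: closed-form print-settings relations and the
# per-run feature vector extracted from a (baseline-corrected) pressure
# trace.

#' Print settings
#'
#' @param tps Target print speed, mm/s.
#' @param layer_height Layer height, mm.
#' @return An object of class `print_settings`.
#' @export
print_settings <- function(tps, layer_height = 0.61) {
  check_positive(tps, "tps")
  check_positive(layer_height, "layer_height")
  structure(list(tps = tps, layer_height = layer_height),
            class = "print_settings")
}

#' Plunger displacement speed from print settings
#'
#' The plunger must displace paste volume at the rate the nozzle deposits
#' it, giving `PDS = TPS * (LH / D)^2`: a 10 mm/s print speed with a
#' 0.61 mm layer height and a 19.3 mm syringe maps to 0.010 mm/s at the
#' plunger.
#'
#' @param settings A [print_settings()] object.
#' @param syringe_diameter Syringe inner diameter D, mm.
#' @return Plunger speed, mm/s.
#' @export
#' @examples
#' plunger_speed(print_settings(10), 19.3)
plunger_speed <- function(settings, syringe_diameter = 19.3) {
  if (!inherits(settings, "print_settings"))
    stopf("`settings` must be a print_settings object")
  check_positive(syringe_diameter, "syringe_diameter")
  settings$tps * (settings$layer_height / syringe_diameter)^2
}

#' Volumetric flow rate from print settings
#'
#' True volumetric flow through the nozzle,
#' `Q = PDS * A_syringe = pi * LH^2 * TPS / 4` (mm^3/s), independent of
#' the syringe diameter. `literal = TRUE` switches to the legacy reading
#' "print speed times syringe radius" (mm^2/s), kept only for
#' compatibility with older spreadsheets.
#'
#' @inheritParams plunger_speed
#' @param literal Use the legacy speed-times-radius reading.
#' @return Flow rate, mm^3/s (or mm^2/s when `literal`).
#' @export
#' @examples
#' flow_rate(print_settings(10))  # 2.9225 mm^3/s
flow_rate <- function(settings, syringe_diameter = 19.3, literal = FALSE) {
  if (!inherits(settings, "print_settings"))
    stopf("`settings` must be a print_settings object")
  check_positive(syringe_diameter, "syringe_diameter")
  if (literal) return(settings$tps * syringe_diameter / 2)
  pi * settings$layer_height^2 * settings$tps / 4
}

#' Apparent wall shear rate in the nozzle
#'
#' Newtonian capillary wall shear rate `4 Q / (pi r^3)`.
#'
#' @param Q Volumetric flow rate, mm^3/s.
#' @param nozzle_radius mm.
#' @return Shear rate, 1/s.
#' @export
shear_rate <- function(Q, nozzle_radius) {
  check_nonneg(Q, "Q")
  check_positive(nozzle_radius, "nozzle_radius")
  4 * Q / (pi * nozzle_radius^3)
}

#' Dynamic viscosity from the steady extrusion force
#'
#' Hagen-Poiseuille balance of the steady plunger force against laminar
#' nozzle flow, `F = 128 Q mu L A / (pi D^4)`, solved for
#' `mu = F pi D^4 / (128 Q L A)` and converted to Pa*s (mm/N/s internal
#' units give MPa*s).
#'
#' @param steady_force Steady-flow plunger force, N.
#' @param Q Volumetric flow rate, mm^3/s.
#' @param nozzle_length L, mm.
#' @param nozzle_diameter D, mm.
#' @param syringe_area A, mm^2.
#' @return Dynamic viscosity, Pa*s.
#' @export
#' @examples
#' dynamic_viscosity(1, 2.9225, 25, 0.61, 292.6)  # ~0.159 Pa*s
dynamic_viscosity <- function(steady_force, Q, nozzle_length, nozzle_diameter,
                              syringe_area) {
  check_nonneg(steady_force, "steady_force")
  check_positive(Q, "Q")
  check_positive(nozzle_length, "nozzle_length")
  check_positive(nozzle_diameter, "nozzle_diameter")
  check_positive(syringe_area, "syringe_area")
  mu_MPa_s <- steady_force * pi * nozzle_diameter^4 /
    (128 * Q * nozzle_length * syringe_area)
  mu_MPa_s * 1e6
}

#' Subtract the plunger-friction baseline from a trace
#'
#' The friction of the plunger against the barrel is captured by an
#' empty-syringe run under the same protocol; its pressure channel,
#' time-interpolated onto the trace grid, is subtracted (clipped at zero).
#' Other channels are unchanged.
#'
#' @param trace,baseline `extrusion_trace` objects recorded under the same
#'   protocol (durations within `tol`).
#' @param tol Relative duration mismatch tolerated.
#' @return The corrected `extrusion_trace`.
#' @export
baseline_correct <- function(trace, baseline, tol = 0.05) {
  validate_trace(trace)
  validate_trace(baseline)
  d1 <- max(trace$time); d2 <- max(baseline$time)
  if (abs(d1 - d2) > tol * max(d1, d2))
    stopf("protocol mismatch: trace lasts %.1f s but baseline %.1f s", d1, d2)
  base_p <- stats::approx(baseline$time, baseline$pressure, trace$time,
                          rule = 2)$y
  out <- trace
  out$pressure <- pmax(0, trace$pressure - base_p)
  out
}

#' Profile-extraction tolerances
#'
#' @param rel_tol Relative departure from the pre-yield linear fit that
#'   marks the yield point.
#' @param r2_min Minimum R^2 of the expanding-window pre-yield fit.
#' @param steady_frac Final fraction of the compression step averaged for
#'   the steady state.
#' @param cessation_window Final seconds of the post-compression hold
#'   averaged for the flow-cessation pressure.
#' @param min_window Minimum samples in the linear fit.
#' @param sustain Consecutive samples the departure must persist.
#' @param stress_convention `"nozzle-area"` (steady force over the nozzle
#'   cross-section) or `"capillary-wall"` (`tau = dP * r / (2L)`).
#' @return A list of class `profile_config`.
#' @export
profile_config <- function(rel_tol = 0.05, r2_min = 0.99, steady_frac = 0.2,
                           cessation_window = 5, min_window = 10, sustain = 3,
                           stress_convention = c("nozzle-area",
                                                 "capillary-wall")) {
  structure(list(rel_tol = rel_tol, r2_min = r2_min, steady_frac = steady_frac,
                 cessation_window = cessation_window, min_window = min_window,
                 sustain = sustain,
                 stress_convention = match.arg(stress_convention)),
            class = "profile_config")
}

# largest expanding-window end index with R^2 >= r2_min for y ~ x,
# computed with cumulative sums; returns the fit over that window
expanding_linear_fit <- function(x, y, r2_min, min_window) {
  n <- length(x)
  k <- seq_len(n)
  sx <- cumsum(x); sy <- cumsum(y)
  sxx <- cumsum(x^2); syy <- cumsum(y^2); sxy <- cumsum(x * y)
  ssxx <- sxx - sx^2 / k
  ssyy <- syy - sy^2 / k
  ssxy <- sxy - sx * sy / k
  r2 <- ifelse(ssxx > 0 & ssyy > 0, ssxy^2 / (ssxx * ssyy), NA_real_)
  ok <- which(k >= min_window & !is.na(r2) & r2 >= r2_min)
  if (!length(ok)) return(NULL)
  m <- max(ok)
  slope <- ssxy[m] / ssxx[m]
  intercept <- sy[m] / m - slope * sx[m] / m
  list(end = m, slope = slope, intercept = intercept, r2 = r2[m])
}

#' Extract the extrudability profile of a trace
#'
#' Implements the standard reading of a compression/hold extrudability
#' run. Phases are identified from the commanded displacement channel
#' (compression = first monotone advance; hold = the stationary stretch
#' that follows). The pre-yield elastic region is the longest
#' expanding-window linear fit of pressure against displacement with
#' `R^2 >= r2_min`; the yield point is the pressure where the curve first
#' departs from that fit by more than `rel_tol` (relative, sustained for
#' `sustain` samples), lightly median-smoothed against sensor noise. The
#' Young modulus is the slope of the linear region (kPa/mm). The steady
#' state is averaged over the final `steady_frac` of the compression step,
#' and the flow-cessation pressure over the final `cessation_window`
#' seconds of the hold. Shear stress, shear rate, apparent viscosity
#' (stress / rate, kPa*s) and dynamic viscosity (Hagen-Poiseuille, Pa*s)
#' are derived from the steady force and the print settings.
#'
#' @param trace A (baseline-corrected) `extrusion_trace`.
#' @param system A [system_params()] object.
#' @param settings A [print_settings()] object.
#' @param config A [profile_config()].
#' @return An `extrudability_profile`: one-row data frame with columns
#'   `yield_point` (kPa), `yield_time` (s), `max_pressure` (kPa),
#'   `pressure_flow_cessation` (kPa), `young_modulus` (kPa/mm),
#'   `shear_stress_steady` (kPa), `shear_rate` (1/s),
#'   `apparent_viscosity` (kPa*s), `dynamic_viscosity` (Pa*s),
#'   `plunger_speed` (mm/s), `flow_rate` (mm^3/s).
#' @export
extract_profile <- function(trace, system = system_params(), settings,
                            config = profile_config()) {
  validate_trace(trace)
  if (!inherits(settings, "print_settings"))
    stopf("`settings` must be a print_settings object")
  dd <- diff(trace$displacement)
  adv <- dd > 1e-12
  if (!any(adv)) stopf("trace has no compression step")
  comp_start <- which(adv)[1]
  comp_end <- comp_start
  while (comp_end < length(dd) && adv[comp_end + 1]) comp_end <- comp_end + 1
  comp_end <- comp_end + 1L  # last sample of the compression step
  hold_end <- comp_end
  while (hold_end < nrow(trace) &&
         abs(trace$displacement[hold_end + 1] - trace$displacement[comp_end]) < 1e-9)
    hold_end <- hold_end + 1L
  comp <- seq(comp_start, comp_end)
  if (length(comp) < config$min_window + config$sustain)
    stopf("trace shorter than protocol: compression step has %d samples",
          length(comp))

  x <- trace$displacement[comp]
  y <- trace$pressure[comp]
  fit <- expanding_linear_fit(x, y, config$r2_min, config$min_window)
  if (is.null(fit))
    stopf("yield undetected: no linear pre-yield region with R^2 >= %.3g",
          config$r2_min)
  pred <- fit$intercept + fit$slope * x
  y_s <- if (length(y) >= 5) stats::runmed(y, 5) else y
  dev <- (pred - y_s) > config$rel_tol * pmax(pred, .Machine$double.eps)
  dev[seq_len(fit$end)] <- FALSE
  yi <- NA_integer_
  run <- 0L
  for (i in seq_along(dev)) {
    run <- if (dev[i]) run + 1L else 0L
    if (run >= config$sustain) { yi <- i - config$sustain + 1L; break }
  }
  if (is.na(yi))
    stopf("yield undetected: pressure never departs from the linear fit by %.3g",
          config$rel_tol)
  # local median around the departure sample: the yield estimate should
  # not ride on one noisy sensor reading
  nb <- seq(max(1L, yi - 5L), min(length(y), yi + 5L))
  yield_point <- median(y[nb])
  yield_time <- trace$time[comp[yi]]
  max_pressure <- max(y)

  # Young modulus: refit strictly pre-yield (smoothed pressure below
  # (1 - rel_tol) * yield), so the kink region does not bias the slope
  pre <- which(y_s <= (1 - config$rel_tol) * yield_point)
  pre <- pre[pre < yi]
  if (length(pre) >= config$min_window) {
    refit <- lm(y[pre] ~ x[pre])
    slope <- unname(coef(refit)[2])
  } else slope <- fit$slope

  n_steady <- max(2L, ceiling(config$steady_frac * length(comp)))
  steady_idx <- comp[(length(comp) - n_steady + 1):length(comp)]
  steady_pressure <- mean(trace$pressure[steady_idx])

  area <- syringe_area(system$syringe_inner_diameter)
  steady_force <- kPa_to_force(steady_pressure, area)

  hold <- seq(comp_end + 1L, hold_end)
  cess <- NA_real_
  if (length(hold) > 1) {
    t_end <- trace$time[hold_end]
    ci <- hold[trace$time[hold] >= t_end - config$cessation_window]
    cess <- mean(trace$pressure[ci])
  }

  r <- system$nozzle_inner_diameter / 2
  Q <- flow_rate(settings, system$syringe_inner_diameter)
  gdot <- shear_rate(Q, r)
  stress <- switch(config$stress_convention,
    "nozzle-area" = force_to_kPa(steady_force, pi * r^2),
    "capillary-wall" = steady_pressure * r / (2 * system$nozzle_length))
  app_visc <- if (gdot > 0) stress / gdot else NA_real_
  dyn_visc <- dynamic_viscosity(steady_force, Q, system$nozzle_length,
                                system$nozzle_inner_diameter, area)

  structure(data.frame(
    yield_point = yield_point, yield_time = yield_time,
    max_pressure = max_pressure, pressure_flow_cessation = cess,
    young_modulus = slope, shear_stress_steady = stress,
    shear_rate = gdot, apparent_viscosity = app_visc,
    dynamic_viscosity = dyn_visc,
    plunger_speed = plunger_speed(settings, system$syringe_inner_diameter),
    flow_rate = Q),
    class = c("extrudability_profile", "data.frame"),
    steady_pressure = steady_pressure,
    stress_convention = config$stress_convention)
}

#' @export
print.extrudability_profile <- function(x, ...) {
  cat("Extrudability profile\n")
  cat(sprintf("  yield point      %8.1f kPa at %.1f s\n", x$yield_point,
              x$yield_time))
  cat(sprintf("  max pressure     %8.1f kPa\n", x$max_pressure))
  cat(sprintf("  flow cessation   %8.1f kPa\n", x$pressure_flow_cessation))
  cat(sprintf("  Young modulus    %8.1f kPa/mm\n", x$young_modulus))
  cat(sprintf("  steady stress    %8.1f kPa (%s)\n", x$shear_stress_steady,
              attr(x, "stress_convention")))
  cat(sprintf("  shear rate       %8.1f 1/s\n", x$shear_rate))
  cat(sprintf("  apparent visc.   %8.3f kPa*s\n", x$apparent_viscosity))
  cat(sprintf("  dynamic visc.    %8.3f Pa*s\n", x$dynamic_viscosity))
  invisible(x)
}
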