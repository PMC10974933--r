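# Oscillatory-sweep and creep-recovery summaries: gel classification,
# yield/flow stress, per-cycle recovery.

validate_sweep <- function(sweep, min_points = 5L) {
  need <- c("control", "G_prime", "G_double_prime")
  miss <- setdiff(need, names(sweep))
  if (length(miss))
    stopf("sweep is missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(sweep) < min_points)
    stopf("sweep needs at least %d points, got %d", min_points, nrow(sweep))
  if (any(diff(sweep$control) <= 0))
    stopf("sweep control variable must be strictly increasing")
  if (any(sweep$G_prime <= 0) || any(sweep$G_double_prime <= 0))
    stopf("moduli must be positive")
  invisible(sweep)
}

#' Classify gel-like behaviour from a frequency sweep
#'
#' A solid gel shows `G' > G''` throughout the sweep with the two moduli
#' parallel on log-log axes (nearly equal power-law slopes).
#'
#' @param freq_sweep Data frame `control` (Hz, ascending), `G_prime`,
#'   `G_double_prime` (Pa).
#' @param parallel_tol Maximum allowed difference of the log-log slopes.
#' @return List `is_gel`, `slope_G_prime`, `slope_G_double_prime`,
#'   `elastic_dominant` (G' > G'' everywhere).
#' @export
classify_gel <- function(freq_sweep, parallel_tol = 0.1) {
  validate_sweep(freq_sweep)
  lw <- log10(freq_sweep$control)
  s1 <- unname(coef(lm(log10(freq_sweep$G_prime) ~ lw))[2])
  s2 <- unname(coef(lm(log10(freq_sweep$G_double_prime) ~ lw))[2])
  elastic <- all(freq_sweep$G_prime > freq_sweep$G_double_prime)
  list(is_gel = elastic && abs(s1 - s2) <= parallel_tol,
       slope_G_prime = s1, slope_G_double_prime = s2,
       elastic_dominant = elastic)
}

#' Yield and flow stress from an amplitude sweep
#'
#' The yield stress is the lowest applied stress at which `G'` leaves its
#' low-amplitude plateau (deviates from the plateau median by more than
#' `plateau_tol`, relative). The flow stress is the solid-to-liquid
#' transition: the stress at which `G'` and `G''` cross, located by
#' log-linear interpolation between the bracketing points
#' (`midpoint = "interpolate"`) or as the geometric mean of the bracketing
#' stresses (`midpoint = "bracket-mean"`).
#'
#' @param amp_sweep Data frame `control` (Pa, ascending), `G_prime`,
#'   `G_double_prime` (Pa).
#' @param plateau_tol Relative tolerance defining the plateau.
#' @param k_plateau Number of initial points whose median anchors the
#'   plateau; they must all lie within `plateau_tol` of it.
#' @param midpoint Crossover convention.
#' @return List `yield_stress` (Pa or NA), `flow_stress` (Pa or NA),
#'   `plateau_modulus`, and logical flags `yield_defined`, `flow_defined`.
#' @export
amplitude_summary <- function(amp_sweep, plateau_tol = 0.05, k_plateau = 5L,
                              midpoint = c("interpolate", "bracket-mean")) {
  validate_sweep(amp_sweep)
  midpoint <- match.arg(midpoint)
  gp <- amp_sweep$G_prime
  tau <- amp_sweep$control
  k <- min(k_plateau, nrow(amp_sweep))
  plateau <- median(gp[seq_len(k)])
  if (any(abs(gp[seq_len(k)] - plateau) > plateau_tol * plateau))
    stopf("no plateau: first %d points spread more than %.3g of their median",
          k, plateau_tol)
  dev <- abs(gp - plateau) > plateau_tol * plateau
  yi <- which(dev)[1]
  yield_stress <- if (is.na(yi)) NA_real_ else tau[yi]

  diffm <- gp - amp_sweep$G_double_prime
  sgn <- sign(diffm)
  cross <- which(sgn[-1] != sgn[-length(sgn)] & sgn[-1] != 0)[1]
  if (is.na(cross)) {
    flow_stress <- NA_real_
  } else if (midpoint == "interpolate") {
    # root of G' - G'' in log stress, linear in the log of the ratio
    lr <- log(gp / amp_sweep$G_double_prime)
    lt <- log(tau)
    w <- lr[cross] / (lr[cross] - lr[cross + 1])
    flow_stress <- exp(lt[cross] + w * (lt[cross + 1] - lt[cross]))
  } else {
    flow_stress <- sqrt(tau[cross] * tau[cross + 1])
  }
  list(yield_stress = yield_stress, flow_stress = flow_stress,
       plateau_modulus = plateau,
       yield_defined = !is.na(yield_stress), flow_defined = !is.na(flow_stress))
}

#' Per-cycle creep-recovery summary
#'
#' For each loading/recovery cycle: the strain at cycle start, the peak
#' strain at the end of loading, the residual strain at the end of
#' recovery, and the recovered percentage
#' `100 * (peak - residual) / (peak - start)`.
#'
#' @param trace A `creep_trace` (data frame `time`, `strain` with a
#'   `cycles` attribute), or a plain data frame plus `cycles`.
#' @param cycles Optional data frame `on_start`, `off_start` (s) if not
#'   attached to `trace`.
#' @return Data frame `cycle`, `start_strain`, `peak_strain`,
#'   `residual_strain`, `recovered_pct`, `degenerate`.
#' @export
creep_summary <- function(trace, cycles = attr(trace, "cycles")) {
  if (is.null(cycles)) stopf("no cycle boundaries supplied")
  if (!all(c("time", "strain") %in% names(trace)))
    stopf("creep trace needs `time` and `strain` columns")
  if (any(cycles$off_start <= cycles$on_start))
    stopf("cycle boundaries must be ordered")
  n <- nrow(cycles)
  at <- function(t) stats::approx(trace$time, trace$strain, t, rule = 2)$y
  next_on <- c(cycles$on_start[-1], max(trace$time))
  out <- data.frame(cycle = seq_len(n),
                    start_strain = at(cycles$on_start),
                    peak_strain = at(cycles$off_start),
                    residual_strain = at(next_on))
  out$degenerate <- out$peak_strain <= out$start_strain
  out$recovered_pct <- ifelse(out$degenerate, NA_real_,
    100 * (out$peak_strain - out$residual_strain) /
      (out$peak_strain - out$start_strain))
  out[, c("cycle", "start_strain", "peak_strain", "residual_strain",
          "recovered_pct", "degenerate")]
}
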