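# Shared fixtures: small, fast study configurations used across tests.

default_fluid <- function(...) fluid_params(...)
default_system <- function(...) system_params(...)

# low-compliance Newtonian configuration whose relaxation time is far
# shorter than the run, so the late-time pressure is the steady state
newtonian_fluid <- function(mu_Pa_s = 30) {
  fluid_params(yield_pressure = 1e-9, consistency_K = mu_Pa_s,
               flow_index_n = 1)
}
stiff_system <- function(...) system_params(compliance = 0.1, ...)

# small batch (fast): 6 printed + 2 priming printlets
small_batch <- function(seed = 1) {
  d <- design_batch(n = 6, speeds = c(10, 20, 30), counts = c(2, 2, 2),
                    priming = list(speed = 5, count = 2))
  r <- randomize_speeds(d$gcode, speeds = c(10, 20, 30), counts = c(2, 2, 2),
                        seed = seed)
  tl <- motion_timeline(r$gcode, sampling_rate = 2)
  list(design = d, randomized = r, timeline = tl)
}

# one full-size batch + timeline, built once per test run
full_batch_env <- new.env()
full_batch <- function(seed = 42) {
  key <- paste0("b", seed)
  if (is.null(full_batch_env[[key]])) {
    d <- design_batch()
    r <- randomize_speeds(d$gcode, seed = seed)
    full_batch_env[[key]] <- list(design = d, randomized = r,
                                  timeline = motion_timeline(r$gcode, 2))
  }
  full_batch_env[[key]]
}

# idealized piecewise trace: linear ramp of slope k (kPa/mm) to P_star,
# then an exact plateau, with a stationary hold appended
ideal_ramp_trace <- function(k = 375, p_star = 400, speed = 0.01,
                             rate = 5, plateau_s = 100, hold_s = 30) {
  dt <- 1 / rate
  t_ramp <- p_star / (k * speed)
  n_ramp <- ceiling(t_ramp * rate)
  n_plat <- plateau_s * rate
  n_hold <- hold_s * rate
  tt <- seq_len(n_ramp + n_plat + n_hold) * dt
  disp <- c(seq_len(n_ramp + n_plat) * speed * dt,
            rep((n_ramp + n_plat) * speed * dt, n_hold))
  pres <- pmin(k * disp, p_star)
  ssepat:::new_extrusion_trace(tt, pres, disp, rep(0, length(tt)),
                               rep(25, length(tt)), pres, rate)
}
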