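# Rheometer-series generator: gel-like oscillatory sweeps and Burgers
# creep-recovery cycles with known ground truth.

#' Gel parameters for the oscillatory-sweep generator
#'
#' @param plateau_modulus G' at 1 Hz / in the amplitude plateau, Pa.
#' @param freq_exponent Common log-log slope of G' and G'' in the frequency
#'   sweep (near 0 for a solid gel).
#' @param loss_ratio G''/G' (< 1 for a gel).
#' @param char_stress Characteristic stress of the amplitude-sweep decay, Pa.
#' @param decay_exponent Power of the amplitude decay of G'.
#' @param noise_cv Multiplicative (lognormal) noise coefficient of variation.
#' @return An object of class `gel_params`.
#' @export
gel_params <- function(plateau_modulus = 2e4, freq_exponent = 0.05,
                       loss_ratio = 0.3, char_stress = 1000,
                       decay_exponent = 4, noise_cv = 0.02) {
  check_positive(plateau_modulus, "plateau_modulus")
  check_nonneg(freq_exponent, "freq_exponent")
  check_positive(loss_ratio, "loss_ratio")
  check_positive(char_stress, "char_stress")
  check_positive(decay_exponent, "decay_exponent")
  check_nonneg(noise_cv, "noise_cv")
  structure(list(plateau_modulus = plateau_modulus,
                 freq_exponent = freq_exponent, loss_ratio = loss_ratio,
                 char_stress = char_stress, decay_exponent = decay_exponent,
                 noise_cv = noise_cv), class = "gel_params")
}

#' Burgers (Maxwell + Kelvin-Voigt) creep parameters
#'
#' Creep compliance `J(t) = 1/E1 + t/eta1 + (1 - exp(-t E2/eta2))/E2`.
#' `eta1 = Inf` gives a fully recovering (visco)elastic solid.
#'
#' @param E1 Instantaneous (Maxwell spring) modulus, Pa.
#' @param eta1 Steady-flow (Maxwell dashpot) viscosity, Pa*s; `Inf` for no
#'   permanent flow.
#' @param E2 Delayed (Kelvin-Voigt) modulus, Pa.
#' @param eta2 Kelvin-Voigt viscosity, Pa*s.
#' @param noise_sd Additive strain noise.
#' @return An object of class `burgers_params`.
#' @export
burgers_params <- function(E1 = 2e4, eta1 = 1e6, E2 = 1e4, eta2 = 5e4,
                           noise_sd = 1e-4) {
  check_positive(E1, "E1")
  if (!(is.numeric(eta1) && length(eta1) == 1L && eta1 > 0))
    stopf("`eta1` must be positive (possibly Inf)")
  check_positive(E2, "E2")
  check_positive(eta2, "eta2")
  check_nonneg(noise_sd, "noise_sd")
  structure(list(E1 = E1, eta1 = eta1, E2 = E2, eta2 = eta2,
                 noise_sd = noise_sd), class = "burgers_params")
}

burgers_compliance <- function(t, p) {
  ifelse(t <= 0, 0,
         1 / p$E1 + t / p$eta1 + (1 - exp(-t * p$E2 / p$eta2)) / p$E2)
}

#' Simulate rheometer series: frequency sweep, amplitude sweep, creep
#'
#' Frequency sweep: `G' = G0 * omega^a`, `G'' = ratio * G'` (parallel on
#' log axes). Amplitude sweep at fixed frequency: `G'` holds a plateau and
#' decays past the characteristic stress,
#' `G' = G0 / (1 + (tau/tau_c)^p)`, while `G''` decays with half the
#' exponent so the curves cross above `tau_c`. Creep: Burgers strain under
#' stepped stress (Boltzmann superposition), `n_cycles` of
#' `on_time` s loading / `off_time` s recovery at `stress` Pa.
#'
#' @param gel A [gel_params()] object.
#' @param creep A [burgers_params()] object.
#' @param freq_range Frequency sweep range, Hz.
#' @param n_freq Points per sweep.
#' @param amp_range Amplitude sweep shear-stress range, Pa.
#' @param n_amp Points per sweep.
#' @param stress Creep stress, Pa.
#' @param on_time,off_time,n_cycles Creep cycle timing, s.
#' @param creep_rate Creep sampling rate, Hz.
#' @param seed Integer seed.
#' @return List with `frequency_sweep` and `amplitude_sweep` (data frames
#'   `control`, `G_prime`, `G_double_prime`) and `creep` (a `creep_trace`:
#'   data frame `time`, `strain` with attributes `cycles` and
#'   `applied_stress`).
#' @export
simulate_rheometer <- function(gel = gel_params(), creep = burgers_params(),
                               freq_range = c(0.01, 100), n_freq = 30,
                               amp_range = c(0.2387, 10000), n_amp = 40,
                               stress = 500, on_time = 60, off_time = 60,
                               n_cycles = 3, creep_rate = 5, seed = 1) {
  if (!inherits(gel, "gel_params")) stopf("`gel` must be a gel_params object")
  if (!inherits(creep, "burgers_params"))
    stopf("`creep` must be a burgers_params object")
  with_seed(seed, {
    omega <- exp(seq(log(freq_range[1]), log(freq_range[2]), length.out = n_freq))
    gp <- gel$plateau_modulus * omega^gel$freq_exponent
    freq_sweep <- data.frame(
      control = omega,
      G_prime = gp * exp(rnorm(n_freq, 0, gel$noise_cv)),
      G_double_prime = gel$loss_ratio * gp * exp(rnorm(n_freq, 0, gel$noise_cv)))

    tau <- exp(seq(log(amp_range[1]), log(amp_range[2]), length.out = n_amp))
    x <- tau / gel$char_stress
    gp_amp <- gel$plateau_modulus / (1 + x^gel$decay_exponent)
    gpp_amp <- gel$loss_ratio * gel$plateau_modulus /
      (1 + x^(gel$decay_exponent / 2))
    amp_sweep <- data.frame(
      control = tau,
      G_prime = gp_amp * exp(rnorm(n_amp, 0, gel$noise_cv)),
      G_double_prime = gpp_amp * exp(rnorm(n_amp, 0, gel$noise_cv)))

    total <- n_cycles * (on_time + off_time)
    tt <- seq(0, total, by = 1 / creep_rate)
    strain <- numeric(length(tt))
    cyc <- data.frame(on_start = (seq_len(n_cycles) - 1) * (on_time + off_time),
                      off_start = (seq_len(n_cycles) - 1) * (on_time + off_time) + on_time)
    for (k in seq_len(n_cycles)) {
      strain <- strain + stress * burgers_compliance(tt - cyc$on_start[k], creep) -
        stress * burgers_compliance(tt - cyc$off_start[k], creep)
    }
    strain <- strain + rnorm(length(tt), 0, creep$noise_sd)
    creep_trace <- structure(
      data.frame(time = tt, strain = strain),
      class = c("creep_trace", "data.frame"),
      cycles = cyc, applied_stress = stress)

    list(frequency_sweep = freq_sweep, amplitude_sweep = amp_sweep,
         creep = creep_trace)
  })
}
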