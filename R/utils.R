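# internal helpers shared across modules

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stopf("`%s` must be a single positive finite number", name)
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stopf("`%s` must be a single non-negative finite number", name)
  invisible(x)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stopf("`seed` must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Trapezoidal integral of y over t.
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum((t[-1] - t[-n]) * (y[-1] + y[-n]) / 2)
}

# Trapezoidal integral split by a per-sample group label: the interval
# [t_i, t_{i+1}] is attributed to the group of sample i, so group integrals
# sum exactly to the whole-trace integral.
trapz_by <- function(t, y, group) {
  n <- length(t)
  if (n < 2L) return(numeric(0))
  contrib <- (t[-1] - t[-n]) * (y[-1] + y[-n]) / 2
  g <- group[-n]
  vapply(split(contrib, g), sum, numeric(1))
}

syringe_area <- function(diameter) pi * diameter^2 / 4

# kPa exerted on the syringe cross-section by a force in N (N/mm^2 = MPa).
force_to_kPa <- function(force_N, area_mm2) 1000 * force_N / area_mm2
kPa_to_force <- function(p_kPa, area_mm2) p_kPa * area_mm2 / 1000
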