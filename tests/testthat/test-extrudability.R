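# Closed-form print-settings relations and profile extraction.

test_that("plunger speed follows TPS * (LH/D)^2", {
  expect_equal(round(plunger_speed(print_settings(10, 0.61), 19.3), 3), 0.010)
  expect_equal(round(plunger_speed(print_settings(20, 0.61), 19.3), 3), 0.020)
  expect_equal(round(plunger_speed(print_settings(30, 0.61), 19.3), 3), 0.030)
  expect_equal(plunger_speed(print_settings(7, 19.3), 19.3), 7)  # LH = D
  expect_error(plunger_speed(print_settings(10), -1), "syringe_diameter")
})

test_that("flow rate is pi*LH^2*TPS/4, linear in TPS, with the legacy literal reading available", {
  expect_equal(flow_rate(print_settings(10, 0.61)), pi * 0.61^2 * 10 / 4)
  expect_equal(flow_rate(print_settings(10, 0.61)), 2.9225, tolerance = 1e-4)
  expect_equal(flow_rate(print_settings(20, 0.61)),
               2 * flow_rate(print_settings(10, 0.61)))
  expect_equal(flow_rate(print_settings(10, 1e-6)), pi * 1e-12 * 10 / 4)
  expect_equal(flow_rate(print_settings(10), 19.3, literal = TRUE),
               10 * 19.3 / 2)
})

test_that("shear rate is 4Q/(pi r^3) with cubic radius scaling", {
  expect_equal(shear_rate(2.9225, 0.305), 4 * 2.9225 / (pi * 0.305^3))
  expect_equal(shear_rate(2.9225, 0.305), 131.2, tolerance = 1e-3)
  expect_equal(shear_rate(0, 0.305), 0)
  expect_equal(shear_rate(5, 0.6), shear_rate(5, 0.3) / 8)
  expect_error(shear_rate(1, 0), "nozzle_radius")
})

test_that("dynamic viscosity inverts the Poiseuille force balance", {
  expect_equal(dynamic_viscosity(1, 2.9225, 25, 0.61, 292.6), 0.159,
               tolerance = 2e-3)
  expect_equal(dynamic_viscosity(0, 2.9225, 25, 0.61, 292.6), 0)
  expect_equal(dynamic_viscosity(1, 2 * 2.9225, 25, 0.61, 292.6),
               dynamic_viscosity(1, 2.9225, 25, 0.61, 292.6) / 2)
})

test_that("baseline correction: self-correction nulls the trace, zero baseline is identity, protocol mismatch errors", {
  sys <- system_params(noise_sd = 1)
  tr <- simulate_extrusion_trace(fluid_params(), sys, extrusion_protocol(20),
                                 seed = 1)
  self <- baseline_correct(tr, tr)
  expect_true(all(self$pressure == 0))
  zero <- tr
  zero$pressure <- rep(0, nrow(tr))
  expect_equal(baseline_correct(tr, zero)$pressure, tr$pressure)
  short <- tr[tr$time < max(tr$time) / 2, ]
  expect_error(baseline_correct(tr, short), "mismatch")
})

test_that("paired friction-only correction recovers the internal steady pressure within 2%", {
  sys <- system_params()
  prot <- extrusion_protocol(10)
  tr <- simulate_extrusion_trace(fluid_params(), sys, prot, seed = 2)
  bl <- simulate_extrusion_trace(NULL, sys, prot, seed = 3)
  cor_tr <- baseline_correct(tr, bl)
  ip <- attr(tr, "internal_pressure")
  comp_n <- round(500 * 5)
  steady_idx <- (comp_n - 200):comp_n
  expect_equal(mean(cor_tr$pressure[steady_idx]), mean(ip[steady_idx]),
               tolerance = 0.02)
})

test_that("ideal ramp-plateau trace yields the plateau pressure and the ramp slope", {
  k <- 375; p_star <- 400
  tr <- ideal_ramp_trace(k = k, p_star = p_star)
  prof <- extract_profile(tr, system_params(), print_settings(10))
  expect_equal(prof$yield_point, p_star, tolerance = 0.05)
  expect_equal(prof$young_modulus, k, tolerance = 0.02)
  expect_equal(prof$max_pressure, p_star)
})

test_that("max pressure of a monotone compression is its final sample", {
  # pressure keeps rising after the yield kink (slope halves), so the
  # channel maximum is the last compression sample
  rate <- 5
  n <- 600
  tt <- seq_len(n) / rate
  disp <- c(seq_len(n - 100) * 0.01 / rate, rep((n - 100) * 0.01 / rate, 100))
  ramp <- pmin(seq_len(n - 100), 250) * 2 +
    pmax(seq_len(n - 100) - 250, 0) * 0.5
  pres <- c(ramp, rep(ramp[n - 100], 100))
  tr <- ssepat:::new_extrusion_trace(tt, pres, disp, rep(0, n), rep(25, n),
                                     pres, rate)
  prof <- extract_profile(tr, system_params(), print_settings(10))
  expect_equal(prof$max_pressure, max(pres))
  expect_equal(prof$max_pressure, pres[n - 100])
  expect_equal(prof$yield_point, 500, tolerance = 0.08)
})

test_that("simulator ground truth is recovered: yield within 5%, steady apparent viscosity within 10%", {
  fl <- fluid_params(yield_pressure = 400, flow_index_n = 0.4)
  sys <- system_params()
  for (seed in c(31, 32, 33)) {
    prot <- extrusion_protocol(10)
    tr <- simulate_extrusion_trace(fl, sys, prot, seed = seed)
    bl <- simulate_extrusion_trace(NULL, sys, prot, seed = seed + 500)
    prof <- extract_profile(baseline_correct(tr, bl), sys, print_settings(10))
    expect_equal(prof$yield_point, 400, tolerance = 0.05)
    # analytic steady apparent viscosity under the same convention
    p_star <- steady_state_pressure(fl, sys, 0.01)
    f_star <- p_star * (pi * 19.3^2 / 4) / 1000
    stress <- 1000 * f_star / (pi * 0.305^2)
    expect_equal(prof$apparent_viscosity, stress / prof$shear_rate,
                 tolerance = 0.1)
  }
})

test_that("yield is speed-invariant while yield time falls and viscosities fall with speed", {
  fl <- fluid_params()
  sys <- system_params()
  profs <- lapply(c(10, 20, 30), function(tps) {
    prot <- extrusion_protocol(tps)
    tr <- simulate_extrusion_trace(fl, sys, prot, seed = 40 + tps)
    bl <- simulate_extrusion_trace(NULL, sys, prot, seed = 140 + tps)
    extract_profile(baseline_correct(tr, bl), sys, print_settings(tps))
  })
  yields <- vapply(profs, `[[`, numeric(1), "yield_point")
  expect_lt(diff(range(yields)) / mean(yields), 0.05)
  ytimes <- vapply(profs, `[[`, numeric(1), "yield_time")
  expect_true(all(diff(ytimes) < 0))
  app <- vapply(profs, `[[`, numeric(1), "apparent_viscosity")
  dyn <- vapply(profs, `[[`, numeric(1), "dynamic_viscosity")
  expect_true(all(diff(app) < 0))
  expect_true(all(diff(dyn) < 0))
  maxp <- vapply(profs, `[[`, numeric(1), "max_pressure")
  steady <- vapply(profs, function(p) attr(p, "steady_pressure"), numeric(1))
  expect_true(all(diff(steady) > 0))
})

test_that("apparent viscosity times shear rate reproduces the steady stress to machine precision", {
  tr <- ideal_ramp_trace()
  prof <- extract_profile(tr, system_params(), print_settings(10))
  expect_equal(prof$apparent_viscosity * prof$shear_rate,
               prof$shear_stress_steady, tolerance = 1e-12)
})

test_that("reference stress/viscosity ratios scale 1:2:3 with speed within 10%", {
  ta <- reference_data("profiles_ta")
  for (f in unique(ta$formulation)) {
    sub <- ta[ta$formulation == f, ]
    ratio <- sub$shear_stress_steady_kPa / sub$apparent_viscosity
    base <- ratio[sub$speed_mm_s == 10]
    expect_equal(ratio[sub$speed_mm_s == 20] / base, 2, tolerance = 0.1)
    expect_equal(ratio[sub$speed_mm_s == 30] / base, 3, tolerance = 0.1)
  }
})
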