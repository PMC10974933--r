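# Extrusion-trace, rheometer and image generators against closed-form
# oracles and construction-level invariants.

test_that("friction-only baseline run reads the friction pressure, extrudes nothing", {
  sys <- system_params(friction_force = 2, noise_sd = 0.5)
  tr <- simulate_extrusion_trace(NULL, sys, extrusion_protocol(10), seed = 1)
  expect_equal(max(tr$extruded_mass), 0)
  fric_kPa <- 1000 * 2 / (pi * 19.3^2 / 4)
  expect_equal(mean(tr$pressure), fric_kPa, tolerance = 0.02)
  expect_lt(sd(tr$pressure), 3 * 0.5)
})

test_that("a stationary plunger never pressurizes and never extrudes", {
  sys <- system_params(friction_force = 2, noise_sd = 0.5)
  prot <- plunger_protocol(list(list(hold = 60)), sampling_rate = 5)
  tr <- simulate_extrusion_trace(fluid_params(yield_pressure = 400), sys,
                                 prot, seed = 2)
  expect_equal(max(tr$extruded_mass), 0)
  expect_true(all(attr(tr, "internal_pressure") == 0))
  fric_kPa <- 1000 * 2 / (pi * 19.3^2 / 4)
  expect_lt(max(abs(tr$pressure - fric_kPa)), 5 * 0.5)
})

test_that("Newtonian steady pressure matches the Hagen-Poiseuille closed form within 1%", {
  # independent oracle: delta_P = 8 mu L Q / (pi r^4), in kPa
  mu <- 30
  sys <- stiff_system(noise_sd = 0)
  for (v in c(0.01, 0.02)) {
    Q <- v * pi * 19.3^2 / 4
    r <- 0.305
    hp_kPa <- 8 * (mu / 1000) * 25 * Q / (pi * r^4)
    prot <- plunger_protocol(list(list(speed = v, distance = 5)),
                             sampling_rate = 5)
    tr <- simulate_extrusion_trace(newtonian_fluid(mu), sys, prot, seed = 3)
    late <- tail(attr(tr, "internal_pressure"), 50)
    expect_equal(mean(late), hp_kPa, tolerance = 0.01)
    expect_equal(steady_state_pressure(newtonian_fluid(mu), sys, v), hp_kPa,
                 tolerance = 1e-9)
  }
})

test_that("mass is conserved: extruded mass bounded by swept volume, equality at drained end state", {
  fl <- newtonian_fluid(20)
  sys <- stiff_system(noise_sd = 0)
  prot <- plunger_protocol(list(list(speed = 0.02, distance = 5),
                                list(hold = 120)), sampling_rate = 5)
  tr <- simulate_extrusion_trace(fl, sys, prot, seed = 4)
  swept <- fl$density * (pi * 19.3^2 / 4) * 5
  expect_lte(max(tr$extruded_mass), swept * (1 + 1e-6))
  # yield-free fluid drains completely during the hold
  expect_equal(max(tr$extruded_mass), swept, tolerance = 0.01)
})

test_that("steady pressure increases strictly with plunger speed", {
  fl <- fluid_params()
  sys <- system_params(noise_sd = 0)
  steadies <- vapply(c(10, 20, 30), function(tps) {
    prot <- extrusion_protocol(tps, sampling_rate = 5)
    tr <- simulate_extrusion_trace(fl, sys, prot, seed = 5)
    ip <- attr(tr, "internal_pressure")
    comp_n <- round(5 / abs(prot$steps[[1]]$speed) * 5)
    mean(ip[(comp_n - 100):comp_n])
  }, numeric(1))
  expect_true(all(diff(steadies) > 0))
  analytic <- vapply(c(10, 20, 30), function(tps)
    steady_state_pressure(fl, sys, plunger_speed(print_settings(tps))),
    numeric(1))
  expect_equal(steadies, analytic, tolerance = 0.005)
})

test_that("clog raises the pressure maximum; bubble depresses pressure in its window", {
  fl <- fluid_params()
  sys <- system_params()
  prot <- plunger_protocol(list(list(speed = 0.02, distance = 5)),
                           sampling_rate = 5)
  base <- simulate_extrusion_trace(fl, sys, prot, seed = 6)
  clog <- simulate_extrusion_trace(
    fl, sys, prot, events = list(event_spec("clog", 150, 0.8, 20)), seed = 6)
  expect_gt(max(clog$pressure), max(base$pressure))
  bub <- simulate_extrusion_trace(
    fl, sys, prot, events = list(event_spec("bubble", 150, 1, 20)), seed = 6)
  win <- which(base$time >= 150 & base$time < 160)
  expect_lt(mean(bub$pressure[win]), mean(base$pressure[win]) - 50)
})

test_that("identical seeds reproduce traces bit-for-bit; seeds do not leak RNG state", {
  prot <- extrusion_protocol(20, sampling_rate = 2)
  a <- simulate_extrusion_trace(fluid_params(), system_params(), prot, seed = 7)
  b <- simulate_extrusion_trace(fluid_params(), system_params(), prot, seed = 7)
  expect_identical(a$pressure, b$pressure)
  c2 <- simulate_extrusion_trace(fluid_params(), system_params(), prot, seed = 8)
  expect_false(identical(a$pressure, c2$pressure))
  set.seed(123); x1 <- runif(1)
  set.seed(123)
  invisible(simulate_extrusion_trace(fluid_params(), system_params(), prot,
                                     seed = 9))
  expect_identical(runif(1), x1)
})

test_that("invalid parameters and empty protocols are rejected", {
  expect_error(fluid_params(consistency_K = -1), "consistency_K")
  expect_error(fluid_params(flow_index_n = 2), "flow_index_n")
  expect_error(system_params(compliance = 0), "compliance")
  expect_error(plunger_protocol(list()), "non-empty")
  expect_error(plunger_protocol(list(list(speed = 1))), "speed")
  expect_error(event_spec("clog", 10, magnitude = 1.5, duration = 5),
               "magnitude")
})

test_that("gel sweeps have G' above G'' and parallel log-log slopes by construction", {
  rh <- simulate_rheometer(gel_params(loss_ratio = 0.3), seed = 11)
  fs <- rh$frequency_sweep
  expect_true(all(fs$G_prime > fs$G_double_prime))
  as_ <- rh$amplitude_sweep
  expect_true(all(as_$G_prime[1:5] > as_$G_double_prime[1:5]))
})

test_that("purely elastic creep recovers fully; Burgers unrecovered strain matches sigma*t/eta", {
  el <- burgers_params(E1 = 1e4, eta1 = Inf, E2 = 5e3, eta2 = 1e3,
                       noise_sd = 0)
  rh <- simulate_rheometer(creep = el, seed = 12)
  cs <- creep_summary(rh$creep)
  expect_equal(cs$recovered_pct, rep(100, 3), tolerance = 0.02)

  # independent oracle: permanent strain per cycle of a Burgers body is
  # stress * on_time / eta1 (the Maxwell dashpot term)
  bp <- burgers_params(E1 = 2e4, eta1 = 1e6, E2 = 1e4, eta2 = 5e4,
                       noise_sd = 0)
  rh2 <- simulate_rheometer(creep = bp, stress = 500, on_time = 60,
                            off_time = 60, n_cycles = 3, seed = 13)
  cs2 <- creep_summary(rh2$creep)
  unrec <- cs2$residual_strain - cs2$start_strain
  expect_equal(unrec, rep(500 * 60 / 1e6, 3), tolerance = 0.02)
})

test_that("rendered batches have the designed number of disks and faithful diameters", {
  b <- design_batch(n = 4, speeds = 10, counts = 4, priming = NULL)
  img <- render_batch_image(b$batch, pixel_scale = 5, noise_sd = 0, seed = 1)
  lab <- EBImage::bwlabel(EBImage::Image(img$image > 0.5))
  expect_equal(max(lab), 4)

  one <- design_batch(n = 1, speeds = 10, counts = 1, priming = NULL)
  im1 <- render_batch_image(one$batch, pixel_scale = 10, noise_sd = 0, seed = 1)
  expect_equal(im1$truth$diameter, 12)
  px <- sum(im1$image > 0.5)
  expect_equal(2 * sqrt(px / pi), 120, tolerance = 1 / 120)

  empty <- structure(list(printlets = data.frame(id = character(0),
                                                 x = numeric(0), y = numeric(0),
                                                 speed = numeric(0),
                                                 priming = logical(0)),
                          radius = 6), class = "batch_model")
  im0 <- render_batch_image(empty, pixel_scale = 5, noise_sd = 0, seed = 1)
  expect_equal(max(EBImage::bwlabel(EBImage::Image(im0$image > 0.5))), 0)
})

test_that("weights rise weakly with assigned speed", {
  fb <- full_batch()
  w <- simulate_weights(fb$timeline, seed = 21)
  iv <- ssepat:::printlet_intervals(fb$timeline)
  w$speed <- iv$speed[match(w$printlet_id, iv$printlet_id)]
  w$priming <- iv$priming[match(w$printlet_id, iv$printlet_id)]
  means <- tapply(w$weight[!w$priming], w$speed[!w$priming], mean)
  expect_true(all(diff(means[order(as.numeric(names(means)))]) > 0))
})
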