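# Trace/timeline alignment, per-printlet reports, anomaly detection.

test_that("segmentation covers every printlet once and AUCs are exactly additive", {
  fb <- small_batch()
  run <- simulate_print_run(fb$timeline, fluid_params(), system_params(),
                            seed = 1)
  segs <- segment_by_printlet(run, fb$timeline)
  expect_equal(nrow(segs), 8)  # 6 + 2 priming
  expect_true(all(segs$i_start <= segs$i_end))
  expect_true(all(segs$i_start[-1] > segs$i_end[-nrow(segs)]))

  # left-attributed interval AUCs over all groups == whole-trace integral
  area <- pi * 19.3^2 / 4
  rec <- batch_report(run, fb$timeline)
  pid <- rep(NA_character_, nrow(run))
  for (i in seq_len(nrow(segs)))
    pid[segs$i_start[i]:segs$i_end[i]] <- segs$printlet_id[i]
  grp <- ifelse(is.na(pid), "travel", pid)
  total <- ssepat:::trapz(run$time, run$pressure * area / 1000)
  parts <- ssepat:::trapz_by(run$time, run$pressure * area / 1000, grp)
  expect_equal(sum(parts), total, tolerance = 1e-12)
  travel_auc <- if ("travel" %in% names(parts)) parts[["travel"]] else 0
  expect_equal(sum(rec$auc) + travel_auc, total, tolerance = 1e-9)
})

test_that("an empty timeline yields zero segments", {
  tl <- motion_timeline(character(0))
  run <- simulate_print_run
  tr <- ssepat:::new_extrusion_trace(1:10 / 2, rep(1, 10), rep(0, 10),
                                     rep(0, 10), rep(25, 10), NULL, 2)
  expect_equal(nrow(segment_by_printlet(tr, tl)), 0)
})

test_that("a constant-pressure segment reports auc = P*A*T and its mean exactly", {
  g <- c("; PRINTLET A BEGIN", "G1 X100 Y0 E10 F600", "; PRINTLET A END")
  tl <- motion_timeline(g, sampling_rate = 2)  # 10 s move
  n <- 21
  tr <- ssepat:::new_extrusion_trace(seq(0.5, 10.5, by = 0.5), rep(200, n),
                                     rep(0, n), rep(0, n), rep(25, n), NULL, 2)
  seg <- segment_by_printlet(tr, tl)
  area <- 100
  rep1 <- printlet_report(seg[1, ], tr, tl, syringe_area = area)
  expect_equal(rep1$auc, 200 * area / 1000 * rep1$duration, tolerance = 1e-12)
  expect_equal(rep1$mean_pressure, 200)
  zero <- tr; zero$pressure <- rep(0, n)
  rep0 <- printlet_report(seg[1, ], zero, tl, syringe_area = area)
  expect_equal(rep0$auc, 0)
  expect_equal(rep0$mean_pressure, 0)
})

test_that("short segments are flagged but still measured", {
  g <- c("; PRINTLET A BEGIN", "G1 X1 Y0 E1 F60", "; PRINTLET A END")
  tl <- motion_timeline(g, sampling_rate = 2)
  tr <- ssepat:::new_extrusion_trace(c(0.4, 0.9), c(100, 100), c(0, 0),
                                     c(0, 0), c(25, 25), NULL, 2)
  seg <- segment_by_printlet(tr, tl)
  rep1 <- printlet_report(seg[1, ], tr, tl, syringe_area = 100)
  expect_true(rep1$short_segment)
  expect_equal(rep1$mean_pressure, 100)
})

test_that("group-mean pressure rises and AUC falls monotonically with speed", {
  fb <- full_batch()
  run <- simulate_print_run(fb$timeline, fluid_params(), system_params(),
                            seed = 2)
  rec <- batch_report(run, fb$timeline)
  main <- rec[!rec$priming, ]
  mp <- tapply(main$mean_pressure, main$assigned_speed, mean)
  au <- tapply(main$auc, main$assigned_speed, mean)
  o <- order(as.numeric(names(mp)))
  expect_true(all(diff(mp[o]) > 0))
  expect_true(all(diff(au[o]) < 0))
})

test_that("printlet metrics are stable under print-order permutation", {
  fb1 <- full_batch(seed = 42)
  d <- fb1$design
  r2 <- randomize_speeds(d$gcode, seed = 77)
  tl2 <- motion_timeline(r2$gcode, 2)
  run1 <- simulate_print_run(fb1$timeline, fluid_params(), system_params(),
                             seed = 3)
  run2 <- simulate_print_run(tl2, fluid_params(), system_params(), seed = 3)
  rec1 <- batch_report(run1, fb1$timeline)
  rec2 <- batch_report(run2, tl2)
  m <- merge(rec1, rec2, by = c("assigned_speed", "priming"))
  # same-speed printlets agree in the mean within 3 noise SDs
  a1 <- tapply(rec1$mean_pressure[!rec1$priming],
               rec1$assigned_speed[!rec1$priming], mean)
  a2 <- tapply(rec2$mean_pressure[!rec2$priming],
               rec2$assigned_speed[!rec2$priming], mean)
  expect_true(all(abs(a1 - a2) < 3 * 5))
})

test_that("injected clogs and bubbles are found on the right printlet; clean runs stay quiet", {
  fb <- full_batch()
  iv <- ssepat:::printlet_intervals(fb$timeline)
  main <- iv[!iv$priming, ]
  row <- main[10, ]
  tmid <- row$t_begin + 0.3 * (row$t_end - row$t_begin)
  clog_run <- simulate_print_run(
    fb$timeline, fluid_params(), system_params(),
    events = list(event_spec("clog", tmid, 0.8, 20)), seed = 4)
  ev <- detect_anomalies(clog_run, timeline = fb$timeline)
  cl <- ev[ev$kind == "clog", ]
  expect_gte(nrow(cl), 1)
  expect_true(row$printlet_id %in% cl$printlet_id)

  bub_run <- simulate_print_run(
    fb$timeline, fluid_params(), system_params(),
    events = list(event_spec("bubble", tmid, 1, 20)), seed = 4)
  ev2 <- detect_anomalies(bub_run, timeline = fb$timeline)
  air <- ev2[ev2$kind == "air", ]
  expect_gte(nrow(air), 1)
  expect_true(row$printlet_id %in% air$printlet_id)

  clean <- simulate_print_run(fb$timeline, fluid_params(), system_params(),
                              seed = 5)
  expect_lte(nrow(detect_anomalies(clean, timeline = fb$timeline)), 1)
  bad <- clean
  bad$pressure[100] <- NaN
  expect_error(detect_anomalies(bad), "sample 100")
})

test_that("scatter export is deterministic and covers all printlets", {
  fb <- small_batch()
  run <- simulate_print_run(fb$timeline, fluid_params(), system_params(),
                            seed = 6)
  s1 <- export_scatter(run, fb$timeline)
  s2 <- export_scatter(run, fb$timeline)
  expect_identical(s1, s2)
  expect_equal(length(unique(s1$printlet_id)), 8)
  expect_equal(nrow(s1), sum(fb$timeline$samples$extruding))
})
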