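# End-to-end deterministic pipeline: simulate -> profile -> design /
# randomize -> print -> PAT report -> off-line QC, with a manifest.

default_config <- function() {
  list(
    seed = 1,
    formulation = "F1",
    speeds = c(10, 20, 30),
    counts = c(20, 20, 20),
    priming = list(speed = 5, count = 10),
    layer_height = 0.61,
    printlet_radius = 6,
    printlet_height = 2.4,
    spacing = 10,
    infill = 0.7,
    shells = 2,
    fluid = list(yield_pressure = 400, consistency_K = 6, flow_index_n = 0.4,
                 density = 0.00125),
    system = list(syringe_inner_diameter = 19.3, nozzle_inner_diameter = 0.61,
                  nozzle_length = 25, compliance = 0.78, friction_force = 8,
                  noise_sd = 5, temperature_C = 25),
    trace_rate = 5,
    timeline_rate = 2,
    pixel_scale = 4,
    events = list()
  )
}

validate_config <- function(config) {
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg <- modifyList(base, config)
  if (length(cfg$speeds) != length(cfg$counts))
    stopf("config: speeds and counts differ in length")
  cfg
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage `%s` failed: %s", name, conditionMessage(e)))
}

#' Run the full analytics pipeline
#'
#' Deterministically produces, under `out_dir`: extrudability traces and
#' profiles per speed, the batch gcode with randomized speeds, the batch
#' pressure trace, per-printlet PAT records (CSV + JSON), detected
#' anomalies, the rendered batch image and its measurements, speed-effect
#' statistics, and a manifest recording the package version, seed and
#' config hash. All randomness derives from `config$seed`.
#'
#' @param config Named list overriding the defaults (see the pipeline
#'   vignette); unknown keys are rejected.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("ssepat_run_")) {
  cfg <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fluid <- do.call(fluid_params, cfg$fluid)
  system <- do.call(system_params, cfg$system)

  # 1. extrudability study per speed, with friction baseline correction
  profiles <- stage("profile", {
    rows <- lapply(seq_along(cfg$speeds), function(i) {
      sp <- cfg$speeds[i]
      prot <- extrusion_protocol(sp, cfg$layer_height,
                                 system$syringe_inner_diameter,
                                 sampling_rate = cfg$trace_rate)
      tr <- simulate_extrusion_trace(fluid, system, prot,
                                     seed = cfg$seed + i,
                                     metadata = list(speed = sp))
      bl <- simulate_extrusion_trace(NULL, system, prot,
                                     seed = cfg$seed + 100 + i)
      corrected <- baseline_correct(tr, bl)
      write_trace(tr, file.path(out_dir, sprintf("trace_%02dmms.csv", sp)))
      prof <- extract_profile(corrected, system, print_settings(sp, cfg$layer_height))
      cbind(formulation = cfg$formulation, speed_mm_s = sp, prof)
    })
    do.call(rbind, rows)
  })
  write_profiles(profiles, file.path(out_dir, "profiles.csv"))

  # 2. batch design + speed randomization
  design <- stage("design", do.call(design_batch, list(
    n = sum(cfg$counts), radius = cfg$printlet_radius,
    height = cfg$printlet_height, layer_height = cfg$layer_height,
    spacing = cfg$spacing, speeds = cfg$speeds, counts = cfg$counts,
    priming = cfg$priming, shells = cfg$shells, infill = cfg$infill,
    nozzle_diameter = system$nozzle_inner_diameter)))
  rnd <- stage("randomize",
               randomize_speeds(design$gcode, cfg$speeds, cfg$counts,
                                seed = cfg$seed + 7))
  writeLines(rnd$gcode, file.path(out_dir, "batch.gcode"))
  write.csv(rnd$assignment, file.path(out_dir, "speed_assignment.csv"),
            row.names = FALSE)

  # 3. print-run simulation + PAT
  timeline <- stage("report", motion_timeline(rnd$gcode, cfg$timeline_rate))
  events <- lapply(cfg$events, function(e) do.call(event_spec, e))
  run <- stage("report", simulate_print_run(timeline, fluid, system,
                                            events = events,
                                            seed = cfg$seed + 13))
  write_trace(run, file.path(out_dir, "print_trace.csv"))
  anomalies <- stage("report", detect_anomalies(run, timeline = timeline))
  weights <- stage("report", simulate_weights(timeline,
                                              density = fluid$density,
                                              seed = cfg$seed + 17))
  records <- stage("report", batch_report(run, timeline, system,
                                          weights = weights,
                                          anomalies = anomalies))
  write.csv(records, file.path(out_dir, "printlet_records.csv"),
            row.names = FALSE)
  jsonlite::write_json(records, file.path(out_dir, "printlet_records.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  write.csv(anomalies, file.path(out_dir, "anomalies.csv"), row.names = FALSE)
  scatter <- stage("report", export_scatter(run, timeline))
  write.csv(scatter, file.path(out_dir, "scatter.csv"), row.names = FALSE)

  # 4. off-line QC: image + weights/diameter statistics
  img <- stage("qc", render_batch_image(design$batch,
                                        pixel_scale = cfg$pixel_scale,
                                        seed = cfg$seed + 23))
  write_batch_png(img, file.path(out_dir, "batch.png"))
  meas <- stage("qc", measure_printlets(img,
                                        design_diameter = 2 * cfg$printlet_radius))
  write.csv(meas, file.path(out_dir, "measurements.csv"), row.names = FALSE)
  stats_in <- records[!records$priming, ]
  qc_stats <- stage("qc", speed_effect_tests(stats_in,
                                             c("mean_pressure", "auc")))
  jsonlite::write_json(list(univariate = qc_stats$univariate,
                            multivariate = qc_stats$multivariate),
                       file.path(out_dir, "speed_effect.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)

  manifest <- list(package = "ssepat",
                   version = as.character(packageVersion("ssepat")),
                   seed = cfg$seed, config_hash = config_hash(cfg),
                   n_printlets = nrow(records),
                   files = sort(list.files(out_dir)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
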