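Package: ssepat
Title: Process Analytics for Instrumented Semi-Solid Extrusion 3D Printing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analytics for pressure-instrumented semi-solid extrusion (SSE)
    3D printing of pharmaceutical dosage units. Provides a physics-based
    generator of plunger-driven extrusion pressure traces (quasi-static
    compliance coupled to Herschel-Bulkley capillary flow), oscillatory and
    creep-recovery rheometer series, and printlet batch images; extrudability
    profiling of traces (yield point, Young modulus, steady-flow stress,
    apparent and dynamic viscosity); a minimal gcode toolpath generator with
    seeded per-printlet speed randomization and a constant-velocity motion
    model; in-line process-analytical-technology reports per dosage unit
    (mean pressure, area under the force-time curve, clog/air anomaly flags);
    and off-line quality control (image-based diameter and edge-defect
    measurement, instrument-comparison regression, speed-effect ANOVA, Tukey
    HSD and MANOVA summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
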