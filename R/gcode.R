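# Batch design, gcode generation, per-printlet speed randomization and the
# constant-velocity motion model. Dialect: RepRap-flavour absolute G0/G1
# with F in mm/min and cumulative E; printlet boundaries are marked with
# structured comments `; PRINTLET <id> BEGIN [PRIMING]` / `; PRINTLET <id>
# END`, which the randomizer and the motion model rely on.

fmt <- function(x, digits = 3) formatC(x, format = "f", digits = digits)

circle_points <- function(cx, cy, r, n = 48) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# toolpath of one printlet layer: `shells` concentric perimeters plus
# serpentine rectilinear infill at the given fraction
layer_paths <- function(cx, cy, radius, shells, infill, width) {
  paths <- list()
  for (s in seq_len(shells)) {
    rs <- radius - (s - 0.5) * width
    if (rs > width) paths[[length(paths) + 1L]] <- circle_points(cx, cy, rs)
  }
  if (infill > 0) {
    ri <- radius - shells * width
    if (ri > width) {
      gap <- width / infill
      ys <- seq(cy - ri + gap / 2, cy + ri - gap / 2, by = gap)
      dirp <- TRUE
      for (yy in ys) {
        half <- sqrt(max(0, ri^2 - (yy - cy)^2))
        seg <- if (dirp) cbind(c(cx - half, cx + half), c(yy, yy))
               else cbind(c(cx + half, cx - half), c(yy, yy))
        paths[[length(paths) + 1L]] <- seg
        dirp <- !dirp
      }
    }
  }
  paths
}

#' Design a printlet batch and generate its gcode
#'
#' Lays `n` cylindrical printlets (plus priming units) on a square grid
#' and emits a simplified sliced toolpath: per layer, `shells` concentric
#' perimeters and serpentine rectilinear infill at `infill` fraction.
#' Priming printlets come first in scan order; the remaining units are
#' assigned the requested speeds in order (use [randomize_speeds()] for
#' the seeded random assignment).
#'
#' @param n Number of non-priming printlets; must equal `sum(counts)`.
#' @param radius,height Printlet cylinder radius and height, mm.
#' @param layer_height mm; layers per printlet = `ceiling(height /
#'   layer_height)`.
#' @param spacing Edge-to-edge gap between neighbouring printlets, mm
#'   (centre pitch = `2 * radius + spacing`).
#' @param speeds,counts Print speeds (mm/s) and how many printlets get
#'   each.
#' @param priming List `speed`, `count` for the syringe-pressurization
#'   units printed first.
#' @param shells Perimeter count.
#' @param infill Rectilinear infill fraction in [0, 1].
#' @param nozzle_diameter Extrusion width, mm.
#' @param travel_speed Travel-move speed, mm/s.
#' @param margin Grid margin, mm.
#' @param allow_overlap Permit layouts whose disks touch.
#' @return List with `batch` (a `batch_model`: `printlets` data frame with
#'   `id`, `x`, `y`, `speed`, `priming`, plus geometry fields) and `gcode`
#'   (character vector of lines).
#' @export
#' @examples
#' b <- design_batch(n = 4, speeds = c(10, 20), counts = c(2, 2),
#'                   priming = list(speed = 5, count = 1))
#' length(unique(b$batch$printlets$id))
design_batch <- function(n = 60, radius = 6, height = 2.4, layer_height = 0.61,
                         spacing = 10, speeds = c(10, 20, 30),
                         counts = c(20, 20, 20),
                         priming = list(speed = 5, count = 10),
                         shells = 2, infill = 0.7, nozzle_diameter = 0.61,
                         travel_speed = 50, margin = 5,
                         allow_overlap = FALSE) {
  if (length(speeds) != length(counts))
    stopf("`speeds` and `counts` must have the same length")
  if (n != sum(counts))
    stopf("n = %d but sum(counts) = %d", n, sum(counts))
  check_positive(radius, "radius"); check_positive(height, "height")
  check_positive(layer_height, "layer_height")
  pitch <- 2 * radius + spacing
  if (pitch <= 2 * radius && !allow_overlap)
    stopf("printlets overlap at spacing %.3g mm; set allow_overlap = TRUE to force",
          spacing)
  n_prime <- if (is.null(priming)) 0L else priming$count
  total <- n + n_prime
  ncols <- ceiling(sqrt(total))
  idx <- seq_len(total) - 1L
  px <- margin + radius + (idx %% ncols) * pitch
  py <- margin + radius + (idx %/% ncols) * pitch
  spd <- c(rep(priming$speed, n_prime), rep(speeds, counts))
  printlets <- data.frame(
    id = sprintf("P%03d", seq_len(total)), x = px, y = py,
    speed = spd, priming = seq_len(total) <= n_prime)

  nlayers <- ceiling(height / layer_height)
  w <- nozzle_diameter
  chunks <- vector("list", total + 1L)
  chunks[[1L]] <- c("; ssepat batch gcode",
                    sprintf("; LAYER_HEIGHT %s", fmt(layer_height)),
                    sprintf("; NOZZLE %s", fmt(nozzle_diameter)), "G90", "G21")
  e <- 0
  for (i in seq_len(total)) {
    p <- printlets[i, ]
    blk <- list(sprintf("; PRINTLET %s BEGIN%s", p$id,
                        if (p$priming) " PRIMING" else ""))
    for (l in seq_len(nlayers)) {
      z <- l * layer_height
      paths <- layer_paths(p$x, p$y, radius, shells, infill, w)
      for (path in paths) {
        seglen <- sqrt(rowSums((path[-1, , drop = FALSE] -
                                  path[-nrow(path), , drop = FALSE])^2))
        ee <- e + cumsum(seglen * w * layer_height)
        e <- ee[length(ee)]
        blk[[length(blk) + 1L]] <- c(
          sprintf("G0 X%s Y%s Z%s F%s", fmt(path[1, 1]), fmt(path[1, 2]),
                  fmt(z), fmt(travel_speed * 60, 0)),
          sprintf("G1 X%s Y%s Z%s E%s F%s", fmt(path[-1, 1]), fmt(path[-1, 2]),
                  fmt(z), fmt(ee, 5), fmt(p$speed * 60, 0)))
      }
    }
    blk[[length(blk) + 1L]] <- sprintf("; PRINTLET %s END", p$id)
    chunks[[i + 1L]] <- unlist(blk)
  }
  lines <- unlist(chunks)
  batch <- structure(list(printlets = printlets, radius = radius,
                          height = height, layer_height = layer_height,
                          spacing = spacing, pitch = pitch, shells = shells,
                          infill = infill, nozzle_diameter = nozzle_diameter),
                     class = "batch_model")
  list(batch = batch, gcode = lines)
}

# index of block boundaries; returns data frame id, begin, end, priming
gcode_blocks <- function(gcode) {
  beg <- grep("^; PRINTLET \\S+ BEGIN", gcode)
  if (!length(beg))
    stopf("gcode has no `; PRINTLET <id> BEGIN` markers; use design_batch() output")
  fin <- grep("^; PRINTLET \\S+ END", gcode)
  if (length(beg) != length(fin)) stopf("unbalanced printlet markers")
  data.frame(id = sub("^; PRINTLET (\\S+) BEGIN.*", "\\1", gcode[beg]),
             begin = beg, end = fin,
             priming = grepl("PRIMING", gcode[beg]))
}

#' Randomize per-printlet print speeds in a gcode file
#'
#' Reassigns the requested speed multiset to the non-priming printlet
#' blocks as a seeded uniform permutation, rewriting the F word (mm/min)
#' of printing moves (G1 with an E word) only; travel moves and priming
#' blocks are untouched.
#'
#' @param gcode Character vector of gcode lines with printlet block
#'   markers (see [design_batch()]).
#' @param speeds,counts Speed set (mm/s) and counts; `sum(counts)` must
#'   equal the number of non-priming blocks.
#' @param seed Integer seed for the permutation.
#' @return List `gcode` (modified lines) and `assignment` (data frame
#'   `printlet_id`, `speed`).
#' @export
randomize_speeds <- function(gcode, speeds = c(10, 20, 30),
                             counts = c(20, 20, 20), seed = 1) {
  blocks <- gcode_blocks(gcode)
  work <- blocks[!blocks$priming, ]
  if (nrow(work) != sum(counts))
    stopf("gcode has %d non-priming printlet blocks but sum(counts) = %d",
          nrow(work), sum(counts))
  assigned <- with_seed(seed, sample(rep(speeds, counts)))
  out <- gcode
  for (i in seq_len(nrow(work))) {
    rng <- seq(work$begin[i], work$end[i])
    printing <- rng[grepl("^G1 ", out[rng]) & grepl(" E[0-9.-]", out[rng])]
    out[printing] <- sub("F[0-9.]+", sprintf("F%s", fmt(assigned[i] * 60, 0)),
                         out[printing])
  }
  list(gcode = out,
       assignment = data.frame(printlet_id = work$id, speed = assigned))
}

#' Time-resolved motion model of a gcode file
#'
#' Constant-velocity kinematics (no acceleration model): each G0/G1 move
#' lasts `distance / (F / 60)` seconds; positions are linearly
#' interpolated onto a regular sample grid. Printlet membership is
#' inherited from the block markers.
#'
#' @param gcode Character vector of gcode lines (absolute coordinates;
#'   G91 relative mode is rejected).
#' @param sampling_rate Samples per second, Hz.
#' @return A `motion_timeline`: list with `segments` (per-move table:
#'   `t0`, `t1`, endpoints, `speed` mm/s, `de`, `extruding`,
#'   `printlet_id`), `samples` (per-sample `time`, `x`, `y`, `z`,
#'   `commanded_speed`, `extruding`, `printlet_id`), `printlets`
#'   (id, priming, assigned speed), `total_time`, `sampling_rate`,
#'   `layer_height` (from the gcode header when present).
#' @export
motion_timeline <- function(gcode, sampling_rate = 2) {
  check_positive(sampling_rate, "sampling_rate")
  if (any(grepl("^G91\\b", gcode)))
    stopf("relative-mode gcode (G91) is not supported")
  lh <- NULL
  lh_line <- grep("^; LAYER_HEIGHT ", gcode, value = TRUE)
  if (length(lh_line)) lh <- as.numeric(sub("^; LAYER_HEIGHT ", "", lh_line[1]))

  # carry the last non-NA value forward (vectorized state tracking)
  locf <- function(v, init) {
    has <- !is.na(v)
    idx <- cumsum(has)
    out <- c(init, v[has])[idx + 1L]
    out
  }
  word_vec <- function(lines, letter) {
    m <- regexpr(paste0(letter, "-?[0-9.]+"), lines)
    out <- rep(NA_real_, length(lines))
    hit <- m > 0
    out[hit] <- as.numeric(substring(regmatches(lines, m), 2))
    out
  }

  nline <- length(gcode)
  is_begin <- grepl("^; PRINTLET \\S+ BEGIN", gcode)
  is_end <- grepl("^; PRINTLET \\S+ END", gcode)
  pid_line <- rep(NA_character_, nline)
  pid_line[is_begin] <- sub("^; PRINTLET (\\S+) BEGIN.*", "\\1", gcode[is_begin])
  pid_line[is_end] <- "<none>"
  pid_all <- locf(pid_line, "<none>")

  mv <- grep("^G[01] ", gcode)
  lines <- gcode[mv]
  xw <- word_vec(lines, "X"); yw <- word_vec(lines, "Y")
  zw <- word_vec(lines, "Z"); ew <- word_vec(lines, "E")
  fw <- word_vec(lines, "F")
  x1 <- locf(xw, 0); y1 <- locf(yw, 0); z1 <- locf(zw, 0)
  f <- locf(fw, 60)
  eabs <- locf(ew, 0)
  x0 <- c(0, x1[-length(x1)]); y0 <- c(0, y1[-length(y1)])
  z0 <- c(0, z1[-length(z1)])
  e0 <- c(0, eabs[-length(eabs)])
  d <- sqrt((x1 - x0)^2 + (y1 - y0)^2 + (z1 - z0)^2)
  de <- eabs - e0
  spd <- f / 60
  keep <- d > 0
  dur <- d[keep] / spd[keep]
  t1v <- cumsum(dur)
  t0v <- t1v - dur
  pid_seg <- pid_all[mv][keep]
  pid_seg[pid_seg == "<none>"] <- NA_character_
  segments <- data.frame(
    t0 = t0v, t1 = t1v, x0 = x0[keep], y0 = y0[keep], z0 = z0[keep],
    x1 = x1[keep], y1 = y1[keep], z1 = z1[keep], speed = spd[keep],
    de = de[keep], extruding = de[keep] > 0, printlet_id = pid_seg)
  nseg <- nrow(segments)
  total <- if (nseg) t1v[nseg] else 0
  if (nseg) {
    tt <- seq(0, total, by = 1 / sampling_rate)
    si <- pmin(pmax(findInterval(tt, segments$t0), 1L), nseg)
    frac <- (tt - segments$t0[si]) /
      pmax(segments$t1[si] - segments$t0[si], .Machine$double.eps)
    frac <- pmin(pmax(frac, 0), 1)
    samples <- data.frame(
      time = tt,
      x = segments$x0[si] + frac * (segments$x1[si] - segments$x0[si]),
      y = segments$y0[si] + frac * (segments$y1[si] - segments$y0[si]),
      z = segments$z0[si] + frac * (segments$z1[si] - segments$z0[si]),
      commanded_speed = ifelse(segments$extruding[si], segments$speed[si], 0),
      extruding = segments$extruding[si],
      printlet_id = segments$printlet_id[si])
    samples$printlet_id[!samples$extruding &
                          is.na(samples$printlet_id)] <- NA_character_
  } else {
    samples <- data.frame(time = numeric(0), x = numeric(0), y = numeric(0),
                          z = numeric(0), commanded_speed = numeric(0),
                          extruding = logical(0), printlet_id = character(0))
  }
  pls <- tryCatch(gcode_blocks(gcode)[, c("id", "priming")],
                  error = function(e) NULL)
  if (!is.null(pls) && nseg) {
    spd_tab <- segments[segments$extruding & !is.na(segments$printlet_id), ]
    pls$speed <- spd_tab$speed[match(pls$id, spd_tab$printlet_id)]
  }
  structure(list(segments = segments, samples = samples, printlets = pls,
                 total_time = total, sampling_rate = sampling_rate,
                 layer_height = lh),
            class = "motion_timeline")
}

# active [t_begin, t_end] interval of each printlet (travel moves inside a
# block included)
printlet_intervals <- function(timeline) {
  seg <- timeline$segments
  seg <- seg[!is.na(seg$printlet_id), ]
  if (!nrow(seg))
    return(data.frame(printlet_id = character(0), t_begin = numeric(0),
                      t_end = numeric(0)))
  sp <- split(seg, factor(seg$printlet_id, levels = unique(seg$printlet_id)))
  out <- data.frame(
    printlet_id = names(sp),
    t_begin = vapply(sp, function(d) min(d$t0), numeric(1)),
    t_end = vapply(sp, function(d) max(d$t1), numeric(1)))
  if (!is.null(timeline$printlets)) {
    out$speed <- timeline$printlets$speed[match(out$printlet_id,
                                                timeline$printlets$id)]
    out$priming <- timeline$printlets$priming[match(out$printlet_id,
                                                    timeline$printlets$id)]
  }
  rownames(out) <- NULL
  out[order(out$t_begin), ]
}

#' @export
print.motion_timeline <- function(x, ...) {
  cat(sprintf("Motion timeline: %d moves, %.1f s, %d printlets, %d samples at %g Hz\n",
              nrow(x$segments), x$total_time,
              if (is.null(x$printlets)) 0L else nrow(x$printlets),
              nrow(x$samples), x$sampling_rate))
  invisible(x)
}
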