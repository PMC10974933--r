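# In-line quality control: align the pressure trace with the motion
# timeline, report per-printlet metrics, flag clog/air anomalies.

#' Map trace samples to printlets
#'
#' Each trace sample is assigned to the printlet active at its time (or to
#' none, for travel between printlets). Segments are contiguous,
#' non-overlapping and exhaustive over the overlap of trace and timeline.
#'
#' @param trace An `extrusion_trace`.
#' @param timeline A [motion_timeline()].
#' @param offset Trace-to-timeline clock offset, s (trace time + offset =
#'   timeline time).
#' @return Data frame `printlet_id`, `i_start`, `i_end` (trace sample
#'   index ranges, in print order).
#' @export
segment_by_printlet <- function(trace, timeline, offset = 0) {
  validate_trace(trace)
  iv <- printlet_intervals(timeline)
  tt <- trace$time + offset
  if (max(trace$time) < timeline$total_time - 1 / timeline$sampling_rate)
    warning("trace is shorter than the timeline; segmentation truncated")
  if (!nrow(iv)) return(data.frame(printlet_id = character(0),
                                   i_start = integer(0), i_end = integer(0)))
  if (min(tt) > max(iv$t_end) || max(tt) < min(iv$t_begin))
    stopf("trace and timeline do not overlap in time")
  idx <- findInterval(tt, iv$t_begin)
  pid <- rep(NA_character_, length(tt))
  inside <- idx >= 1 & tt <= iv$t_end[pmax(idx, 1L)]
  pid[inside] <- iv$printlet_id[idx[inside]]
  r <- rle(ifelse(is.na(pid), "<travel>", pid))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "<travel>"
  data.frame(printlet_id = r$values[keep], i_start = starts[keep],
             i_end = ends[keep])
}

#' Per-printlet PAT report
#'
#' Time-weighted mean pressure and trapezoidal area under the force-time
#' curve over one printlet's trace segment. Force is pressure times the
#' syringe cross-section. Interval weights are attributed to the left
#' sample, so segment AUCs plus travel AUCs reproduce the whole-trace AUC
#' exactly.
#'
#' @param segment One row of [segment_by_printlet()] output (or a list
#'   with `printlet_id`, `i_start`, `i_end`).
#' @param trace The `extrusion_trace`.
#' @param timeline The [motion_timeline()] (supplies position, assigned
#'   speed, priming flag).
#' @param syringe_area mm^2.
#' @param humidity_pct Pass-through ambient humidity label.
#' @return A one-row data frame (`printlet_record`): `printlet_id`, `x`,
#'   `y`, `z`, `assigned_speed`, `mean_pressure` (kPa), `auc` (N*s),
#'   `duration` (s), `temperature_C`, `humidity_pct`, `priming`,
#'   `short_segment`.
#' @export
printlet_report <- function(segment, trace, timeline,
                            syringe_area = syringe_area(19.3),
                            humidity_pct = NA_real_) {
  validate_trace(trace)
  i0 <- segment$i_start; i1 <- segment$i_end
  if (is.null(i0) || is.null(i1) || i1 < i0) stopf("segment is empty")
  short <- (i1 - i0 + 1L) < 3L
  # left-attributed intervals: the segment owns [t_i, t_{i+1}] for every
  # sample i it contains, including the gap to the sample after it
  j1 <- min(i1 + 1L, nrow(trace))
  tt <- trace$time[i0:j1]
  pp <- trace$pressure[i0:j1]
  contrib_p <- trapz(tt, pp)
  dur <- trace$time[j1] - trace$time[i0]
  if (dur <= 0) dur <- .Machine$double.eps
  mean_p <- contrib_p / dur
  auc <- contrib_p * syringe_area / 1000  # kPa*mm^2 -> N
  iv <- printlet_intervals(timeline)
  row <- iv[iv$printlet_id == segment$printlet_id, , drop = FALSE]
  mid_t <- (trace$time[i0] + trace$time[i1]) / 2
  sm <- timeline$samples
  si <- which.min(abs(sm$time - mid_t))
  data.frame(printlet_id = segment$printlet_id,
             x = sm$x[si], y = sm$y[si], z = sm$z[si],
             assigned_speed = if (nrow(row) && !is.null(row$speed)) row$speed
                              else NA_real_,
             mean_pressure = mean_p, auc = auc, duration = dur,
             temperature_C = mean(trace$temperature_C[i0:i1]),
             humidity_pct = humidity_pct,
             priming = if (nrow(row) && !is.null(row$priming)) row$priming
                       else NA,
             short_segment = short)
}

#' Per-printlet reports for a whole batch
#'
#' Convenience wrapper: segments the trace and builds one
#' [printlet_report()] row per printlet, optionally joining weights and
#' flagging printlets hit by detected anomalies.
#'
#' @inheritParams segment_by_printlet
#' @param system A [system_params()] for the syringe area.
#' @param weights Optional data frame `printlet_id`, `weight` (g).
#' @param anomalies Optional [detect_anomalies()] output; adds logical
#'   `clog` / `air` columns.
#' @return Data frame of printlet records in print order.
#' @export
batch_report <- function(trace, timeline, system = system_params(),
                         weights = NULL, anomalies = NULL, offset = 0) {
  segs <- segment_by_printlet(trace, timeline, offset = offset)
  area <- syringe_area(system$syringe_inner_diameter)
  rows <- lapply(seq_len(nrow(segs)), function(i)
    printlet_report(segs[i, ], trace, timeline, syringe_area = area))
  rec <- do.call(rbind, rows)
  rec$clog <- FALSE
  rec$air <- FALSE
  if (!is.null(anomalies) && nrow(anomalies)) {
    rec$clog <- rec$printlet_id %in%
      anomalies$printlet_id[anomalies$kind == "clog"]
    rec$air <- rec$printlet_id %in%
      anomalies$printlet_id[anomalies$kind == "air"]
  }
  if (!is.null(weights))
    rec$weight <- weights$weight[match(rec$printlet_id, weights$printlet_id)]
  rec
}

#' Detect clog and air anomalies in a pressure trace
#'
#' Rolling robust z-score: residuals against a trailing-window rolling
#' median, scaled by a trailing MAD-based robust SD over the same
#' `window`. Trailing (causal) windows keep the baseline anchored to the
#' pre-event signal at the event onset, where a centred window would be
#' contaminated by the excursion itself. A clog is a positive excursion
#' beyond `k_sigma` robust SDs sustained for at least `min_duration`; an
#' air bubble is the mirror-image negative excursion (an excursion longer
#' than the window is truncated once the baseline adapts, which does not
#' affect detection). Events separated by less than `merge_gap` are
#' merged, and each is attributed to the printlet active at its peak.
#'
#' The default window and threshold are set by the physics of a
#' compliance-buffered printhead: a clog ramps the pressure at most at the
#' charging rate (plunger inflow / compliance), and the trailing-median
#' residual of a ramp saturates at `slope * window / 2`. A 20 s window
#' with a 6-sigma threshold keeps the legitimate pressurization ramp of
#' the priming phase below threshold while clog ramps at printing speeds
#' (at least twice that slope) cross it. The robust SD uses a longer
#' (`sd_window`) trailing MAD so a short event cannot inflate its own
#' threshold.
#'
#' @param trace An `extrusion_trace`.
#' @param window Rolling-median window, s.
#' @param k_sigma Detection threshold in robust SDs.
#' @param min_duration Minimum sustained excursion, s.
#' @param merge_gap Events closer than this are merged, s.
#' @param sd_window Trailing window of the robust SD, s.
#' @param timeline Optional [motion_timeline()] for printlet attribution.
#' @param sd_floor Lower bound on the robust SD, kPa (guards against a
#'   locally constant signal).
#' @return Data frame `kind`, `t_start`, `t_end`, `peak_deviation` (kPa),
#'   `printlet_id`.
#' @export
detect_anomalies <- function(trace, window = 20, k_sigma = 6,
                             min_duration = 1, merge_gap = 3,
                             sd_window = 3 * window,
                             timeline = NULL, sd_floor = 0.5) {
  validate_trace(trace)
  bad <- which(!is.finite(trace$pressure))
  if (length(bad))
    stopf("non-finite pressure at sample %d", bad[1])
  rate <- attr(trace, "sampling_rate") %||%
    (1 / median(diff(trace$time)))
  k <- max(3L, round(window * rate))
  ksd <- max(k, round(sd_window * rate))
  n <- nrow(trace)
  if (k >= n) stopf("trace shorter than the rolling window")
  trailing_median <- function(v, w) {
    vapply(seq_len(n), function(i) median(v[max(1L, i - w + 1L):i]),
           numeric(1))
  }
  med <- trailing_median(trace$pressure, k)
  resid <- trace$pressure - med
  # robust SD from a longer window lagged by the median window, so an
  # excursion cannot inflate its own detection threshold
  rsd_raw <- pmax(1.4826 * trailing_median(abs(resid), ksd), sd_floor)
  rsd <- rsd_raw[pmax(seq_len(n) - k, 1L)]
  z <- resid / rsd
  # 2 s trailing mean knocks the per-sample noise off z so genuine
  # excursions form sustained runs
  ks <- max(1L, round(2 * rate))
  cz <- cumsum(c(0, z))
  idx <- seq_len(n)
  lo <- pmax(idx - ks + 1L, 1L)
  zs <- (cz[idx + 1L] - cz[lo]) / (idx - lo + 1L)
  flag <- ifelse(zs > k_sigma, 1L, ifelse(zs < -k_sigma, -1L, 0L))
  # no verdicts until both windows hold real history
  flag[seq_len(min(n, k + ksd))] <- 0L
  r <- rle(flag)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  min_n <- max(1L, round(min_duration * rate))
  keep <- r$values != 0L & r$lengths >= min_n
  ev <- data.frame(kind = ifelse(r$values[keep] > 0, "clog", "air"),
                   i_start = starts[keep], i_end = ends[keep])
  if (nrow(ev) > 1) {
    merged <- ev[1, , drop = FALSE]
    for (i in 2:nrow(ev)) {
      last <- nrow(merged)
      gap <- trace$time[ev$i_start[i]] - trace$time[merged$i_end[last]]
      if (ev$kind[i] == merged$kind[last] && gap < merge_gap) {
        merged$i_end[last] <- ev$i_end[i]
      } else merged <- rbind(merged, ev[i, ])
    }
    ev <- merged
  }
  if (!nrow(ev))
    return(data.frame(kind = character(0), t_start = numeric(0),
                      t_end = numeric(0), peak_deviation = numeric(0),
                      printlet_id = character(0)))
  ev$t_start <- trace$time[ev$i_start]
  ev$t_end <- trace$time[ev$i_end]
  ev$peak_deviation <- vapply(seq_len(nrow(ev)), function(i)
    max(abs(resid[ev$i_start[i]:ev$i_end[i]])), numeric(1))
  ev$printlet_id <- NA_character_
  if (!is.null(timeline)) {
    iv <- printlet_intervals(timeline)
    for (i in seq_len(nrow(ev))) {
      # the trailing median lags: walk back to where the excursion began
      # and attribute the printlet active at the onset
      on <- ev$i_start[i]
      sgn <- if (ev$kind[i] == "clog") 1 else -1
      while (on > 1L && sgn * z[on - 1L] > 1) on <- on - 1L
      ton <- trace$time[on]
      hit <- which(iv$t_begin <= ton & iv$t_end >= ton)
      if (length(hit)) ev$printlet_id[i] <- iv$printlet_id[hit[1]]
    }
  }
  ev[, c("kind", "t_start", "t_end", "peak_deviation", "printlet_id")]
}

#' Spatially resolved pressure table for 3D scatter plots
#'
#' One row per extruding sample of the motion timeline - printer
#' coordinates, printlet id, and the trace pressure interpolated at that
#' time - suitable for plotting pressure in (X, Y, Z).
#'
#' @inheritParams segment_by_printlet
#' @return Data frame `x`, `y`, `z`, `pressure`, `printlet_id`; the row
#'   count equals the number of extruding timeline samples.
#' @export
export_scatter <- function(trace, timeline, offset = 0) {
  validate_trace(trace)
  sm <- timeline$samples
  ext <- which(sm$extruding)
  p <- stats::approx(trace$time + offset, trace$pressure, sm$time[ext],
                     rule = 2)$y
  data.frame(x = sm$x[ext], y = sm$y[ext], z = sm$z[ext], pressure = p,
             printlet_id = sm$printlet_id[ext])
}
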