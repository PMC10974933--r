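# Batch-image renderer: disks on the batch grid with optional per-printlet
# diameter offsets and edge notches, plus the ground-truth table the
# measurement stage is validated against.

#' Render a synthetic top-view image of a printed batch
#'
#' Draws one filled disk per printlet of a [design_batch()] model at its
#' batch coordinate. Per-printlet diameter offsets emulate spreading;
#' an edge notch (a circular bite centred on the rim) emulates an edge
#' defect. Mild Gaussian pixel noise is added so thresholding is
#' non-trivial.
#'
#' @param batch A `batch_model` from [design_batch()].
#' @param pixel_scale Pixels per mm.
#' @param diameter_offsets Optional named numeric vector (names = printlet
#'   ids) of diameter offsets in mm.
#' @param notches Optional data frame with columns `id`, `depth` (bite
#'   radius as a fraction of the printlet radius) and `angle` (radians).
#' @param noise_sd Pixel noise standard deviation (image in [0, 1]).
#' @param margin Border margin, mm.
#' @param seed Integer seed.
#' @return A `batch_image`: list with `image` (matrix, rows = y), `truth`
#'   (data frame `id`, `x`, `y`, `diameter`, `notched`), `pixel_scale`,
#'   and `overlap` flag (disks touching at the chosen scale).
#' @export
render_batch_image <- function(batch, pixel_scale = 5, diameter_offsets = NULL,
                               notches = NULL, noise_sd = 0.02, margin = 5,
                               seed = 1) {
  if (!inherits(batch, "batch_model")) stopf("`batch` must be a batch_model")
  check_positive(pixel_scale, "pixel_scale")
  pl <- batch$printlets
  n <- nrow(pl)
  dia <- rep(2 * batch$radius, length.out = max(n, 0L))
  if (n > 0 && !is.null(diameter_offsets)) {
    idx <- match(names(diameter_offsets), as.character(pl$id))
    if (anyNA(idx)) stopf("diameter_offsets name not a printlet id")
    dia[idx] <- dia[idx] + as.numeric(diameter_offsets)
  }
  if (n > 0) {
    wx <- max(pl$x + dia / 2) + margin
    wy <- max(pl$y + dia / 2) + margin
  } else {
    wx <- wy <- 2 * margin
  }
  ncol_px <- ceiling(wx * pixel_scale)
  nrow_px <- ceiling(wy * pixel_scale)
  img <- matrix(0, nrow = nrow_px, ncol = ncol_px)
  xs <- (seq_len(ncol_px) - 0.5) / pixel_scale
  ys <- (seq_len(nrow_px) - 0.5) / pixel_scale
  notched <- logical(n)
  for (i in seq_len(n)) {
    r <- dia[i] / 2
    cx <- pl$x[i]; cy <- pl$y[i]
    jx <- which(abs(xs - cx) <= r + 1 / pixel_scale)
    jy <- which(abs(ys - cy) <= r + 1 / pixel_scale)
    d2 <- outer((ys[jy] - cy)^2, (xs[jx] - cx)^2, `+`)
    inside <- d2 <= r^2
    if (!is.null(notches)) {
      k <- which(notches$id == pl$id[i])
      if (length(k)) {
        notched[i] <- TRUE
        for (kk in k) {
          nr <- notches$depth[kk] * r
          nx <- cx + r * cos(notches$angle[kk])
          ny <- cy + r * sin(notches$angle[kk])
          nd2 <- outer((ys[jy] - ny)^2, (xs[jx] - nx)^2, `+`)
          inside <- inside & (nd2 > nr^2)
        }
      }
    }
    img[jy, jx] <- pmax(img[jy, jx], inside * 1)
  }
  overlap <- FALSE
  if (n > 1) {
    dmat <- as.matrix(stats::dist(pl[, c("x", "y")]))
    diag(dmat) <- Inf
    overlap <- any(dmat < outer(dia / 2, dia / 2, `+`))
    if (overlap) warning("printlet disks overlap at the chosen layout")
  }
  if (noise_sd > 0)
    img <- pmin(pmax(img + with_seed(seed,
      rnorm(length(img), 0, noise_sd)), 0), 1)
  truth <- data.frame(id = pl$id, x = pl$x, y = pl$y, diameter = dia,
                      notched = notched)
  structure(list(image = img, truth = truth, pixel_scale = pixel_scale,
                 overlap = overlap), class = "batch_image")
}

#' Write / read a batch image as PNG
#'
#' @param x A `batch_image` or a numeric matrix in [0, 1].
#' @param path File path.
#' @return `write_batch_png()` returns `path` invisibly; `read_batch_png()`
#'   returns a grayscale matrix.
#' @export
write_batch_png <- function(x, path) {
  img <- if (inherits(x, "batch_image")) x$image else x
  png::writePNG(img, target = path)
  invisible(path)
}

#' @rdname write_batch_png
#' @export
read_batch_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' Per-printlet weights for a simulated batch
#'
#' Each dosage unit's weight is its deposited volume (the summed E-word
#' extrusion of its moves in the motion model) times the paste density,
#' inflated by a small speed-linked over-extrusion term
#' `1 + speed_gain * (speed / ref_speed - 1)` - emulating the slight
#' weight increase with print speed that the higher residual pressure at
#' higher speeds produces - plus seeded balance/process noise.
#'
#' @param timeline A [motion_timeline()] of the batch.
#' @param density Paste density, g/mm^3.
#' @param speed_gain Fractional over-extrusion per unit of
#'   `speed / ref_speed - 1`.
#' @param ref_speed Reference print speed, mm/s.
#' @param noise_sd Weighing/process noise, g.
#' @param seed Integer seed.
#' @return Data frame `printlet_id`, `weight` (g).
#' @export
simulate_weights <- function(timeline, density = 0.00125, speed_gain = 0.01,
                             ref_speed = 10, noise_sd = 0.005, seed = 1) {
  if (!inherits(timeline, "motion_timeline"))
    stopf("`timeline` must be a motion_timeline object")
  iv <- printlet_intervals(timeline)
  if (!nrow(iv))
    return(data.frame(printlet_id = character(0), weight = numeric(0)))
  seg <- timeline$segments
  seg <- seg[!is.na(seg$printlet_id), ]
  vol <- vapply(split(seg$de, seg$printlet_id), sum, numeric(1))
  w <- density * vol[iv$printlet_id] *
    (1 + speed_gain * (iv$speed / ref_speed - 1))
  w <- w + with_seed(seed, rnorm(length(w), 0, noise_sd))
  data.frame(printlet_id = iv$printlet_id, weight = unname(w))
}
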