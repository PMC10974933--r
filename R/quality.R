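# Off-line quality control: image-based printlet measurement and the
# instrument-comparison / speed-effect statistics.

#' Measure printlets in a batch image
#'
#' Global Otsu threshold, connected-component labelling, then per
#' component: equivalent-circle diameter `2 * sqrt(area / pi)` (robust to
#' edge notches), circularity `4 pi A / P^2` with the perimeter taken
#' from the traced contour polygon, dimensional accuracy
#' `100 * (1 - |diameter - design| / design)`, and an edge-defect flag
#' when circularity falls below `circ_min`.
#'
#' @param image Numeric matrix in [0, 1] (or a `batch_image`).
#' @param pixel_scale Pixels per mm.
#' @param design_diameter Nominal printlet diameter, mm.
#' @param threshold `"otsu"` or a numeric cut in (0, 1).
#' @param min_area_mm2 Components smaller than this are discarded as
#'   noise, mm^2.
#' @param circ_min Circularity below which `edge_defect` is flagged.
#' @param diameter_method `"equivalent-circle"` (default) or
#'   `"max-feret"` (twice the maximal centre-to-contour radius).
#' @return Data frame `printlet_id` (component label), `x`, `y` (centroid,
#'   mm), `diameter` (mm), `circularity`, `accuracy` (%), `edge_defect`.
#'   Empty (with a warning) if no component survives.
#' @export
measure_printlets <- function(image, pixel_scale, design_diameter = 12,
                              threshold = "otsu", min_area_mm2 = 4,
                              circ_min = 0.85,
                              diameter_method = c("equivalent-circle",
                                                  "max-feret")) {
  diameter_method <- match.arg(diameter_method)
  if (inherits(image, "batch_image")) {
    if (missing(pixel_scale)) pixel_scale <- image$pixel_scale
    image <- image$image
  }
  check_positive(pixel_scale, "pixel_scale")
  thr <- if (identical(threshold, "otsu"))
    EBImage::otsu(EBImage::Image(image), range = c(0, 1)) else threshold
  mask <- EBImage::Image(image > thr)
  lab <- EBImage::bwlabel(mask)
  nlab <- max(lab)
  if (nlab == 0) {
    warning("no printlets found in image")
    return(data.frame(printlet_id = integer(0), x = numeric(0), y = numeric(0),
                      diameter = numeric(0), circularity = numeric(0),
                      accuracy = numeric(0), edge_defect = logical(0)))
  }
  labm <- EBImage::imageData(lab)
  areas <- tabulate(labm[labm > 0], nbins = nlab)
  min_px <- min_area_mm2 * pixel_scale^2
  keep <- which(areas >= min_px)
  if (!length(keep)) {
    warning("no printlets found in image")
    return(data.frame(printlet_id = integer(0), x = numeric(0), y = numeric(0),
                      diameter = numeric(0), circularity = numeric(0),
                      accuracy = numeric(0), edge_defect = logical(0)))
  }
  contours <- EBImage::ocontour(lab)
  rows <- lapply(keep, function(l) {
    px <- which(labm == l, arr.ind = TRUE)
    area <- nrow(px)
    cy <- mean(px[, 1]); cx <- mean(px[, 2])  # matrix rows are y
    ct <- contours[[l]]
    dct <- rbind(diff(ct), ct[1, ] - ct[nrow(ct), ])
    perim <- sum(sqrt(rowSums(dct^2)))
    dia_px <- switch(diameter_method,
      "equivalent-circle" = 2 * sqrt(area / pi),
      "max-feret" = 2 * max(sqrt((ct[, 1] - cy)^2 + (ct[, 2] - cx)^2)))
    dia <- dia_px / pixel_scale
    circ <- if (perim > 0) 4 * pi * area / perim^2 else NA_real_
    data.frame(printlet_id = l, x = cx / pixel_scale, y = cy / pixel_scale,
               diameter = dia, circularity = circ,
               accuracy = 100 * (1 - abs(dia - design_diameter) /
                                   design_diameter),
               edge_defect = is.na(circ) || circ < circ_min)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired regression comparison between two instruments
#'
#' For each parameter, ordinary least squares of instrument B on
#' instrument A over rows matched by key columns, with the Pearson
#' correlation and its two-sided t-test p-value.
#'
#' @param values_a,values_b Data frames sharing the key columns and the
#'   parameter columns.
#' @param parameters Character vector of parameter column names.
#' @param keys Key columns matched across the two tables.
#' @return Data frame `parameter`, `slope`, `intercept`, `pearson_r`,
#'   `p_value`, `n`, `degenerate` (zero variance in either column).
#' @export
#' @examples
#' a <- data.frame(k = 1:5, v = c(1, 2, 3, 4, 5))
#' b <- data.frame(k = 1:5, v = c(1.1, 1.9, 3.2, 3.8, 5.1))
#' compare_instruments(a, b, "v", keys = "k")
compare_instruments <- function(values_a, values_b, parameters,
                                keys = c("formulation", "speed_mm_s")) {
  keys <- intersect(keys, intersect(names(values_a), names(values_b)))
  if (!length(keys)) stopf("no shared key columns between the two tables")
  ka <- do.call(paste, c(values_a[keys], sep = "\r"))
  kb <- do.call(paste, c(values_b[keys], sep = "\r"))
  unmatched <- c(setdiff(ka, kb), setdiff(kb, ka))
  if (length(unmatched))
    stopf("unmatched row keys: %s",
          paste(gsub("\r", "/", unmatched), collapse = ", "))
  m <- match(ka, kb)
  rows <- lapply(parameters, function(p) {
    if (!p %in% names(values_a) || !p %in% names(values_b))
      stopf("parameter `%s` missing from one of the tables", p)
    xa <- values_a[[p]]
    xb <- values_b[[p]][m]
    ok <- complete.cases(xa, xb)
    xa <- xa[ok]; xb <- xb[ok]
    n <- length(xa)
    if (n < 3) stopf("parameter `%s`: need at least 3 matched pairs", p)
    if (sd(xa) == 0 || sd(xb) == 0)
      return(data.frame(parameter = p, slope = NA_real_, intercept = NA_real_,
                        pearson_r = NA_real_, p_value = NA_real_, n = n,
                        degenerate = TRUE))
    fit <- lm(xb ~ xa)
    ct <- cor.test(xa, xb)
    data.frame(parameter = p, slope = unname(coef(fit)[2]),
               intercept = unname(coef(fit)[1]),
               pearson_r = unname(ct$estimate), p_value = ct$p.value, n = n,
               degenerate = FALSE)
  })
  do.call(rbind, rows)
}

#' Speed-effect ANOVA, Tukey HSD and MANOVA
#'
#' One-way ANOVA per response, Tukey honest-significant-difference
#' pairwise comparisons (family level 0.05), and the multivariate tests
#' (Wilks' lambda, Pillai's trace, Roy's greatest root) over all
#' responses jointly.
#'
#' @param records Data frame of observations.
#' @param responses Character vector of response column names.
#' @param factor_col Grouping column name.
#' @return List `univariate` (data frame `response`, `F`, `p`), `tukey`
#'   (named list of pairwise tables: `diff`, lwr/upr, `p_adj`),
#'   `multivariate` (data frame `test`, `statistic`, `F`, `p`; `NULL`
#'   with `multivariate_available = FALSE` when the within-group
#'   cross-product matrix is singular).
#' @export
speed_effect_tests <- function(records, responses, factor_col = "assigned_speed") {
  if (!factor_col %in% names(records)) stopf("no column `%s`", factor_col)
  g <- factor(records[[factor_col]])
  if (nlevels(g) < 2) stopf("need at least 2 factor levels")
  if (any(table(g) < 2)) stopf("need at least 2 observations per level")
  uni <- lapply(responses, function(rsp) {
    fit <- aov(records[[rsp]] ~ g)
    s <- summary(fit)[[1]]
    data.frame(response = rsp, F = s$`F value`[1], p = s$`Pr(>F)`[1])
  })
  tk <- lapply(responses, function(rsp) {
    as.data.frame(TukeyHSD(aov(records[[rsp]] ~ g), conf.level = 0.95)$g)
  })
  names(tk) <- responses
  multiv <- NULL
  ok <- TRUE
  if (length(responses) == 1L) {
    # one response: the multivariate statistics collapse onto the ANOVA
    # sums of squares (Wilks = SSW/(SSB+SSW), Pillai = 1 - Wilks,
    # Roy = SSB/SSW), all sharing the ANOVA F and p
    y <- records[[responses]]
    ssb <- sum(tapply(y, g, function(v)
      length(v) * (mean(v) - mean(y))^2))
    ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
    if (ssw <= 0) {
      ok <- FALSE
    } else {
      multiv <- data.frame(test = c("Wilks", "Pillai", "Roy"),
                           statistic = c(ssw / (ssb + ssw),
                                         ssb / (ssb + ssw), ssb / ssw),
                           F = rep(uni[[1]]$F, 3), p = rep(uni[[1]]$p, 3))
    }
  } else {
    Y <- as.matrix(records[responses])
    multiv <- tryCatch({
      fit <- manova(Y ~ g)
      res <- do.call(rbind, lapply(c("Wilks", "Pillai", "Roy"), function(tst) {
        s <- summary(fit, test = tst)$stats
        data.frame(test = tst, statistic = s[1, 2], F = s[1, 3],
                   p = s[1, 6])
      }))
      if (any(!is.finite(res$statistic))) stop("singular within matrix")
      res
    }, error = function(e) { ok <<- FALSE; NULL })
  }
  list(univariate = do.call(rbind, uni), tukey = tk, multivariate = multiv,
       multivariate_available = ok && !is.null(multiv))
}
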