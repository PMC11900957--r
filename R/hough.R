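# Circle detection via the Hough transform: voting in (a, b, r) parameter
# space over edge pixels, peak identification above a support threshold, and
# non-maximum suppression. Used to localize the pupil and the iris (limbal
# circle) from segmentation-mask boundaries or image edges.

#' Describe one detected circle
#'
#' @param center_x,center_y circle center, 0-based pixel coordinates.
#' @param radius radius in pixels, positive.
#' @param support accumulator votes backing the detection (`NA` for circles
#'   known by construction).
#' @param fallback logical; `TRUE` when the circle was not detected but
#'   filled in by a fallback rule (see [locate_pupil_iris()]).
#' @return object of class `detected_circle`.
#' @export
detected_circle <- function(center_x, center_y, radius, support = NA_real_,
                            fallback = FALSE) {
  if (radius <= 0)
    cm_stop("radius must be positive", "spec_validation_error")
  structure(list(center_x = as.numeric(center_x),
                 center_y = as.numeric(center_y),
                 radius = as.numeric(radius),
                 support = as.numeric(support),
                 fallback = isTRUE(fallback)),
            class = "detected_circle")
}

#' @export
print.detected_circle <- function(x, ...) {
  cat(sprintf("<circle center=(%.1f, %.1f) r=%.1f support=%s%s>\n",
              x$center_x, x$center_y, x$radius,
              ifelse(is.na(x$support), "-", format(x$support)),
              if (x$fallback) " fallback" else ""))
  invisible(x)
}

#' Hough transform configuration
#'
#' Numeric parameters of circle detection. `radius_min`/`radius_max` left
#' `NULL` are resolved against the raster at call time as `0.05` and `0.45`
#' of the smaller image side. `peak_min_support` left `NULL` becomes a
#' per-radius threshold of `min_support_frac` times the candidate circle's
#' circumference `2*pi*r` (a peak must collect votes from at least that
#' fraction of a full circle's worth of edge pixels).
#'
#' @param radius_min,radius_max candidate radius range, pixels.
#' @param radius_step spacing of the radius grid, pixels.
#' @param theta_step angular step in degrees; must divide 360.
#' @param edge_low,edge_high gradient thresholds forwarded to
#'   [detect_edges()] when detection runs on a grayscale image.
#' @param peak_min_support absolute vote threshold; overrides
#'   `min_support_frac` when given.
#' @param min_support_frac fraction of the candidate circumference required
#'   as support.
#' @param nms_min_separation non-maximum suppression radius: a candidate is
#'   suppressed when a stronger accepted peak lies within this distance in
#'   both center and radius.
#' @return object of class `hough_config`.
#' @export
hough_config <- function(radius_min = NULL, radius_max = NULL,
                         radius_step = 1, theta_step = 1,
                         edge_low = NULL, edge_high = NULL,
                         peak_min_support = NULL, min_support_frac = 0.25,
                         nms_min_separation = 10) {
  if (360 %% theta_step != 0)
    cm_stop("theta_step must divide 360", "spec_validation_error")
  if (radius_step <= 0)
    cm_stop("radius_step must be positive", "spec_validation_error")
  if (!is.null(radius_min) && !is.null(radius_max) &&
      (radius_min <= 0 || radius_min >= radius_max))
    cm_stop("need 0 < radius_min < radius_max", "spec_validation_error")
  structure(list(radius_min = radius_min, radius_max = radius_max,
                 radius_step = radius_step, theta_step = theta_step,
                 edge_low = edge_low, edge_high = edge_high,
                 peak_min_support = peak_min_support,
                 min_support_frac = min_support_frac,
                 nms_min_separation = nms_min_separation),
            class = "hough_config")
}

resolve_radii <- function(config, shape) {
  s <- min(shape)
  rmin <- if (is.null(config$radius_min)) max(2, round(0.05 * s)) else config$radius_min
  rmax <- if (is.null(config$radius_max)) 0.45 * s else config$radius_max
  if (rmin >= rmax)
    cm_stop("resolved radius range is empty", "spec_validation_error")
  seq(rmin, rmax, by = config$radius_step)
}

#' Detect circles in an edge raster
#'
#' Casts one vote per (edge pixel, radius, theta) at the candidate center
#' `a = x - r*cos(theta)`, `b = y - r*sin(theta)` with theta on a regular
#' grid over `[0, 360)` degrees; each edge pixel contributes at most one
#' vote per cell and radius. Cell support is then pooled over adjacent
#' radius-grid cells (a circle whose radius falls midway between two grid
#' values splits its votes between them), cells meeting the threshold are
#' collected, ordered by support (ties broken by smaller radius, then
#' smaller b, then smaller a), and reduced by greedy non-maximum
#' suppression.
#'
#' @param edges logical matrix of edge pixels (see [detect_edges()]).
#' @param config a [hough_config()].
#' @return data frame with columns `center_x`, `center_y`, `radius`,
#'   `support`, sorted by decreasing support; zero rows when there are no
#'   edge pixels or no peak reaches the threshold.
#' @export
hough_circles <- function(edges, config = hough_config()) {
  if (!is.matrix(edges))
    cm_stop("edges must be a logical matrix", "shape_mismatch_error")
  edges <- edges != 0
  empty <- data.frame(center_x = numeric(0), center_y = numeric(0),
                      radius = numeric(0), support = numeric(0))
  if (!any(edges)) return(empty)

  h <- nrow(edges); w <- ncol(edges)
  idx <- which(edges)
  ex <- as.integer((idx - 1) %/% h)  # column index -> x
  ey <- as.integer((idx - 1) %% h)   # row index -> y
  radii <- resolve_radii(config, c(h, w))
  n_theta <- as.integer(360 / config$theta_step)

  acc <- hough_accumulate_cpp(ex, ey, radii, n_theta, w, h)

  # a circle whose true center or radius falls between accumulator cells
  # splits its votes across neighbours; pool each cell with its 3x3x3
  # neighbourhood so peak support reflects the whole boundary
  nr <- length(radii)
  pooled <- hough_pool_cpp(acc, w, h, nr)

  # support at a true center scales with the number of boundary pixels on
  # the circle, i.e. with the circumference 2*pi*r
  thr <- if (is.null(config$peak_min_support))
    config$min_support_frac * 2 * pi * radii
  else rep(config$peak_min_support, nr)

  cand <- which(pooled >= rep(thr, each = as.numeric(w) * h))
  if (!length(cand)) return(empty)
  ai <- arrayInd(cand, dim(pooled))
  peaks <- data.frame(center_x = ai[, 1] - 1, center_y = ai[, 2] - 1,
                      radius = radii[ai[, 3]], support = as.numeric(pooled[cand]))
  ord <- order(-peaks$support, peaks$radius, peaks$center_y, peaks$center_x)
  peaks <- peaks[ord, , drop = FALSE]
  if (nrow(peaks) > 5000) peaks <- peaks[1:5000, , drop = FALSE]

  sep <- config$nms_min_separation
  kept <- integer(0)
  for (i in seq_len(nrow(peaks))) {
    if (!length(kept)) { kept <- i; next }
    dc <- sqrt((peaks$center_x[kept] - peaks$center_x[i])^2 +
               (peaks$center_y[kept] - peaks$center_y[i])^2)
    dr <- abs(peaks$radius[kept] - peaks$radius[i])
    if (!any(dc < sep & dr < sep)) kept <- c(kept, i)
  }
  out <- peaks[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Localize the pupil and the iris from segmentation masks
#'
#' Runs the Hough transform on the boundary pixels of the visible-iris mask
#' (searching the configured radius range) to find the limbal circle, then on
#' the visible-pupil boundary over radii `[0.15, 0.85]` of the found iris
#' radius, keeping the best-supported pupil candidate whose center lies
#' inside the iris circle. Boundary pixels that coincide with the exposed-eye
#' (lid margin) boundary are excluded from both edge sets, so the circles are
#' fit to the limbal and pupillary arcs rather than to lid margins. When no pupil circle is found (e.g. the lid covers
#' the pupil) the pupil falls back to the iris center at
#' `pupil_fallback_ratio` times the iris radius and is flagged.
#'
#' @param masks a [seg_masks()] object.
#' @param config a [hough_config()].
#' @param pupil_fallback_ratio pupil/iris radius ratio used by the fallback.
#' @return list with elements `pupil` and `iris`, both [detected_circle()];
#'   `pupil$fallback` records whether the fallback rule fired.
#' @export
locate_pupil_iris <- function(masks, config = hough_config(),
                              pupil_fallback_ratio = 0.4) {
  stopifnot(inherits(masks, "seg_masks"))
  if (!any(masks$visible_iris))
    cm_stop("visible_iris mask is empty: no iris to locate", "no_iris_error")

  # Where a lid crosses the iris, the visible-iris boundary contains the lid
  # margin as well as the limbal arc; the margin pixels coincide with the
  # exposed-eye (aperture) boundary, so subtract that band and fit the
  # circle to the surviving limbal arc only.
  lid_band <- detect_edges(masks$exposed_eye)
  iris_edges <- detect_edges(masks$visible_iris) & !lid_band
  if (!any(iris_edges)) iris_edges <- detect_edges(masks$visible_iris)

  iris_peaks <- hough_circles(iris_edges, config)
  if (!nrow(iris_peaks))
    cm_stop("no iris-scale circle found in the visible_iris boundary",
            "no_iris_error")
  ib <- iris_peaks[1, ]
  iris <- detected_circle(ib$center_x, ib$center_y, ib$radius, ib$support)

  pupil <- NULL
  if (any(masks$visible_pupil)) {
    pcfg <- config
    pcfg$radius_min <- max(2, 0.15 * iris$radius)
    pcfg$radius_max <- 0.85 * iris$radius
    pupil_edges <- detect_edges(masks$visible_pupil) & !lid_band
    if (!any(pupil_edges)) pupil_edges <- detect_edges(masks$visible_pupil)
    pupil_peaks <- hough_circles(pupil_edges, pcfg)
    if (nrow(pupil_peaks)) {
      inside <- (pupil_peaks$center_x - iris$center_x)^2 +
        (pupil_peaks$center_y - iris$center_y)^2 < iris$radius^2
      pupil_peaks <- pupil_peaks[inside & pupil_peaks$radius < iris$radius, ,
                                 drop = FALSE]
      if (nrow(pupil_peaks)) {
        pb <- pupil_peaks[1, ]
        pupil <- detected_circle(pb$center_x, pb$center_y, pb$radius, pb$support)
      }
    }
  }
  if (is.null(pupil))
    pupil <- detected_circle(iris$center_x, iris$center_y,
                             pupil_fallback_ratio * iris$radius,
                             fallback = TRUE)
  list(pupil = pupil, iris = iris)
}
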