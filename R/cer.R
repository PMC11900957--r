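# CER core: full-iris Boolean disc, logical AND with the exposed-eye mask,
# pixel-count ratio x 100, and pixel-to-mm calibration from the interlimbal
# distance.

#' Full-iris disc as a Boolean mask
#'
#' Reconstructs the complete limbal disc from a detected iris circle: pixel
#' (x, y) is `TRUE` iff `(x - cx)^2 + (y - cy)^2 <= r^2` at the pixel
#' center, regardless of lid occlusion.
#'
#' @param iris a [detected_circle()].
#' @param shape `c(height, width)` of the target raster.
#' @return logical matrix.
#' @export
full_iris_mask <- function(iris, shape) {
  stopifnot(inherits(iris, "detected_circle"))
  m <- disc_mask(shape, iris$center_x, iris$center_y, iris$radius)
  if (!any(m))
    cm_stop("iris disc lies entirely outside the image", "empty_mask_error")
  m
}

#' Compute the corneal exposure ratio from masks and an iris circle
#'
#' The cornea mask is the logical AND of the full-iris disc and the
#' exposed-eye mask; the CER is 100 times the ratio of non-zero cornea
#' pixels to non-zero full-iris pixels. The denominator is the whole limbal
#' disc including the pupil region (the cornea overlies both iris and
#' pupil), and pupil pixels inside the aperture count as exposed cornea.
#'
#' @param masks a [seg_masks()] object.
#' @param iris the limbal circle, a [detected_circle()].
#' @param pupil optional pupil circle, carried through to the result.
#' @param mm_per_px optional pixel scale, carried through to the result.
#' @return object of class `cer_result` with fields `exposed_cornea_px`,
#'   `full_iris_px`, `cer_percent` (full precision; printed to 2 decimals),
#'   `iris_circle`, `pupil_circle`, `mm_per_px`.
#' @export
compute_cer <- function(masks, iris, pupil = NULL, mm_per_px = NULL) {
  stopifnot(inherits(masks, "seg_masks"))
  full <- full_iris_mask(iris, masks$shape)
  n_full <- sum(full)
  if (n_full == 0)
    cm_stop("full iris mask has zero pixels", "empty_mask_error")
  cornea <- full & masks$exposed_eye
  n_exposed <- sum(cornea)
  structure(list(exposed_cornea_px = as.integer(n_exposed),
                 full_iris_px = as.integer(n_full),
                 cer_percent = 100 * n_exposed / n_full,
                 iris_circle = iris, pupil_circle = pupil,
                 mm_per_px = mm_per_px),
            class = "cer_result")
}

#' @export
print.cer_result <- function(x, ...) {
  cat(sprintf("CER: %.2f%%  (exposed cornea %d px / full iris %d px)\n",
              x$cer_percent, x$exposed_cornea_px, x$full_iris_px))
  cat(sprintf("  iris: center (%.1f, %.1f), radius %.1f px",
              x$iris_circle$center_x, x$iris_circle$center_y,
              x$iris_circle$radius))
  if (!is.null(x$mm_per_px))
    cat(sprintf("  [%.4f mm/px; iris diameter %.2f mm]",
                x$mm_per_px, 2 * x$iris_circle$radius * x$mm_per_px))
  cat("\n")
  if (!is.null(x$pupil_circle) && x$pupil_circle$fallback)
    cat("  note: pupil not detected; fallback pupil in use\n")
  invisible(x)
}

#' Pixel-to-millimetre calibration from the interlimbal distance
#'
#' Converts pixel measurements to millimetres using the horizontal
#' white-to-white corneal diameter (interlimbal distance) as the anatomical
#' reference: `mm_per_px = interlimbal_mm / (2 * iris radius in pixels)`.
#' The default reference is 11.7 mm.
#'
#' @param iris a [detected_circle()] for the limbal circle, or a numeric
#'   radius in pixels.
#' @param interlimbal_mm reference corneal diameter in millimetres.
#' @return object of class `cer_calibration` with `interlimbal_mm` and
#'   `mm_per_px`.
#' @examples
#' calibrate(detected_circle(0, 0, 117))$mm_per_px  # 0.05
#' @export
calibrate <- function(iris, interlimbal_mm = 11.7) {
  r <- if (inherits(iris, "detected_circle")) iris$radius else as.numeric(iris)
  if (is.na(r) || r <= 0)
    cm_stop("iris radius must be positive for calibration",
            "spec_validation_error")
  if (interlimbal_mm <= 0)
    cm_stop("interlimbal_mm must be positive", "spec_validation_error")
  structure(list(interlimbal_mm = interlimbal_mm,
                 mm_per_px = interlimbal_mm / (2 * r)),
            class = "cer_calibration")
}

#' Measure the corneal exposure ratio of one eye
#'
#' Runs the full measurement pipeline: segmentation (when given an image
#' rather than masks), pupil/iris localization by the Hough transform on the
#' mask boundaries, full-iris disc reconstruction, Boolean intersection with
#' the exposed-eye mask, and the pixel-count ratio. Deterministic: identical
#' input and configuration give a bit-identical result.
#'
#' @param x either a single-channel image matrix or a [seg_masks()] object.
#' @param config a [hough_config()].
#' @param palette palette for [segment_reference()] when `x` is an image.
#' @param interlimbal_mm reference diameter for calibration; `NULL` skips
#'   calibration.
#' @return a `cer_result` (see [compute_cer()]).
#' @export
measure_eye <- function(x, config = hough_config(),
                        palette = default_palette(), interlimbal_mm = 11.7) {
  masks <- if (inherits(x, "seg_masks")) x else {
    if (!is.matrix(x))
      cm_stop("measure_eye [segmentation]: input must be an image matrix or seg_masks",
              "shape_mismatch_error")
    segment_reference(x, palette)
  }
  circles <- locate_pupil_iris(masks, config)
  mmpp <- if (is.null(interlimbal_mm)) NULL
          else calibrate(circles$iris, interlimbal_mm)$mm_per_px
  compute_cer(masks, circles$iris, pupil = circles$pupil, mm_per_px = mmpp)
}
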