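# Synthetic eye generator: parametric frontal-view eye rasters with exact
# ground-truth masks, so every downstream stage (segmentation, circle
# detection, CER) can be tested against analytically known answers.

#' Default grayscale palette for synthetic eyes
#'
#' Nominal 8-bit intensities for the four painted classes. The minimum gap
#' between any two classes is 70 intensity units; additive noise in
#' [generate_eye()] is clamped below half that gap so nearest-class
#' relabeling recovers the painted classes exactly.
#'
#' @return named numeric vector with entries `pupil`, `iris`, `skin`,
#'   `sclera`.
#' @export
default_palette <- function() {
  c(pupil = 20, iris = 90, skin = 160, sclera = 235)
}

#' Specify a synthetic eye
#'
#' Builds the parametric description of one synthetic eye: a circular iris
#' disc with a concentric pupil, and a palpebral-fissure aperture bounded by
#' two parabolic lid curves. Lid curves are quadratics in the 0-based pixel
#' coordinate x, `y(x) = c0 + c1*x + c2*x^2` (y increases downward): the
#' upper lid opens downward (`c2 > 0`, lowest at its apex), the lower lid
#' opens upward. The aperture is the set of pixels with
#' `y_upper(x) <= y <= y_lower(x)`.
#'
#' @param image_width,image_height raster size in pixels.
#' @param iris_center numeric `c(x, y)`, 0-based pixel coordinates.
#' @param iris_radius iris (limbal) radius in pixels; the disc must lie fully
#'   inside the image.
#' @param pupil_radius pupil radius in pixels, strictly less than
#'   `iris_radius`; the pupil is concentric with the iris.
#' @param upper_lid,lower_lid numeric coefficient vectors `c(c0, c1, c2)` of
#'   the two lid curves.
#' @param palette named intensities for `pupil`, `iris`, `skin`, `sclera`;
#'   see [default_palette()].
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   applied to the rendered image (masks are always noise-free). Noise is
#'   clamped to less than half the minimum palette gap.
#' @param seed integer seed used for the noise only.
#' @return an object of class `eye_spec`.
#' @seealso [generate_eye()], [lid_parabola()]
#' @export
eye_spec <- function(image_width = 512, image_height = 512,
                     iris_center = c(image_width / 2, image_height / 2),
                     iris_radius = 0.25 * min(image_width, image_height),
                     pupil_radius = 0.4 * iris_radius,
                     upper_lid = lid_parabola(iris_center[1],
                                              iris_center[2] - iris_radius - 2,
                                              0.27 / iris_radius),
                     lower_lid = lid_parabola(iris_center[1],
                                              iris_center[2] + iris_radius + 2,
                                              -0.12 / iris_radius),
                     palette = default_palette(),
                     noise_sd = 0, seed = 1L) {
  spec <- structure(list(
    image_width = as.integer(image_width),
    image_height = as.integer(image_height),
    iris_center = as.numeric(iris_center),
    iris_radius = as.numeric(iris_radius),
    pupil_radius = as.numeric(pupil_radius),
    upper_lid = as.numeric(upper_lid),
    lower_lid = as.numeric(lower_lid),
    palette = palette,
    noise_sd = as.numeric(noise_sd),
    seed = as.integer(seed)
  ), class = "eye_spec")
  validate_eye_spec(spec)
  spec
}

#' Lid parabola from apex and curvature
#'
#' Convenience constructor for lid-curve coefficients: a parabola with vertex
#' at `(apex_x, apex_y)` and leading coefficient `curvature`, returned as
#' `c(c0, c1, c2)` of `y(x) = c0 + c1*x + c2*x^2`. Positive curvature opens
#' downward in image coordinates (an upper lid), negative opens upward (a
#' lower lid).
#'
#' @param apex_x,apex_y vertex position, 0-based pixels.
#' @param curvature leading coefficient, 1/pixels.
#' @return numeric vector `c(c0, c1, c2)`.
#' @export
lid_parabola <- function(apex_x, apex_y, curvature) {
  c(apex_y + curvature * apex_x^2, -2 * curvature * apex_x, curvature)
}

lid_eval <- function(coef, x) coef[1] + coef[2] * x + coef[3] * x^2

validate_eye_spec <- function(spec) {
  w <- spec$image_width; h <- spec$image_height
  cx <- spec$iris_center[1]; cy <- spec$iris_center[2]; r <- spec$iris_radius
  if (w < 1 || h < 1)
    cm_stop("image dimensions must be positive", "spec_validation_error")
  if (r <= 0)
    cm_stop("iris_radius must be positive", "spec_validation_error")
  if (cx - r < 0 || cx + r > w - 1 || cy - r < 0 || cy + r > h - 1)
    cm_stop("iris disc must lie fully inside the image bounds",
            "spec_validation_error")
  if (spec$pupil_radius <= 0 || spec$pupil_radius >= r)
    cm_stop("pupil_radius must be positive and smaller than iris_radius",
            "spec_validation_error")
  need <- c("pupil", "iris", "skin", "sclera")
  if (!all(need %in% names(spec$palette)))
    cm_stop("palette must name pupil, iris, skin and sclera intensities",
            "spec_validation_error")
  if (length(spec$upper_lid) != 3 || length(spec$lower_lid) != 3)
    cm_stop("lid curves must have 3 coefficients each", "spec_validation_error")
  invisible(spec)
}

aperture_mask <- function(spec) {
  h <- spec$image_height; w <- spec$image_width
  xs <- 0:(w - 1)
  yu <- lid_eval(spec$upper_lid, xs)
  yl <- lid_eval(spec$lower_lid, xs)
  g <- pixel_grid(c(h, w))
  YU <- matrix(yu, nrow = h, ncol = w, byrow = TRUE)
  YL <- matrix(yl, nrow = h, ncol = w, byrow = TRUE)
  g$y >= YU & g$y <= YL
}

#' Render a synthetic eye and its ground truth
#'
#' Rasterizes the eye by painting skin over the whole image, the aperture
#' interior as sclera, the visible iris (iris disc intersected with the
#' aperture) and finally the visible pupil. The ground-truth masks are the
#' exact painted regions, and the true CER is obtained by pixel counting on
#' them: 100 x (iris-disc pixels inside the aperture) / (iris-disc pixels).
#'
#' @param spec an [eye_spec()].
#' @return list with elements
#'   \describe{
#'     \item{image}{numeric matrix of intensities in `[0, 255]`.}
#'     \item{truth}{list with `masks` (a [seg_masks()] object),
#'       `true_cer_percent`, `true_circle` and `true_pupil`
#'       ([detected_circle()] descriptions of the generating circles).}
#'   }
#' @examples
#' eye <- generate_eye(eye_spec(image_width = 96, image_height = 96,
#'                              iris_radius = 24))
#' eye$truth$true_cer_percent
#' @export
generate_eye <- function(spec) {
  validate_eye_spec(spec)
  h <- spec$image_height; w <- spec$image_width
  cx <- spec$iris_center[1]; cy <- spec$iris_center[2]

  aperture <- aperture_mask(spec)
  iris_disc <- disc_mask(c(h, w), cx, cy, spec$iris_radius)
  pupil_disc <- disc_mask(c(h, w), cx, cy, spec$pupil_radius)

  visible_iris <- iris_disc & aperture
  visible_pupil <- pupil_disc & aperture
  sclera <- aperture & !iris_disc

  pal <- spec$palette
  img <- matrix(pal[["skin"]], h, w)
  img[sclera] <- pal[["sclera"]]
  img[visible_iris] <- pal[["iris"]]
  img[visible_pupil] <- pal[["pupil"]]

  if (spec$noise_sd > 0) {
    gap <- min(diff(sort(pal)))
    clamp <- gap / 2 - 1
    noise <- with_seed(spec$seed, rnorm(h * w, sd = spec$noise_sd))
    noise <- pmin(pmax(noise, -clamp), clamp)
    img <- img + matrix(noise, h, w)
    img <- pmin(pmax(img, 0), 255)
  }

  # visible iris and sclera partition the aperture, so the exposed-eye mask
  # (their union with the pupil) is the aperture itself
  masks <- seg_masks(visible_iris = visible_iris,
                     visible_pupil = visible_pupil,
                     sclera = sclera,
                     exposed_eye = aperture)
  truth <- list(
    masks = masks,
    true_cer_percent = 100 * sum(visible_iris) / sum(iris_disc),
    true_circle = detected_circle(cx, cy, spec$iris_radius),
    true_pupil = detected_circle(cx, cy, spec$pupil_radius)
  )
  list(image = img, truth = truth)
}

#' Generate a synthetic cohort with graded lid droop
#'
#' Draws `n_eyes` synthetic eyes whose upper lid is lowered by a droop
#' sampled uniformly from `droop_range_mm`. At zero droop the upper-lid apex
#' sits 0.5 mm above the superior limbus and the lower lid 0.5 mm below the
#' inferior limbus, so the limbal disc is fully exposed (CER = 100); droop
#' lowers the upper lid by `droop_mm / mm_per_px` pixels. The pixel scale
#' defaults to the interlimbal calibration `11.7 mm / (2 * iris radius)`.
#' Iris center and radius receive small per-eye jitter so cohorts are not
#' collinear.
#'
#' @param n_eyes number of eyes, at least 1.
#' @param droop_range_mm numeric `c(lo, hi)` in millimetres, `0 <= lo <= hi`;
#'   the default spans fully open through severe ptosis.
#' @param image_size raster side in pixels (square images).
#' @param mm_per_px pixel scale; default derived from the 11.7 mm interlimbal
#'   distance and the nominal iris radius.
#' @param noise_sd image noise passed to [eye_spec()].
#' @param seed integer; the whole cohort is deterministic given `seed`.
#' @return list of `n_eyes` records, each with `eye_id`, `droop_mm`, `spec`,
#'   `image`, `truth`.
#' @export
generate_cohort <- function(n_eyes, droop_range_mm = c(0, 8),
                            image_size = 512, mm_per_px = NULL,
                            noise_sd = 4, seed = 1L) {
  if (n_eyes < 1)
    cm_stop("n_eyes must be at least 1", "spec_validation_error")
  if (length(droop_range_mm) != 2 || any(is.na(droop_range_mm)) ||
      droop_range_mm[1] > droop_range_mm[2] || droop_range_mm[1] < 0 ||
      droop_range_mm[2] > 12)
    cm_stop("droop_range_mm must be an interval within [0, 12] mm",
            "spec_validation_error")

  r0 <- 0.25 * image_size
  if (is.null(mm_per_px)) mm_per_px <- 11.7 / (2 * r0)

  draws <- with_seed(as.integer(seed), {
    list(droop = runif(n_eyes, droop_range_mm[1], droop_range_mm[2]),
         jx = runif(n_eyes, -0.02, 0.02) * image_size,
         jy = runif(n_eyes, -0.02, 0.02) * image_size,
         jr = runif(n_eyes, 0.92, 1.08),
         jp = runif(n_eyes, 0.35, 0.45),
         seeds = sample.int(.Machine$integer.max - 1L, n_eyes))
  })

  lapply(seq_len(n_eyes), function(i) {
    r <- r0 * draws$jr[i]
    cx <- image_size / 2 + draws$jx[i]
    cy <- image_size / 2 + draws$jy[i]
    droop_px <- draws$droop[i] / mm_per_px
    margin_px <- 0.5 / mm_per_px
    spec <- eye_spec(
      image_width = image_size, image_height = image_size,
      iris_center = c(cx, cy), iris_radius = r,
      pupil_radius = draws$jp[i] * r,
      upper_lid = lid_parabola(cx, cy - r - margin_px + droop_px, 0.27 / r),
      lower_lid = lid_parabola(cx, cy + r + margin_px, -0.12 / r),
      noise_sd = noise_sd, seed = draws$seeds[i]
    )
    eye <- generate_eye(spec)
    list(eye_id = sprintf("eye_%03d", i), droop_mm = draws$droop[i],
         mm_per_px = mm_per_px, spec = spec,
         image = eye$image, truth = eye$truth)
  })
}
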