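# Segmentation masks: the per-class binary rasters the CER pipeline consumes.
# A trained semantic-segmentation backend can be plugged in wherever a
# function EyeImage -> seg_masks is accepted; the reference segmenter here is
# a nearest-palette-class labeler sufficient for synthetic images.

#' Per-class segmentation masks for one eye image
#'
#' Container for the four binary rasters the pipeline uses: the visible iris
#' (including the pupil region), the visible pupil, the sclera (the white of
#' the eye inside the fissure), and the exposed-eye aperture. Invariants are
#' checked on construction: all rasters share one shape, the pupil mask is
#' contained in the iris mask, the aperture contains both the visible iris
#' and the sclera, and sclera and visible iris are disjoint.
#'
#' @param visible_iris,visible_pupil,sclera,exposed_eye logical (or 0/1)
#'   matrices of one common shape.
#' @return object of class `seg_masks`: list of four logical matrices plus
#'   `shape = c(height, width)`.
#' @export
seg_masks <- function(visible_iris, visible_pupil, sclera, exposed_eye) {
  ms <- list(visible_iris = visible_iris, visible_pupil = visible_pupil,
             sclera = sclera, exposed_eye = exposed_eye)
  ms <- lapply(ms, function(m) {
    if (!is.matrix(m))
      cm_stop("masks must be matrices", "shape_mismatch_error")
    m != 0
  })
  check_same_shape(lapply(ms, dim), "seg_masks")
  if (any(ms$visible_pupil & !ms$visible_iris))
    cm_stop("containment violation: visible_pupil must be a subset of visible_iris",
            "containment_violation_error")
  if (any(ms$visible_iris & !ms$exposed_eye) || any(ms$sclera & !ms$exposed_eye))
    cm_stop("containment violation: exposed_eye must contain visible_iris and sclera",
            "containment_violation_error")
  if (any(ms$sclera & ms$visible_iris))
    cm_stop("containment violation: sclera and visible_iris must be disjoint",
            "containment_violation_error")
  structure(c(ms, list(shape = dim(ms$visible_iris))), class = "seg_masks")
}

#' @export
print.seg_masks <- function(x, ...) {
  cat(sprintf("<seg_masks %dx%d>  iris: %d px  pupil: %d px  sclera: %d px  aperture: %d px\n",
              x$shape[1], x$shape[2], sum(x$visible_iris), sum(x$visible_pupil),
              sum(x$sclera), sum(x$exposed_eye)))
  invisible(x)
}

#' Reference segmentation by nearest palette class
#'
#' Labels every pixel of a single-channel image with the nearest class of the
#' given intensity palette, then assembles [seg_masks()]: the visible iris is
#' the union of iris- and pupil-labeled pixels, and the exposed-eye aperture
#' is the union of all within-fissure classes (visible iris, pupil, sclera).
#' This is exact on noise-free synthetic images and on images whose noise
#' stays below half the minimum palette gap; it stands in for any semantic
#' segmentation backend producing the same mask contract.
#'
#' @param image numeric matrix of intensities.
#' @param palette named intensities (`pupil`, `iris`, `skin`, `sclera`).
#' @return a [seg_masks()] object.
#' @export
segment_reference <- function(image, palette = default_palette()) {
  if (!is.matrix(image))
    cm_stop("image must be a single-channel matrix", "shape_mismatch_error")
  need <- c("pupil", "iris", "skin", "sclera")
  if (!all(need %in% names(palette)))
    cm_stop("palette must name pupil, iris, skin and sclera intensities",
            "spec_validation_error")
  pal <- palette[need]
  # distance of every pixel to every class intensity; nearest class wins,
  # ties broken toward the darker class (palette order above)
  d <- vapply(pal, function(v) abs(as.vector(image) - v), numeric(length(image)))
  lab <- need[max.col(-d, ties.method = "first")]
  lab <- matrix(lab, nrow(image), ncol(image))
  pupil <- lab == "pupil"
  iris <- lab == "iris" | pupil
  sclera <- lab == "sclera"
  seg_masks(visible_iris = iris, visible_pupil = pupil, sclera = sclera,
            exposed_eye = iris | sclera)
}

mask_classes <- c("visible_iris", "visible_pupil", "sclera", "exposed_eye")

#' Write segmentation masks as single-channel PNG files
#'
#' One PNG per class, 0/255 encoded, named `<prefix>_<class>.png`.
#'
#' @param masks a [seg_masks()] object.
#' @param prefix path prefix (directory must exist).
#' @return named character vector of the four file paths, invisibly.
#' @export
write_masks <- function(masks, prefix) {
  stopifnot(inherits(masks, "seg_masks"))
  paths <- vapply(mask_classes, function(cl) {
    p <- paste0(prefix, "_", cl, ".png")
    png::writePNG(masks[[cl]] * 1, p)
    p
  }, character(1))
  invisible(paths)
}

#' Load segmentation masks from per-class PNG files
#'
#' Reads four aligned binary PNGs (0/255) and assembles an invariant-checked
#' [seg_masks()] object. Distinct validation errors are raised for a missing
#' class, non-binary pixel values, shape mismatches between classes, and
#' containment violations.
#'
#' @param paths named character vector or list with entries `visible_iris`,
#'   `visible_pupil`, `sclera`, `exposed_eye`.
#' @return a [seg_masks()] object.
#' @export
load_masks <- function(paths) {
  missing <- setdiff(mask_classes, names(paths))
  if (length(missing))
    cm_stop(paste("missing mask class(es):", paste(missing, collapse = ", ")),
            "missing_class_error")
  ms <- lapply(mask_classes, function(cl) {
    p <- paths[[cl]]
    if (!file.exists(p))
      cm_stop(paste("mask file does not exist:", p), "missing_class_error")
    v <- png::readPNG(p)
    if (length(dim(v)) == 3) v <- v[, , 1]
    iv <- round(v * 255)
    if (!all(iv %in% c(0, 255)))
      cm_stop(sprintf("mask %s is not binary (found value %d)", p,
                      setdiff(unique(as.vector(iv)), c(0, 255))[1]),
              "non_binary_error")
    iv == 255
  })
  names(ms) <- mask_classes
  check_same_shape(lapply(ms, dim), "load_masks")
  seg_masks(visible_iris = ms$visible_iris, visible_pupil = ms$visible_pupil,
            sclera = ms$sclera, exposed_eye = ms$exposed_eye)
}
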