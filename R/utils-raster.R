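# Raster conventions used throughout the package
# ------------------------------------------------
# An image or mask is a base-R matrix indexed [row, col] = [y + 1, x + 1]:
# 0-based pixel coordinates, origin at the top-left corner, x increasing to
# the right, y increasing downward. A pixel belongs to a region when its
# CENTER (the integer point (x, y)) satisfies the region's inequality; no
# partial-pixel weighting anywhere.

cm_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cermetrics_error")))
}

#' Coordinate grids for a raster shape
#'
#' Returns matrices `x` and `y` holding the 0-based pixel-center coordinates
#' of every pixel of a `shape = c(height, width)` raster.
#'
#' @param shape integer vector `c(height, width)`.
#' @return list with matrices `x` and `y`, each `height x width`.
#' @keywords internal
pixel_grid <- function(shape) {
  h <- shape[1]; w <- shape[2]
  list(
    x = matrix(rep(0:(w - 1), each = h), nrow = h, ncol = w),
    y = matrix(rep(0:(h - 1), times = w), nrow = h, ncol = w)
  )
}

#' Rasterize a disc as a logical mask
#'
#' Pixel (x, y) is `TRUE` iff (x - cx)^2 + (y - cy)^2 <= r^2 at the pixel
#' center.
#'
#' @param shape `c(height, width)`.
#' @param cx,cy disc center in 0-based pixel coordinates.
#' @param r disc radius in pixels.
#' @return logical matrix.
#' @keywords internal
disc_mask <- function(shape, cx, cy, r) {
  g <- pixel_grid(shape)
  (g$x - cx)^2 + (g$y - cy)^2 <= r^2
}

# Inner boundary of a binary mask: pixels in the mask with at least one
# 4-neighbour outside it (image border counts as outside).
mask_boundary <- function(mask) {
  mask <- mask != 0
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  up    <- pad[1:h,       2:(w + 1)]
  down  <- pad[3:(h + 2), 2:(w + 1)]
  left  <- pad[2:(h + 1), 1:w]
  right <- pad[2:(h + 1), 3:(w + 2)]
  mask & !(up & down & left & right)
}

# 3x3 binary dilation (used to grow the lid-margin band when subtracting it
# from limbal edge sets).
dilate3 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  out <- matrix(FALSE, h, w)
  for (dy in -1:1) for (dx in -1:1)
    out <- out | pad[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
  out
}

# Shared shape check with a classed error.
check_same_shape <- function(shapes, what) {
  ref <- shapes[[1]]
  for (s in shapes) {
    if (!identical(as.integer(s), as.integer(ref))) {
      cm_stop(sprintf("%s: rasters do not share one shape (%s vs %s)",
                      what, paste(ref, collapse = "x"),
                      paste(s, collapse = "x")),
              "shape_mismatch_error")
    }
  }
  invisible(ref)
}

# Evaluate noise reproducibly from a seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
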