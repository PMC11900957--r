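# Edge detection: the first stage of circle detection. Binary masks get an
# exact boundary extraction; grayscale images get Sobel gradient-magnitude
# thresholding with hysteresis, thresholds derived from the gradient
# magnitude range when not supplied.

sobel_magnitude <- function(img) {
  h <- nrow(img); w <- ncol(img)
  # replicate-pad by one pixel, then take the eight shifted copies
  pr <- img[c(1, 1:h, h), c(1, 1:w, w)]
  sh <- function(dy, dx) pr[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  sqrt(gx^2 + gy^2)
}

#' Detect edge pixels in an image or mask
#'
#' For a binary input (logical matrix, or numeric with only two values) the
#' edge set is the exact inner boundary of the foreground: every foreground
#' pixel with a 4-neighbour outside the foreground. For a grayscale image,
#' Sobel gradient magnitudes are thresholded with hysteresis: pixels at or
#' above `high` seed edges, pixels at or above `low` are kept when connected
#' to a seed. Default thresholds are 0.2 and 0.08 times the maximum gradient
#' magnitude.
#'
#' @param x single-channel raster (matrix); logical or binary inputs are
#'   treated as masks.
#' @param low,high hysteresis thresholds on the gradient magnitude; ignored
#'   for binary inputs.
#' @return logical matrix marking edge pixels.
#' @export
detect_edges <- function(x, low = NULL, high = NULL) {
  if (!is.matrix(x))
    cm_stop("detect_edges expects a single-channel matrix; convert multi-channel images first",
            "shape_mismatch_error")
  vals <- unique(as.vector(x))
  if (is.logical(x) || length(vals) <= 2) {
    if (length(vals) == 1) return(matrix(FALSE, nrow(x), ncol(x)))
    return(mask_boundary(x == max(vals)))
  }
  mag <- sobel_magnitude(x)
  if (all(mag == 0)) return(matrix(FALSE, nrow(x), ncol(x)))
  if (is.null(high)) high <- 0.2 * max(mag)
  if (is.null(low)) low <- 0.4 * high
  strong <- mag >= high
  weak <- mag >= low
  if (!any(strong)) return(matrix(FALSE, nrow(x), ncol(x)))
  # keep weak components that contain at least one strong pixel
  lab <- EBImage::bwlabel(weak)
  keep <- unique(lab[strong])
  weak & (lab %in% keep)
}
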