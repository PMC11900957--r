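# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the Hough oracle is a vectorized enumeration
# over every (edge pixel, radius, theta) triple, and the geometry oracles
# are closed-form areas.

# Exhaustive Hough accumulator: enumerate all (edge, radius, theta) votes,
# deduplicate multiple hits of one cell by the same edge pixel at one
# radius, tabulate, pool each cell with its 3x3x3 neighbourhood in
# (a, b, radius) (the package's declared selection rule), and return the
# argmax cell under the declared tie-break (support desc, then radius, then
# b, then a ascending).
hough_brute_top <- function(edges, radii, n_theta = 360L) {
  h <- nrow(edges); w <- ncol(edges)
  idx <- which(edges != 0)
  ex <- (idx - 1) %/% h
  ey <- (idx - 1) %% h
  theta <- 2 * pi * (0:(n_theta - 1)) / n_theta
  votes <- do.call(rbind, lapply(seq_along(radii), function(ri) {
    r <- radii[ri]
    a <- floor(outer(ex, r * cos(theta), `-`) + 0.5)
    b <- floor(outer(ey, r * sin(theta), `-`) + 0.5)
    pix <- row(a)
    keep <- a >= 0 & a < w & b >= 0 & b < h
    data.frame(pix = pix[keep], a = a[keep], b = b[keep], ri = ri)
  }))
  votes <- unique(votes)                       # one vote per pixel and cell
  cells <- aggregate(cbind(support = pix) ~ a + b + ri, data = votes, length)
  # each raw cell contributes to its full 3x3x3 neighbourhood
  shifts <- expand.grid(da = -1:1, db = -1:1, dr = -1:1)
  spread <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(s)
    transform(cells, a = a + shifts$da[s], b = b + shifts$db[s],
              ri = ri + shifts$dr[s])))
  spread <- spread[spread$ri >= 1 & spread$ri <= length(radii) &
                   spread$a >= 0 & spread$a < w &
                   spread$b >= 0 & spread$b < h, ]
  pooled <- aggregate(support ~ a + b + ri, data = spread, sum)
  pooled$r <- radii[pooled$ri]
  pooled[order(-pooled$support, pooled$r, pooled$b, pooled$a)[1],
         c("a", "b", "r", "support")]
}

# Edge raster of a circular arc: distinct rounded lattice points of the
# circle over the given angular window (degrees).
arc_edges <- function(shape, cx, cy, r, theta_deg = c(0, 360)) {
  th <- seq(theta_deg[1], theta_deg[2], by = 0.1) * pi / 180
  xs <- floor(cx + r * cos(th) + 0.5)
  ys <- floor(cy + r * sin(th) + 0.5)
  keep <- xs >= 0 & xs < shape[2] & ys >= 0 & ys < shape[1]
  m <- matrix(FALSE, shape[1], shape[2])
  m[cbind(ys[keep] + 1, xs[keep] + 1)] <- TRUE
  m
}

# Fraction of a disc of radius r lying in the half-plane y >= cy + d
# (circular-segment area), d in [-r, r].
segment_fraction <- function(d, r) {
  (r^2 * acos(d / r) - d * sqrt(r^2 - d^2)) / (pi * r^2)
}

# Half-plane exposure masks paired with a disc, as seg_masks: the aperture
# is the half-plane, the visible iris its intersection with the disc.
halfplane_masks <- function(shape, cx, cy, r, y_from) {
  g_y <- matrix(rep(0:(shape[1] - 1), times = shape[2]), shape[1], shape[2])
  g_x <- matrix(rep(0:(shape[2] - 1), each = shape[1]), shape[1], shape[2])
  aperture <- g_y >= y_from
  disc <- (g_x - cx)^2 + (g_y - cy)^2 <= r^2
  seg_masks(visible_iris = disc & aperture,
            visible_pupil = disc & aperture & ((g_x - cx)^2 + (g_y - cy)^2 <= (0.4 * r)^2),
            sclera = aperture & !disc,
            exposed_eye = aperture)
}

# Two-way mean squares for an n x 2 table, by explicit sums of squares.
ms_oracle <- function(a, b) {
  x <- cbind(a, b)
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  rowm <- rowMeans(x); colm <- colMeans(x)
  list(
    MSR = k * sum((rowm - grand)^2) / (n - 1),
    MSC = n * sum((colm - grand)^2) / (k - 1),
    MSE = sum((sweep(sweep(x, 1, rowm), 2, colm) + grand)^2) /
      ((n - 1) * (k - 1)),
    n = n, k = k
  )
}

# Small deterministic cohort used by several files (masks only, no Hough).
tiny_cohort <- function(n = 8, seed = 11, image_size = 96,
                        droop = c(0, 8), noise_sd = 0) {
  generate_cohort(n, droop_range_mm = droop, image_size = image_size,
                  noise_sd = noise_sd, seed = seed)
}
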