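# Edge detection and Hough circle recovery.

test_that("edge detection on masks returns the exact disc boundary", {
  disc <- generate_eye(eye_spec(image_width = 96, image_height = 96,
                                iris_radius = 24,
                                upper_lid = c(-10, 0, 0),
                                lower_lid = c(200, 0, 0)))
  ed <- detect_edges(disc$truth$masks$visible_iris)
  pts <- which(ed, arr.ind = TRUE)
  dist <- sqrt((pts[, 2] - 1 - 48)^2 + (pts[, 1] - 1 - 48)^2)
  expect_true(all(abs(dist - 24) <= 1))

  expect_equal(sum(detect_edges(matrix(7, 32, 32))), 0)
  expect_error(detect_edges(array(0, c(8, 8, 3))),
               class = "shape_mismatch_error")
})

test_that("image-based edges cover the limbus", {
  for (noise in c(0, 4)) {
    eye <- generate_eye(eye_spec(image_width = 128, image_height = 128,
                                 iris_radius = 32, noise_sd = noise, seed = 3))
    ed <- detect_edges(eye$image)
    g_x <- matrix(rep(0:127, each = 128), 128, 128)
    g_y <- matrix(rep(0:127, times = 128), 128, 128)
    disc <- (g_x - 64)^2 + (g_y - 64)^2 <= 32^2
    limbus <- detect_edges(disc) & eye$truth$masks$exposed_eye
    li <- which(limbus, arr.ind = TRUE)
    ei <- which(ed, arr.ind = TRUE)
    d2 <- outer(li[, 1], ei[, 1], "-")^2 + outer(li[, 2], ei[, 2], "-")^2
    coverage <- mean(apply(d2, 1, min) <= 2)
    expect_gte(coverage, 0.9)
  }
})

test_that("a perfect circle is recovered within one pixel", {
  edges <- arc_edges(c(128, 128), 64, 64, 30)
  top <- hough_circles(edges, hough_config(radius_min = 20, radius_max = 40))[1, ]
  expect_lte(abs(top$center_x - 64), 1)
  expect_lte(abs(top$center_y - 64), 1)
  expect_lte(abs(top$radius - 30), 1)
})

test_that("two concentric circles are both recovered", {
  edges <- arc_edges(c(128, 128), 60, 62, 15) | arc_edges(c(128, 128), 60, 62, 45)
  found <- hough_circles(edges, hough_config(radius_min = 8, radius_max = 55))
  expect_gte(nrow(found), 2)
  radii <- sort(found$radius[1:2])
  expect_lte(abs(radii[1] - 15), 1)
  expect_lte(abs(radii[2] - 45), 1)
  expect_true(all(abs(found$center_x[1:2] - 60) <= 1))
  expect_true(all(abs(found$center_y[1:2] - 62) <= 1))
})

test_that("top peak equals the exhaustive brute-force accumulator argmax", {
  radii <- seq(4, 12, by = 1)
  cfg <- hough_config(radius_min = 4, radius_max = 12, peak_min_support = 1)
  set.seed(17)
  for (rep in 1:20) {
    shape <- c(sample(16:32, 1), sample(16:32, 1))
    edges <- matrix(FALSE, shape[1], shape[2])
    edges[sample(length(edges), sample(10:30, 1))] <- TRUE
    top <- hough_circles(edges, cfg)[1, ]
    oracle <- hough_brute_top(edges, radii)
    expect_equal(top$center_x, oracle$a)
    expect_equal(top$center_y, oracle$b)
    expect_equal(top$radius, oracle$r)
    expect_equal(top$support, oracle$support)
  }
})

test_that("detection is translation-equivariant", {
  base <- arc_edges(c(100, 100), 40, 40, 12)
  cfg <- hough_config(radius_min = 8, radius_max = 16)
  top0 <- hough_circles(base, cfg)[1, ]
  shifted <- matrix(FALSE, 100, 100)
  pts <- which(base, arr.ind = TRUE)
  shifted[cbind(pts[, 1] + 20, pts[, 2] + 15)] <- TRUE
  top1 <- hough_circles(shifted, cfg)[1, ]
  expect_equal(top1$center_x, top0$center_x + 15)
  expect_equal(top1$center_y, top0$center_y + 20)
  expect_equal(top1$radius, top0$radius)
})

test_that("partial arcs of at least a third of the circle are recovered", {
  cfg <- hough_config(radius_min = 15, radius_max = 35)
  for (window in list(c(0, 120), c(90, 215), c(200, 330))) {
    edges <- arc_edges(c(96, 96), 47, 45, 25, theta_deg = window)
    top <- hough_circles(edges, cfg)[1, ]
    expect_lte(abs(top$center_x - 47), 2)
    expect_lte(abs(top$center_y - 45), 2)
    expect_lte(abs(top$radius - 25), 2)
  }
})

test_that("degenerate edge inputs give empty results, not errors", {
  none <- matrix(FALSE, 64, 64)
  expect_equal(nrow(hough_circles(none)), 0)
  sparse <- matrix(FALSE, 64, 64); sparse[30, 30] <- TRUE
  expect_equal(nrow(hough_circles(sparse, hough_config(radius_min = 10,
                                                       radius_max = 20))), 0)
})

test_that("pupil and iris are localized from masks", {
  # lids clear of the limbus: iris radius within 1 px of the spec
  open_eye <- generate_eye(eye_spec(image_width = 128, image_height = 128,
                                    iris_radius = 32, pupil_radius = 13))
  loc <- locate_pupil_iris(open_eye$truth$masks)
  expect_lte(abs(loc$iris$radius - 32), 1)
  expect_lte(abs(loc$iris$center_x - 64), 1)
  expect_lte(abs(loc$iris$center_y - 64), 1)
  expect_false(loc$pupil$fallback)
  expect_lte(abs(loc$pupil$radius - 13), 1)
  expect_lt(loc$pupil$radius, loc$iris$radius)

  # severe droop occluding the upper limbus: iris still within 2 px
  droop <- generate_eye(eye_spec(image_width = 128, image_height = 128,
                                 iris_center = c(64, 64), iris_radius = 32,
                                 upper_lid = lid_parabola(64, 64 + 8, 0.27 / 32),
                                 lower_lid = lid_parabola(64, 64 + 34, -0.12 / 32)))
  expect_lt(droop$truth$true_cer_percent, 45)
  loc <- locate_pupil_iris(droop$truth$masks)
  expect_lte(abs(loc$iris$radius - 32), 2)
  expect_lte(abs(loc$iris$center_x - 64), 2)
  expect_lte(abs(loc$iris$center_y - 64), 2)

  # absent pupil mask: fallback pupil at the configured ratio, flagged
  m <- open_eye$truth$masks
  no_pupil <- seg_masks(m$visible_iris, matrix(FALSE, 128, 128),
                        m$sclera, m$exposed_eye)
  loc <- locate_pupil_iris(no_pupil)
  expect_true(loc$pupil$fallback)
  expect_equal(loc$pupil$radius, 0.4 * loc$iris$radius)

  empty <- seg_masks(matrix(FALSE, 32, 32), matrix(FALSE, 32, 32),
                     matrix(FALSE, 32, 32), matrix(FALSE, 32, 32))
  expect_error(locate_pupil_iris(empty), class = "no_iris_error")
})
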