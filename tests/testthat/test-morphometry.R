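test_that("polygon area and perimeter match analytic shapes", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  ap <- polygon_area_perimeter(sq)
  expect_equal(ap$area_px2, 1)
  expect_equal(ap$perimeter_px, 4)

  circ <- regular_polygon(360, 1)
  ap <- polygon_area_perimeter(circ)
  expect_lt(abs(ap$area_px2 - pi) / pi, 1e-3)
  expect_lt(abs(ap$perimeter_px - 2 * pi) / (2 * pi), 1e-3)

  expect_error(polygon_area_perimeter(cbind(c(0, 1), c(0, 1))), "3 vertices")
  bowtie <- cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))
  expect_error(polygon_area_perimeter(bowtie), "self-intersecting")
})

test_that("equivalent circular diameter converts area and calibration", {
  expect_equal(equivalent_circular_diameter(100 * pi, calibration(1)), 20)
  expect_equal(equivalent_circular_diameter(pi, calibration(2)), 4)
  expect_error(equivalent_circular_diameter(-1, calibration(1)), "positive")
  expect_error(calibration(0), "um_per_px")
})

test_that("a 250-px disc measures 500 um at 2 um/px through the pipeline", {
  sc <- scene_config(frame_size_px = c(400L, 400L), um_per_px = 2,
                     noise_sd = 0.01, seed = 9L)
  one <- single_particle_frame(sc, 199.5, 199.5, 0, 500)
  det <- detector_config(focus_score_threshold = 0.05,
                         score_norm_range = c(0, 0.3))
  found <- segment_in_focus(one$frame, det)
  expect_length(found, 1L)
  m <- shape_metrics(found, calibration(2))
  expect_lt(abs(m$ecd_um - 500) / 500, 0.02)
})

test_that("circularity matches closed forms and is capped at 1", {
  r <- 3
  expect_equal(circularity(pi * r^2, 2 * pi * r), 1)
  expect_equal(circularity(1, 4), pi / 4)
  expect_equal(circularity(2, 6), 8 * pi / 36)
  expect_warning(cl <- circularity(1.02 * pi, 2 * pi), "clipped")
  expect_equal(cl, 1)
  expect_error(circularity(1, 0), "perimeter")
})

test_that("ellipse fit recovers axes, aspect ratio and rotation invariance", {
  e <- fit_ellipse_aspect_ratio(ellipse_points(2, 1))
  expect_equal(e$aspect_ratio, 0.5, tolerance = 1e-3)
  expect_equal(e$major_axis, 4, tolerance = 1e-3)

  circ <- fit_ellipse_aspect_ratio(ellipse_points(1.5, 1.5))
  expect_equal(circ$aspect_ratio, 1, tolerance = 1e-3)

  rot <- fit_ellipse_aspect_ratio(ellipse_points(3, 1, angle = pi / 4))
  expect_equal(rot$aspect_ratio, 1 / 3, tolerance = 1e-2)
  unrot <- fit_ellipse_aspect_ratio(ellipse_points(3, 1))
  expect_equal(rot$aspect_ratio, unrot$aspect_ratio, tolerance = 1e-2)

  expect_error(fit_ellipse_aspect_ratio(regular_polygon(4, 1)), "5 vertices")
  line <- cbind(1:6, 2 * (1:6) + 3)
  expect_error(fit_ellipse_aspect_ratio(line), "collinear")
})

test_that("rasterization labels 8-connected regions and agrees with the
           polygon area", {
  disc <- regular_polygon(64, 10, 15, 15)
  r <- rasterize_and_label(disc, c(32L, 32L))
  expect_equal(r$n_components, 1L)
  expect_lt(abs(r$area_px2 - pi * 100) / (pi * 100), 0.05)

  # diagonal contact joins components under 8-connectivity
  m <- matrix(FALSE, 8, 8)
  m[2:3, 2:3] <- TRUE; m[4:5, 4:5] <- TRUE
  expect_equal(max(pelletscope:::label8(m)), 1L)
  m2 <- m; m2[4:5, 4:5] <- FALSE; m2[5:6, 5:6] <- TRUE
  expect_equal(max(pelletscope:::label8(m2)), 2L)

  expect_error(rasterize_and_label(regular_polygon(8, 2, 100, 100),
                                   c(32L, 32L)), "no pixel centers")
})

test_that("metrics are scale-equivariant and rotation-invariant", {
  set.seed(21)
  for (rep in 1:5) {
    th <- sort(runif(40, 0, 2 * pi))
    rad <- 10 + 3 * sin(3 * th) + rnorm(40, 0, 0.2)
    p <- cbind(rad * cos(th), rad * sin(th))
    ap <- polygon_area_perimeter(p)
    c0 <- suppressWarnings(circularity(ap$area_px2, ap$perimeter_px))
    ar0 <- fit_ellipse_aspect_ratio(p)$aspect_ratio
    s <- runif(1, 0.5, 3)
    aps <- polygon_area_perimeter(p * s)
    expect_equal(aps$area_px2, ap$area_px2 * s^2, tolerance = 1e-9)
    expect_equal(aps$perimeter_px, ap$perimeter_px * s, tolerance = 1e-9)
    expect_equal(suppressWarnings(circularity(aps$area_px2,
                                              aps$perimeter_px)),
                 c0, tolerance = 1e-9)
    expect_equal(fit_ellipse_aspect_ratio(p * s)$aspect_ratio, ar0,
                 tolerance = 1e-6)
    ang <- runif(1, 0, 2 * pi)
    pr <- rotate_polygon(p, ang)
    apr <- polygon_area_perimeter(pr)
    expect_equal(apr$area_px2, ap$area_px2, tolerance = 1e-6)
    expect_equal(apr$perimeter_px, ap$perimeter_px, tolerance = 1e-6)
    expect_equal(fit_ellipse_aspect_ratio(pr)$aspect_ratio, ar0,
                 tolerance = 1e-4)
  }
})

test_that("raster-path and polygon-path circularity agree for large discs", {
  for (r in c(20, 30, 45)) {
    disc <- regular_polygon(128, r, 63.3, 64.7)
    ap <- polygon_area_perimeter(disc)
    cp <- suppressWarnings(circularity(ap$area_px2, ap$perimeter_px))
    rr <- rasterize_and_label(disc, c(128L, 128L))
    cr <- suppressWarnings(circularity(rr$area_px2, rr$perimeter_px))
    expect_lt(abs(cp - cr), 0.05)
    # raster path rotation robustness: area within 2%
    rrot <- rasterize_and_label(rotate_polygon(disc, 0.7, c(63.3, 64.7)),
                                c(128L, 128L))
    expect_lt(abs(rrot$area_px2 - rr$area_px2) / rr$area_px2, 0.02)
  }
})

test_that("circularity never exceeds 1 for valid polygons", {
  set.seed(8)
  for (rep in 1:20) {
    th <- sort(runif(30, 0, 2 * pi))
    rad <- 5 + runif(1, 0, 4) * abs(sin(runif(1, 1, 4) * th))
    p <- cbind(rad * cos(th), rad * sin(th))
    ap <- polygon_area_perimeter(p)
    expect_lte(suppressWarnings(circularity(ap$area_px2, ap$perimeter_px)),
               1)
  }
})
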