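test_that("scene sampling honors the diameter distribution and focus rule", {
  sc <- test_scene(n_particles = 10L,
                   diameter_dist = diameter_dist("fixed", value_um = 500))
  truth <- sample_scene(sc)
  expect_equal(nrow(truth$particles), 10L)
  expect_true(all(truth$particles$diameter_um == 500))

  sc2 <- test_scene(slab_depth_um = 200, focus_tolerance_um = 200)
  truth2 <- sample_scene(sc2)
  expect_true(all(truth2$particles$in_focus))

  sc3 <- test_scene(n_particles = 5000L,
                    diameter_dist = diameter_dist("lognormal",
                                                  median_um = 500,
                                                  sdlog = 0.1),
                    seed = 7L)
  truth3 <- sample_scene(sc3)
  expect_lt(abs(median(truth3$particles$diameter_um) - 500) / 500, 0.02)

  # in_focus is exactly the |z| <= tolerance rule
  p <- sample_scene(test_scene(seed = 5L))$particles
  expect_identical(p$in_focus, abs(p$z_um) <= 150)
})

test_that("scene configuration rejects invalid parameters", {
  expect_error(diameter_dist("fixed", value_um = -5), "value_um")
  expect_error(test_scene(focus_tolerance_um = 400, slab_depth_um = 300),
               "focus_tolerance_um")
  expect_error(test_scene(blur_coeff = -1), "blur_coeff")
})

test_that("identical seeds give bit-identical truth and frames", {
  sc <- test_scene(seed = 123L)
  t1 <- sample_scene(sc); t2 <- sample_scene(sc)
  expect_identical(t1$particles, t2$particles)
  expect_identical(render_frame(t1, sc), render_frame(t2, sc))
})

test_that("an empty scene renders exactly the illumination background", {
  sc <- test_scene(n_particles = 0L, noise_sd = 0)
  fr <- render_frame(sample_scene(sc), sc)
  ill <- sc$illumination
  nx <- sc$frame_size_px[1L]; ny <- sc$frame_size_px[2L]
  gx <- matrix(rep(seq_len(nx) - 1L, times = ny), nx) / (nx - 1L)
  gy <- matrix(rep(seq_len(ny) - 1L, each = nx), nx) / (ny - 1L)
  expected <- ill$base + ill$gradient[1L] * (gx - 0.5) +
    ill$gradient[2L] * (gy - 0.5)
  expect_equal(fr, expected, tolerance = 1e-12)
})

test_that("defocus blur reduces the boundary gradient of a rendered disc", {
  sc <- test_scene(noise_sd = 0)
  sharp <- single_particle_frame(sc, 224, 224, 0, 500)
  blurred <- single_particle_frame(sc, 224, 224, sc$slab_depth_um, 500)
  band_score <- function(fr, truth) {
    grad <- pelletscope:::sobel_magnitude(fr)
    mask <- pelletscope:::rasterize_polygon(truth$outlines[[1L]],
                                            c(450L, 450L))
    pelletscope:::focus_score(grad, mask)
  }
  expect_gt(band_score(sharp$frame, sharp$truth),
            band_score(blurred$frame, blurred$truth))
})

test_that("nearer particles occlude farther ones at identical positions", {
  sc <- test_scene(n_particles = 2L, noise_sd = 0, blur_coeff = 0)
  truth <- sample_scene(sc)
  truth$particles$x_px <- c(224, 224)
  truth$particles$y_px <- c(224, 224)
  truth$particles$z_um <- c(-100, 100)  # particle 1 nearer the camera
  truth$particles$diameter_um <- c(400, 500)
  truth$particles$r_px <- truth$particles$diameter_um / 2 / sc$um_per_px
  fr_both <- render_frame(truth, sc)
  solo <- truth
  solo$particles <- solo$particles[1L, ]
  fr_near <- render_frame(solo, sc)
  inside <- pelletscope:::rasterize_polygon(
    pelletscope:::circle_polygon(224, 224, 400 / 2 / sc$um_per_px - 2),
    c(450L, 450L))
  expect_equal(fr_both[inside], fr_near[inside], tolerance = 1e-12)
})

test_that("fully visible particles clear the border and visibility bar", {
  for (seed in c(2L, 3L)) {
    truth <- sample_scene(test_scene(seed = seed))
    p <- truth$particles
    fv <- p[p$fully_visible, ]
    expect_true(all(fv$visible_frac >= 0.9))
    expect_true(all(fv$x_px - fv$r_px >= 0 & fv$x_px + fv$r_px <= 449 &
                    fv$y_px - fv$r_px >= 0 & fv$y_px + fv$r_px <= 449))
  }
})

test_that("layering growth follows the equal-thickness mass balance", {
  base <- layering_run_config(
    core_diameter_dist = diameter_dist("fixed", value_um = 500),
    n_phases = 1L, spray_duration = 20L, dry_duration = 5L,
    efficiency_curve = NULL, total_layer_thickness_um = 50,
    frames_per_checkpoint = 5L, n_batch = 50L, seed = 2L)
  run <- simulate_layering_run(base, test_scene())
  expect_equal(unique(run$batch_diameters_um), 600, tolerance = 1e-9)

  none <- base
  none$spray_mass_per_phase <- 0
  none$total_layer_thickness_um <- 0
  run0 <- simulate_layering_run(none, test_scene())
  expect_equal(unique(run0$batch_diameters_um), 500, tolerance = 1e-12)
})

test_that("every particle's diameter trajectory is non-decreasing and the
           checkpoint D50 rises under the logistic efficiency", {
  cfg <- layering_run_config(frames_per_checkpoint = 40L, n_batch = 400L,
                             seed = 3L)
  run <- simulate_layering_run(cfg, test_scene())
  d50 <- vapply(run$checkpoints, function(ck) ck$psd$d50_um, 0)
  expect_true(all(diff(d50) >= -1e-9))
  # per-particle growth of the tracer batch is monotone at checkpoints
  mats <- vapply(run$checkpoints, `[[`, numeric(400), "batch_diameters_um")
  expect_true(all(diff(t(mats)) >= -1e-9))
  expect_true(all(run$stream$ecd_um > 0))
  # consecutive checkpoints inside a dry phase freeze the batch
  phases <- vapply(run$checkpoints, `[[`, "", "phase")
  frames <- vapply(run$checkpoints, `[[`, 0, "frame")
  for (k in which(phases == "dry")[-1L]) {
    between <- run$stream$phase[run$stream$frame > frames[k - 1L] &
                                run$stream$frame <= frames[k]]
    if (phases[k - 1L] == "dry" && all(between == "dry")) {
      expect_equal(run$checkpoints[[k]]$batch_diameters_um,
                   run$checkpoints[[k - 1L]]$batch_diameters_um,
                   tolerance = 1e-12)
    }
  }
})
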