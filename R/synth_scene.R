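# Synthetic endoscope-like scenes of dense fluidized pellet flow.
#
# Geometry: the camera looks along z at a focal plane z = 0; particles live
# in a slab z in [-slab_depth_um, slab_depth_um]. Pixel coordinates are
# 0-based, x right, y down, pixel centers at integers. Frames are plain
# numeric matrices in [0, 1], indexed [x + 1, y + 1].

#' Describe a particle diameter distribution
#'
#' @param family one of `"fixed"`, `"uniform"`, `"lognormal"`, `"empirical"`.
#' @param value_um fixed diameter (family `"fixed"`).
#' @param min_um,max_um bounds in micrometers (family `"uniform"`).
#' @param median_um,sdlog median diameter and log-scale standard deviation
#'   (family `"lognormal"`).
#' @param values_um vector of diameters to resample from
#'   (family `"empirical"`).
#' @return an object of class `diameter_dist`.
#' @export
diameter_dist <- function(family = c("lognormal", "uniform", "fixed",
                                     "empirical"),
                          value_um = NULL, min_um = NULL, max_um = NULL,
                          median_um = NULL, sdlog = NULL, values_um = NULL) {
  family <- match.arg(family)
  d <- switch(family,
    fixed = {
      check_number(value_um, "value_um", lower = 0, strict_lower = TRUE)
      list(family = family, value_um = value_um)
    },
    uniform = {
      check_number(min_um, "min_um", lower = 0, strict_lower = TRUE)
      check_number(max_um, "max_um", lower = min_um)
      list(family = family, min_um = min_um, max_um = max_um)
    },
    lognormal = {
      check_number(median_um, "median_um", lower = 0, strict_lower = TRUE)
      check_number(sdlog, "sdlog", lower = 0)
      list(family = family, median_um = median_um, sdlog = sdlog)
    },
    empirical = {
      if (!is.numeric(values_um) || !length(values_um) ||
          any(!is.finite(values_um)) || any(values_um <= 0))
        stop_config("values_um must be positive finite diameters")
      list(family = family, values_um = values_um)
    })
  structure(d, class = "diameter_dist")
}

sample_diameters <- function(dist, n) {
  switch(dist$family,
    fixed = rep(dist$value_um, n),
    uniform = runif(n, dist$min_um, dist$max_um),
    lognormal = rlnorm(n, meanlog = log(dist$median_um), sdlog = dist$sdlog),
    empirical = sample(dist$values_um, n, replace = TRUE))
}

illumination_defaults <- function() {
  list(
    base = 0.16,             # background level at frame center
    gradient = c(0.04, 0.03), # linear ramp amplitude across x and y
    particle_base = 0.38,     # diffuse ambient contrast at the pellet rim
    particle_lambert = 0.35,  # Lambertian contrast added toward the center
    specular_strength = 0.12, # highlight amplitude
    specular_offset_frac = 0.3, # highlight offset from center, in radii
    specular_sigma_frac = 0.25, # highlight width, in radii
    attenuation_per_um = 9e-4 # contrast loss per um of |z| (light falloff)
  )
}

#' Configure a synthetic pellet scene
#'
#' Defaults emulate an endoscopic probe watching fluidized sugar pellets:
#' a 900 x 900 px sensor, a shallow observable slab in front of the probe
#' window of which about half lies within the depth of focus, and defocus
#' blur that grows linearly with distance from the focal plane.
#'
#' @param frame_size_px integer pair (width, height).
#' @param um_per_px calibration, micrometers per pixel.
#' @param n_particles particles per frame (in and out of focus); the
#'   default yields around 10-15 in-focus pellets per frame.
#' @param diameter_dist a [diameter_dist()].
#' @param slab_depth_um half-depth of the particle slab around the focal
#'   plane; z is drawn uniformly from `[-slab_depth_um, slab_depth_um]`.
#' @param focus_tolerance_um particles with `|z|` at or below this count as
#'   in focus.
#' @param blur_coeff Gaussian blur scale: `sigma_px = blur_coeff * |z| /
#'   um_per_px`.
#' @param noise_sd additive Gaussian sensor noise (intensity units).
#' @param illumination list of shading parameters, see
#'   `pelletscope:::illumination_defaults()`; partial lists are completed
#'   with defaults.
#' @param fully_visible_min_frac minimum un-occluded area fraction for a
#'   particle to count as fully visible.
#' @param seed integer seed; scenes and renders are deterministic given it.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(frame_size_px = c(900L, 900L),
                         um_per_px = 6,
                         n_particles = 24L,
                         diameter_dist = pelletscope::diameter_dist(
                           "lognormal", median_um = 500, sdlog = 0.1),
                         slab_depth_um = 300,
                         focus_tolerance_um = 150,
                         blur_coeff = 0.12,
                         noise_sd = 0.02,
                         illumination = list(),
                         fully_visible_min_frac = 0.9,
                         seed = 1L) {
  if (length(frame_size_px) != 2L || any(frame_size_px < 1))
    stop_config("frame_size_px must be two positive integers")
  check_number(um_per_px, "um_per_px", lower = 0, strict_lower = TRUE)
  check_number(n_particles, "n_particles", lower = 0)
  if (!inherits(diameter_dist, "diameter_dist"))
    stop_config("diameter_dist must be created with diameter_dist()")
  check_number(slab_depth_um, "slab_depth_um", lower = 0, strict_lower = TRUE)
  check_number(focus_tolerance_um, "focus_tolerance_um", lower = 0)
  if (focus_tolerance_um > slab_depth_um)
    stop_config("focus_tolerance_um must not exceed slab_depth_um")
  check_number(blur_coeff, "blur_coeff", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(fully_visible_min_frac, "fully_visible_min_frac",
               lower = 0, upper = 1)
  ill <- utils::modifyList(illumination_defaults(), illumination)
  structure(list(
    frame_size_px = as.integer(frame_size_px), um_per_px = um_per_px,
    n_particles = as.integer(n_particles), diameter_dist = diameter_dist,
    slab_depth_um = slab_depth_um, focus_tolerance_um = focus_tolerance_um,
    blur_coeff = blur_coeff, noise_sd = noise_sd, illumination = ill,
    fully_visible_min_frac = fully_visible_min_frac,
    seed = as.integer(seed)), class = "scene_config")
}

# pixel offsets of a disc of radius r (px) around the origin
disc_pixels <- function(r) {
  ri <- ceiling(r)
  xs <- (-ri):ri
  g <- expand.grid(dx = xs, dy = xs)
  g[g$dx^2 + g$dy^2 <= r^2, , drop = FALSE]
}

#' Sample the ground truth for one synthetic frame
#'
#' Draws particle positions uniformly in the slab and diameters i.i.d. from
#' the configured distribution, then derives per-particle visibility: the
#' fraction of each disc left un-occluded by nearer particles (z-buffer over
#' pixel centers) and whether the disc stays clear of the frame border.
#'
#' @param config a [scene_config()].
#' @return an object of class `scene_truth`: a list with a `particles`
#'   data frame (`id`, `x_px`, `y_px`, `z_um`, `diameter_um`, `r_px`,
#'   `in_focus`, `fully_visible`, `visible_frac`), an `outlines` list of
#'   polygon matrices, and the generating `config`.
#' @export
sample_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  n <- config$n_particles
  nx <- config$frame_size_px[1L]; ny <- config$frame_size_px[2L]
  with_seed(config$seed, {
    d <- sample_diameters(config$diameter_dist, n)
    if (any(d <= 0)) stop_config("diameter distribution produced d <= 0")
    x <- runif(n, 0, nx - 1)
    y <- runif(n, 0, ny - 1)
    z <- runif(n, -config$slab_depth_um, config$slab_depth_um)
  })
  r_px <- d / 2 / config$um_per_px
  in_focus <- abs(z) <= config$focus_tolerance_um
  # z-buffer over pixel centers: smaller z-distance to camera (= smaller z,
  # camera on the negative side) occludes
  visible_frac <- rep(1, n)
  if (n > 0) {
    zbuf <- matrix(Inf, nx, ny)
    owner <- matrix(0L, nx, ny)
    total <- integer(n)
    for (i in seq_len(n)) {
      px <- disc_pixels(r_px[i])
      gx <- round(x[i]) + px$dx; gy <- round(y[i]) + px$dy
      total[i] <- nrow(px)
      keep <- gx >= 0 & gx < nx & gy >= 0 & gy < ny
      idx <- cbind(gx[keep] + 1L, gy[keep] + 1L)
      win <- z[i] < zbuf[idx]
      if (any(win)) {
        idxw <- idx[win, , drop = FALSE]
        zbuf[idxw] <- z[i]
        owner[idxw] <- i
      }
    }
    vis <- tabulate(owner[owner > 0L], nbins = n)
    visible_frac <- ifelse(total > 0L, vis / total, 0)
  }
  touches_border <- (x - r_px) < 0 | (x + r_px) > (nx - 1) |
    (y - r_px) < 0 | (y + r_px) > (ny - 1)
  fully_visible <- visible_frac >= config$fully_visible_min_frac &
    !touches_border
  outlines <- lapply(seq_len(n), function(i)
    circle_polygon(x[i], y[i], r_px[i]))
  particles <- data.frame(
    id = seq_len(n), x_px = x, y_px = y, z_um = z, diameter_um = d,
    r_px = r_px, in_focus = in_focus, fully_visible = fully_visible,
    visible_frac = visible_frac)
  structure(list(particles = particles, outlines = outlines,
                 config = config), class = "scene_truth")
}

#' Render a synthetic frame from a scene truth
#'
#' Particles are drawn as shaded discs (ambient + Lambertian falloff plus a
#' small off-center specular highlight), composited far-to-near so nearer
#' particles occlude farther ones, blurred per particle with
#' `sigma_px = blur_coeff * |z| / um_per_px`, dimmed with depth, and
#' finished with additive Gaussian sensor noise.
#'
#' @param truth a [sample_scene()] result.
#' @param config the matching [scene_config()]; defaults to the config the
#'   truth was generated with.
#' @return numeric matrix `[x, y]` with values in `[0, 1]`.
#' @export
render_frame <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "scene_truth"), inherits(config, "scene_config"))
  nx <- config$frame_size_px[1L]; ny <- config$frame_size_px[2L]
  ill <- config$illumination
  gx <- matrix(rep(seq_len(nx) - 1L, times = ny), nx) / max(nx - 1L, 1L)
  gy <- matrix(rep(seq_len(ny) - 1L, each = nx), nx) / max(ny - 1L, 1L)
  frame <- ill$base + ill$gradient[1L] * (gx - 0.5) +
    ill$gradient[2L] * (gy - 0.5)
  p <- truth$particles
  if (nrow(p)) {
    for (i in order(p$z_um, decreasing = TRUE)) {  # far first, near last
      r <- p$r_px[i]
      sigma <- config$blur_coeff * abs(p$z_um[i]) / config$um_per_px
      pad <- ceiling(3 * sigma) + 2L
      ri <- ceiling(r) + pad
      # local patch grid centered on the particle
      x0 <- floor(p$x_px[i]) - ri; y0 <- floor(p$y_px[i]) - ri
      side <- 2L * ri + 1L
      lx <- matrix(rep(x0:(x0 + side - 1L), times = side), side)
      ly <- matrix(rep(y0:(y0 + side - 1L), each = side), side)
      rho <- sqrt((lx - p$x_px[i])^2 + (ly - p$y_px[i])^2)
      alpha <- (rho <= r) * 1
      atten <- max(0, 1 - ill$attenuation_per_um * abs(p$z_um[i]))
      shade <- ill$particle_base +
        ill$particle_lambert * sqrt(pmax(0, 1 - (rho / r)^2))
      sx <- p$x_px[i] - ill$specular_offset_frac * r
      sy <- p$y_px[i] - ill$specular_offset_frac * r
      shade <- shade + ill$specular_strength *
        exp(-((lx - sx)^2 + (ly - sy)^2) / (2 * (ill$specular_sigma_frac * r)^2))
      sprite <- atten * shade * alpha  # premultiplied contrast above background
      if (sigma > 0.05) {
        sprite <- gauss_blur(sprite, sigma)
        alpha <- gauss_blur(alpha, sigma)
      }
      # composite the patch over the frame
      fx <- (x0:(x0 + side - 1L))
      fy <- (y0:(y0 + side - 1L))
      kx <- fx >= 0 & fx < nx; ky <- fy >= 0 & fy < ny
      if (!any(kx) || !any(ky)) next
      fxi <- fx[kx] + 1L; fyi <- fy[ky] + 1L
      sub <- frame[fxi, fyi, drop = FALSE]
      frame[fxi, fyi] <- (1 - alpha[kx, ky, drop = FALSE]) * sub +
        alpha[kx, ky, drop = FALSE] * (ill$base) +
        sprite[kx, ky, drop = FALSE]
    }
  }
  if (config$noise_sd > 0) {
    noise <- with_seed((config$seed + 1L) %% 2147483647L,
                       matrix(rnorm(nx * ny, 0, config$noise_sd), nx, ny))
    frame <- frame + noise
  }
  clamp(frame, 0, 1)
}

#' Configure a pellet layering (drug coating) run
#'
#' A batch of inert cores is coated in alternating spray and dry phases.
#' Sprayed mass deposits as a layer of equal thickness across particles
#' (mass capture proportional to surface area), modulated by a logistic
#' spray efficiency over cumulative sprayed mass fraction, which makes the
#' median-diameter trajectory S-shaped: slow at first while pores fill,
#' then near-linear, then saturating.
#'
#' @param core_diameter_dist a [diameter_dist()] for the inert cores;
#'   defaults to a tightly sieved fraction (median 315 um, sdlog 0.05).
#' @param batch_core_mass_g total core mass in the apparatus; with
#'   `layer_density_proxy` it converts sprayed mass into layer thickness.
#' @param n_phases number of spray phases (dry phases interleave).
#' @param spray_mass_per_phase grams sprayed per phase.
#' @param spray_duration,dry_duration phase lengths in frames.
#' @param layer_density_proxy effective density (g/cm^3) of core and layer
#'   material used for the mass-to-thickness conversion.
#' @param efficiency_curve `list(midpoint=, steepness=)` for the logistic
#'   efficiency over cumulative mass fraction, or `NULL` for efficiency 1.
#' @param total_layer_thickness_um optional: specify the layer thickness
#'   (um) reached at efficiency 1 directly, bypassing the mass balance.
#' @param frames_per_checkpoint scene/PSD checkpoint spacing in frames.
#' @param n_batch number of simulated tracer particles representing the
#'   batch.
#' @param particles_per_frame diameters contributed to the measurement
#'   stream per frame.
#' @param seed integer seed.
#' @return an object of class `layering_run_config`.
#' @export
layering_run_config <- function(core_diameter_dist = diameter_dist(
                                  "lognormal", median_um = 315, sdlog = 0.05),
                                batch_core_mass_g = 500,
                                n_phases = 4L,
                                spray_mass_per_phase = 150,
                                spray_duration = 60L,
                                dry_duration = 20L,
                                layer_density_proxy = 1.25,
                                efficiency_curve = list(midpoint = 0.25,
                                                        steepness = 10),
                                total_layer_thickness_um = NULL,
                                frames_per_checkpoint = 20L,
                                n_batch = 2000L,
                                particles_per_frame = 12L,
                                seed = 1L) {
  if (!inherits(core_diameter_dist, "diameter_dist"))
    stop_config("core_diameter_dist must be created with diameter_dist()")
  check_number(n_phases, "n_phases", lower = 1)
  check_number(spray_mass_per_phase, "spray_mass_per_phase", lower = 0)
  check_number(spray_duration, "spray_duration", lower = 1)
  check_number(dry_duration, "dry_duration", lower = 0)
  check_number(layer_density_proxy, "layer_density_proxy", lower = 0,
               strict_lower = TRUE)
  check_number(batch_core_mass_g, "batch_core_mass_g", lower = 0,
               strict_lower = TRUE)
  if (!is.null(total_layer_thickness_um))
    check_number(total_layer_thickness_um, "total_layer_thickness_um",
                 lower = 0)
  structure(list(
    core_diameter_dist = core_diameter_dist,
    batch_core_mass_g = batch_core_mass_g,
    n_phases = as.integer(n_phases),
    spray_mass_per_phase = spray_mass_per_phase,
    spray_duration = as.integer(spray_duration),
    dry_duration = as.integer(dry_duration),
    layer_density_proxy = layer_density_proxy,
    efficiency_curve = efficiency_curve,
    total_layer_thickness_um = total_layer_thickness_um,
    frames_per_checkpoint = as.integer(frames_per_checkpoint),
    n_batch = as.integer(n_batch),
    particles_per_frame = as.integer(particles_per_frame),
    seed = as.integer(seed)), class = "layering_run_config")
}

logistic_efficiency <- function(curve, mass_frac) {
  if (is.null(curve)) return(rep(1, length(mass_frac)))
  1 / (1 + exp(-curve$steepness * (mass_frac - curve$midpoint)))
}

#' Simulate a pellet layering run
#'
#' Evolves a tracer batch of core diameters through alternating spray and
#' dry phases (see [layering_run_config()]), emits a per-frame measurement
#' stream of true diameters, and records checkpoints with phase label, the
#' batch's volume-weighted PSD, and a full scene truth drawn from the
#' current batch (rendered to an image on request).
#'
#' @param config a [layering_run_config()].
#' @param scene_config a [scene_config()] describing the imaging geometry;
#'   its diameter distribution is replaced per checkpoint by the evolving
#'   batch.
#' @param render if `TRUE`, render a frame at every checkpoint.
#' @return an object of class `layering_run`: list with `checkpoints`
#'   (each: `frame`, `time_s`, `phase`, `truth`, `batch_diameters_um`,
#'   `psd`, optional `image`),
#'   `stream` (data frame `frame`, `time_s`, `phase`, `ecd_um`),
#'   `batch_diameters_um` (final), `d0_50_um` (initial volume-weighted
#'   D50), and the configs. Frame time assumes 50 frames per second.
#' @export
simulate_layering_run <- function(config, scene_config = pelletscope::scene_config(),
                                  render = FALSE) {
  stopifnot(inherits(config, "layering_run_config"),
            inherits(scene_config, "scene_config"))
  fps <- 50
  d0 <- with_seed(config$seed,
                  sample_diameters(config$core_diameter_dist, config$n_batch))
  rho <- config$layer_density_proxy
  # number of real particles represented, from the core mass balance
  v_mean_cm3 <- mean(pi / 6 * (d0 * 1e-4)^3)
  n_real <- config$batch_core_mass_g / (rho * v_mean_cm3)
  total_mass <- config$n_phases * config$spray_mass_per_phase
  phase_seq <- unlist(lapply(seq_len(config$n_phases), function(p)
    c(rep("spray", config$spray_duration), rep("dry", config$dry_duration))))
  n_frames <- length(phase_seq)
  h <- 0  # layer thickness, um (equal across particles)
  sprayed <- 0
  stream <- vector("list", n_frames)
  checkpoints <- list()
  d50_0 <- unname(weighted_quantiles(size_sample(d0), 0.5))
  ck_frames <- unique(c(seq(config$frames_per_checkpoint, n_frames,
                            by = config$frames_per_checkpoint), n_frames))
  stream_draws <- with_seed((config$seed + 7L) %% 2147483647L,
    matrix(sample.int(config$n_batch, n_frames * config$particles_per_frame,
                      replace = TRUE), nrow = n_frames))
  for (f in seq_len(n_frames)) {
    if (phase_seq[f] == "spray" && config$spray_mass_per_phase > 0) {
      dm <- config$spray_mass_per_phase / config$spray_duration
      mf <- (sprayed + dm / 2) / total_mass
      eff <- logistic_efficiency(config$efficiency_curve, mf)
      if (!is.null(config$total_layer_thickness_um)) {
        dh <- eff * config$total_layer_thickness_um *
          dm / total_mass
      } else {
        d_now <- d0 + 2 * h
        a_tot_cm2 <- n_real * mean(pi * (d_now * 1e-4)^2)
        dh <- if (a_tot_cm2 > 0) eff * (dm / rho) / a_tot_cm2 * 1e4 else 0
      }
      h <- h + dh
      sprayed <- sprayed + dm
    }
    d_now <- d0 + 2 * h
    stream[[f]] <- data.frame(
      frame = f, time_s = f / fps, phase = phase_seq[f],
      ecd_um = d_now[stream_draws[f, ]])
    if (f %in% ck_frames) {
      sc <- scene_config
      sc$diameter_dist <- diameter_dist("empirical", values_um = d_now)
      sc$seed <- as.integer((config$seed + 100L + f) %% 2147483647L)
      truth <- sample_scene(sc)
      ck <- list(frame = f, time_s = f / fps, phase = phase_seq[f],
                 truth = truth,
                 batch_diameters_um = d_now,
                 psd = psd_summary(size_sample(d_now, label =
                   sprintf("frame %d", f))))
      if (render) ck$image <- render_frame(truth, sc)
      checkpoints[[length(checkpoints) + 1L]] <- ck
    }
  }
  structure(list(checkpoints = checkpoints,
                 stream = do.call(rbind, stream),
                 batch_diameters_um = d0 + 2 * h,
                 d0_50_um = d50_0,
                 config = config, scene_config = scene_config),
            class = "layering_run")
}
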