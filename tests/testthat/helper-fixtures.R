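# Shared fixtures: analytic polygons, a reduced-scale scene configuration
# (same 2.7 x 2.7 mm physical field as the default 900 px / 6 um-per-px
# sensor at half the frame diagonal, coarser sampling keeps tests fast),
# and independent brute-force oracles.

regular_polygon <- function(n, r = 1, cx = 0, cy = 0, phase = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)] + phase
  cbind(cx + r * cos(th), cy + r * sin(th))
}

ellipse_points <- function(a, b, n = 100, angle = 0, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x <- a * cos(th); y <- b * sin(th)
  cbind(cx + x * cos(angle) - y * sin(angle),
        cy + x * sin(angle) + y * cos(angle))
}

rotate_polygon <- function(p, angle, about = c(0, 0)) {
  q <- sweep(p, 2L, about)
  sweep(cbind(q[, 1L] * cos(angle) - q[, 2L] * sin(angle),
              q[, 1L] * sin(angle) + q[, 2L] * cos(angle)), 2L, -about)
}

test_scene <- function(seed = 1L, ...) {
  scene_config(frame_size_px = c(450L, 450L), um_per_px = 12, seed = seed,
               ...)
}

# render a single particle at a controlled position/depth
single_particle_frame <- function(scene, x, y, z, diameter_um) {
  scene$n_particles <- 1L
  scene$diameter_dist <- diameter_dist("fixed", value_um = diameter_um)
  truth <- sample_scene(scene)
  truth$particles$x_px <- x
  truth$particles$y_px <- y
  truth$particles$z_um <- z
  list(truth = truth, frame = render_frame(truth, scene))
}

# brute-force weighted quantile: explicit cumulative-sum search with linear
# interpolation between cumulative-weight midpoints
oracle_weighted_quantile <- function(d, q, volume = TRUE) {
  o <- order(d)
  d <- d[o]
  w <- if (volume) d^3 else rep(1, length(d))
  w <- w / sum(w)
  cmid <- numeric(length(d))
  acc <- 0
  for (i in seq_along(d)) {
    cmid[i] <- acc + w[i] / 2
    acc <- acc + w[i]
  }
  vapply(q, function(qq) {
    if (qq <= cmid[1L]) return(d[1L])
    if (qq >= cmid[length(d)]) return(d[length(d)])
    i <- max(which(cmid <= qq))
    d[i] + (d[i + 1L] - d[i]) * (qq - cmid[i]) / (cmid[i + 1L] - cmid[i])
  }, 0)
}

# naive pair-counting GLCM and feature oracle (double loops)
oracle_glcm <- function(lev, n_levels, dy, dx, symmetric = FALSE) {
  m <- matrix(0, n_levels, n_levels)
  for (y in seq_len(nrow(lev))) {
    for (x in seq_len(ncol(lev))) {
      y2 <- y + dy; x2 <- x + dx
      if (y2 < 1 || y2 > nrow(lev) || x2 < 1 || x2 > ncol(lev)) next
      m[lev[y, x], lev[y2, x2]] <- m[lev[y, x], lev[y2, x2]] + 1
      if (symmetric) m[lev[y2, x2], lev[y, x]] <- m[lev[y2, x2], lev[y, x]] + 1
    }
  }
  m / sum(m)
}

oracle_glcm_features <- function(p) {
  n <- nrow(p)
  contrast <- 0; energy <- 0; homog <- 0
  mu_i <- 0; mu_j <- 0
  for (i in 1:n) for (j in 1:n) {
    mu_i <- mu_i + i * p[i, j]; mu_j <- mu_j + j * p[i, j]
  }
  s_i <- 0; s_j <- 0; cov_ij <- 0
  for (i in 1:n) for (j in 1:n) {
    contrast <- contrast + p[i, j] * (i - j)^2
    energy <- energy + p[i, j]^2
    homog <- homog + p[i, j] / (1 + abs(i - j))
    s_i <- s_i + p[i, j] * (i - mu_i)^2
    s_j <- s_j + p[i, j] * (j - mu_j)^2
    cov_ij <- cov_ij + p[i, j] * (i - mu_i) * (j - mu_j)
  }
  corr <- if (s_i * s_j == 0) NaN else cov_ij / sqrt(s_i * s_j)
  list(contrast = contrast, correlation = corr, energy = energy,
       homogeneity = homog)
}

# naive AP oracle: for every operating point (confidence cutoff) match
# from scratch, then integrate the 101-point interpolated precision
oracle_ap <- function(dets, truths, tau, mode = "polygon") {
  conf <- vapply(dets, `[[`, 0, "confidence")
  cuts <- sort(unique(conf), decreasing = TRUE)
  pr <- matrix(NA_real_, length(cuts), 2L)
  for (ci in seq_along(cuts)) {
    sel <- which(conf >= cuts[ci])
    sel <- sel[order(conf[sel], decreasing = TRUE)]
    used <- rep(FALSE, length(truths))
    tp <- 0
    for (i in sel) {
      best <- 0; bj <- 0
      for (j in seq_along(truths)) {
        if (used[j]) next
        if (dets[[i]]$frame_id != truths[[j]]$frame_id) next
        v <- iou(dets[[i]], truths[[j]], mode = mode)
        if (v > best) { best <- v; bj <- j }
      }
      if (bj > 0 && best >= tau) { used[bj] <- TRUE; tp <- tp + 1 }
    }
    pr[ci, ] <- c(tp / length(sel), tp / length(truths))
  }
  ap <- 0
  for (r in seq(0, 1, by = 0.01)) {
    pbest <- 0
    for (ci in seq_len(nrow(pr))) {
      if (pr[ci, 2L] >= r && pr[ci, 1L] > pbest) pbest <- pr[ci, 1L]
    }
    ap <- ap + pbest / 101
  }
  ap
}

# random axis-aligned square detections/truths on a couple of frames
random_eval_instance <- function(seed) {
  set.seed(seed)
  sq <- function(cx, cy, s) {
    cbind(c(cx, cx + s, cx + s, cx), c(cy, cy, cy + s, cy + s))
  }
  n_t <- sample(1:5, 1L); n_d <- sample(1:5, 1L)
  truths <- lapply(seq_len(n_t), function(i)
    particle_outline("f1", sq(runif(1, 0, 30), runif(1, 0, 30),
                              runif(1, 5, 12)), 1, source = "truth"))
  dets <- lapply(seq_len(n_d), function(i) {
    base <- truths[[sample(n_t, 1L)]]$outline
    jit <- base + matrix(rnorm(2, sd = 3), nrow(base), 2L, byrow = TRUE)
    particle_outline("f1", jit, confidence = runif(1), source = "external")
  })
  list(dets = outline_set(dets), truths = outline_set(truths))
}
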