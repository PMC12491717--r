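# Particle detection: a classical in-focus instance segmentation stage for
# synthetic or recorded frames, and confidence filtering shared with
# externally produced detections.

#' Construct a particle outline
#'
#' @param frame_id frame identifier (character).
#' @param outline n x 2 matrix of (x, y) pixel coordinates, 0-based,
#'   implicitly closed, at least 3 vertices.
#' @param confidence detection confidence in `[0, 1]`.
#' @param source one of `"classical"`, `"external"`, `"truth"`.
#' @return an object of class `particle_outline`.
#' @export
particle_outline <- function(frame_id, outline, confidence = 1,
                             source = c("classical", "external", "truth")) {
  source <- match.arg(source)
  outline <- as_polygon_matrix(outline)
  if (nrow(outline) < 3L)
    stop_validation("outline must have at least 3 vertices")
  if (!is.numeric(confidence) || length(confidence) != 1L ||
      is.na(confidence) || confidence < 0 || confidence > 1)
    stop_validation("confidence must be a single value in [0, 1]")
  structure(list(frame_id = as.character(frame_id), outline = outline,
                 confidence = as.numeric(confidence), source = source),
            class = "particle_outline")
}

outline_set <- function(detections) {
  structure(detections, class = "outline_set")
}

#' @export
print.outline_set <- function(x, ...) {
  cat(sprintf("outline_set: %d detections over %d frame(s)\n", length(x),
              length(unique(vapply(x, `[[`, "", "frame_id")))))
  invisible(x)
}

#' Configure the classical in-focus detector
#'
#' @param confidence_threshold confidence cut applied by
#'   [filter_by_confidence()]; detections below 0.45 are conventionally
#'   excluded from size analysis.
#' @param focus_score_threshold minimum raw focus score (mean boundary-band
#'   Sobel gradient) for a segment to count as in focus; `NULL` requests
#'   calibration via [calibrate_focus_threshold()] before use (a fallback
#'   of 0.02 applies if segmentation runs uncalibrated).
#' @param min_area_px2,max_area_px2 instance area bounds in px^2.
#' @param border_margin_px instances within this margin of the frame border
#'   are removed (partially visible particles must not be measured).
#' @param split_touching split merged blobs by watershed on the distance
#'   transform.
#' @param min_edge_coverage minimum fraction of a candidate's contour that
#'   must carry a real image edge, mirroring the annotation rule that only
#'   particles with a fully visible outline are counted. Partially
#'   occluded particles come out of blob splitting bounded partly by a
#'   featureless chord; a disc with 10% of its area hidden already loses
#'   about a quarter of its contour arc, so 0.7 is the arc-fraction
#'   equivalent of the 90% visible-area rule.
#' @param score_norm_range optional `c(lo, hi)` raw-score range used to
#'   normalize focus scores into confidences; default is per-frame min-max.
#' @return an object of class `detector_config`.
#' @export
detector_config <- function(confidence_threshold = 0.45,
                            focus_score_threshold = NULL,
                            min_area_px2 = 150,
                            max_area_px2 = Inf,
                            border_margin_px = 2L,
                            split_touching = TRUE,
                            min_edge_coverage = 0.7,
                            score_norm_range = NULL) {
  check_number(confidence_threshold, "confidence_threshold", 0, 1)
  if (!is.null(focus_score_threshold))
    check_number(focus_score_threshold, "focus_score_threshold", lower = 0)
  check_number(min_area_px2, "min_area_px2", lower = 0)
  check_number(border_margin_px, "border_margin_px", lower = 0)
  check_number(min_edge_coverage, "min_edge_coverage", 0, 1)
  structure(list(confidence_threshold = confidence_threshold,
                 focus_score_threshold = focus_score_threshold,
                 min_area_px2 = min_area_px2, max_area_px2 = max_area_px2,
                 border_margin_px = border_margin_px,
                 split_touching = isTRUE(split_touching),
                 min_edge_coverage = min_edge_coverage,
                 score_norm_range = score_norm_range),
            class = "detector_config")
}

# Sobel gradient magnitude of a [x, y] matrix
sobel_magnitude <- function(m) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, byrow = TRUE) / 4
  gx <- EBImage::filter2(m, kx)
  gy <- EBImage::filter2(m, t(kx))
  sqrt(gx^2 + gy^2)
}

# mean Sobel magnitude over a 3-px inner boundary band of a labeled
# object; the band is measured against the background so that chords where
# touching particles were split apart (low gradient by construction) do
# not dilute the score
focus_score <- function(grad, obj_mask, dist_to_bg = NULL) {
  if (is.null(dist_to_bg))
    dist_to_bg <- as.matrix(EBImage::distmap(EBImage::Image(obj_mask * 1)))
  band <- obj_mask & dist_to_bg <= 3
  if (!any(band)) band <- obj_mask
  mean(grad[band])
}

# resample a closed contour at ~step px spacing and smooth vertices with a
# circular moving average: pixel-chain contours otherwise carry a heavily
# inflated (staircase) perimeter
smooth_contour <- function(p, step = 2, window = 5L) {
  n <- nrow(p)
  if (n < 8L) return(p)
  per <- polygon_perimeter_px(p)
  m <- max(8L, round(per / step))
  d <- c(0, cumsum(sqrt(diff(c(p[, 1L], p[1L, 1L]))^2 +
                        diff(c(p[, 2L], p[1L, 2L]))^2)))
  tt <- seq(0, per, length.out = m + 1L)[-(m + 1L)]
  px <- approx(d, c(p[, 1L], p[1L, 1L]), xout = tt)$y
  py <- approx(d, c(p[, 2L], p[1L, 2L]), xout = tt)$y
  h <- window %/% 2L
  idx <- outer(seq_len(m), (-h):h, function(i, k) ((i + k - 1L) %% m) + 1L)
  cbind(rowMeans(matrix(px[idx], m)), rowMeans(matrix(py[idx], m)))
}

# fraction of contour vertices carrying a real image edge: the local
# gradient magnitude (maximum over a 1-px neighborhood) must reach half
# the contour's upper-quartile gradient. Chords introduced by blob
# splitting are featureless and score 0 there.
contour_edge_coverage <- function(p, grad, nx, ny) {
  g <- numeric(nrow(p))
  for (d in list(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    xi <- clamp(round(p[, 1L]) + d[1L], 0L, nx - 1L) + 1L
    yi <- clamp(round(p[, 2L]) + d[2L], 0L, ny - 1L) + 1L
    g <- pmax(g, grad[cbind(xi, yi)])
  }
  ref <- quantile(g, 0.75, names = FALSE)
  if (ref <= 0) return(0)
  mean(g >= 0.5 * ref)
}

# robust linear background: plane fit to below-median pixels
background_plane <- function(frame) {
  nx <- nrow(frame); ny <- ncol(frame)
  sx <- seq(1L, nx, by = max(1L, nx %/% 64L))
  sy <- seq(1L, ny, by = max(1L, ny %/% 64L))
  g <- expand.grid(x = sx, y = sy)
  v <- frame[cbind(g$x, g$y)]
  keep <- v <= median(v)
  fit <- lm(v ~ x + y, data = data.frame(g, v = v), subset = keep)
  b <- coef(fit)
  outer(seq_len(nx), rep(1, ny)) * b[["x"]] +
    outer(rep(1, nx), seq_len(ny)) * b[["y"]] + b[["(Intercept)"]]
}

# expand a contour outward by half a pixel: boundary-pixel centers sit half
# a pixel inside the true edge, so areas are otherwise biased low
expand_contour_half_px <- function(p) {
  ctr <- polygon_centroid(p)
  r_eq <- sqrt(abs(polygon_signed_area(p)) / pi)
  if (r_eq < 1) return(p)
  s <- 1 + 0.5 / r_eq
  sweep(sweep(p, 2, ctr, "-") * s, 2, ctr, "+")
}

#' Segment in-focus particles in a frame
#'
#' Classical instance segmentation tuned for bright near-spherical pellets
#' on a darker background: a robust plane fit removes the illumination
#' gradient, Otsu thresholding yields a foreground mask, touching blobs are
#' split by watershed on the distance transform, and each instance gets a
#' focus score (mean Sobel gradient magnitude over a 3-px inner boundary
#' band) — defocused particles have soft edges and score low. Instances
#' touching the border, outside the area bounds, or below the focus-score
#' threshold are removed. Scores are min-max normalized (per frame, or over
#' `score_norm_range` when calibrated) and reported as confidences.
#'
#' @param frame numeric matrix `[x, y]` in `[0, 1]` (a [render_frame()]
#'   output or a grayscale image read with [read_frame()]).
#' @param config a [detector_config()].
#' @param frame_id identifier stored on the returned outlines.
#' @return an `outline_set` of [particle_outline()] objects
#'   (`source = "classical"`).
#' @export
segment_in_focus <- function(frame, config = detector_config(),
                             frame_id = "frame") {
  stopifnot(inherits(config, "detector_config"))
  if (!is.matrix(frame) || !is.numeric(frame))
    stop_validation("frame must be a 2D numeric matrix")
  nx <- nrow(frame); ny <- ncol(frame)
  bs <- frame - background_plane(frame)
  bs <- clamp(bs, 0, 1)
  # below any plausible particle contrast (sensor noise alone): nothing to
  # segment; a light blur suppresses isolated noise peaks first
  if (max(gauss_blur(bs, 1)) < 0.1) return(outline_set(list()))
  img <- EBImage::Image(bs / max(bs))
  thr <- EBImage::otsu(img)
  mask <- img > thr
  mask <- EBImage::fillHull(mask)
  lab <- if (config$split_touching) {
    EBImage::watershed(EBImage::distmap(mask), tolerance = 2, ext = 2)
  } else {
    EBImage::bwlabel(mask)
  }
  lab <- as.matrix(lab)
  nlab <- max(lab)
  if (nlab == 0L) return(outline_set(list()))
  grad <- sobel_magnitude(frame)
  dist_to_bg <- as.matrix(EBImage::distmap(EBImage::Image((lab > 0) * 1)))
  keep <- logical(nlab); score <- rep(NA_real_, nlab)
  margin <- config$border_margin_px
  for (i in seq_len(nlab)) {
    obj <- lab == i
    a <- sum(obj)
    if (a < config$min_area_px2 || a > config$max_area_px2) next
    w <- which(obj, arr.ind = TRUE)
    if (min(w[, 1L]) <= 1L + margin || max(w[, 1L]) >= nx - margin ||
        min(w[, 2L]) <= 1L + margin || max(w[, 2L]) >= ny - margin) next
    keep[i] <- TRUE
    score[i] <- focus_score(grad, obj, dist_to_bg)
  }
  if (!any(keep)) return(outline_set(list()))
  idx <- which(keep)
  s <- score[idx]
  rng <- config$score_norm_range
  if (is.null(rng)) rng <- range(s)
  conf <- if (diff(rng) > 0) clamp((s - rng[1L]) / (rng[2L] - rng[1L]), 0, 1)
          else rep(1, length(s))
  fthr <- config$focus_score_threshold
  if (is.null(fthr)) fthr <- 0.02
  pass <- s >= fthr
  if (!any(pass)) return(outline_set(list()))
  contours <- EBImage::ocontour(EBImage::Image(lab))
  dets <- lapply(which(pass), function(k) {
    p <- contours[[idx[k]]]
    if (is.null(p) || nrow(p) < 3L) return(NULL)
    p <- smooth_contour(as_polygon_matrix(p))
    if (nrow(p) < 3L || abs(polygon_signed_area(p)) < 2) return(NULL)
    if (contour_edge_coverage(p, grad, nx, ny) < config$min_edge_coverage)
      return(NULL)
    if (!polygon_is_simple(p)) return(NULL)
    p <- expand_contour_half_px(p)
    particle_outline(frame_id, p, confidence = conf[k], source = "classical")
  })
  outline_set(Filter(Negate(is.null), dets))
}

# raw focus score of an isolated reference disc rendered at depth z
reference_disc_score <- function(scene, z) {
  d_ref <- switch(scene$diameter_dist$family,
    fixed = scene$diameter_dist$value_um,
    uniform = mean(c(scene$diameter_dist$min_um, scene$diameter_dist$max_um)),
    lognormal = scene$diameter_dist$median_um,
    empirical = median(scene$diameter_dist$values_um))
  sc <- scene
  sc$n_particles <- 1L
  sc$diameter_dist <- diameter_dist("fixed", value_um = d_ref)
  sc$noise_sd <- 0
  truth <- sample_scene(sc)
  truth$particles$x_px <- (sc$frame_size_px[1L] - 1) / 2
  truth$particles$y_px <- (sc$frame_size_px[2L] - 1) / 2
  truth$particles$z_um <- z
  fr <- render_frame(truth, sc)
  grad <- sobel_magnitude(fr)
  mask <- fr > (sc$illumination$base + 0.5 * sc$illumination$particle_base)
  if (!any(mask)) return(0)
  focus_score(grad, mask)
}

#' Calibrate the focus-score threshold against a scene configuration
#'
#' The focus score of a particle embedded in a dense scene runs lower than
#' that of an isolated disc at the same depth (blurred neighbors raise the
#' local background around its edge), so the threshold is calibrated on
#' whole synthetic scenes: a few frames are sampled from the scene
#' configuration, segmented without a focus cut, each candidate is labeled
#' by whether it overlaps an in-focus fully-visible truth particle at
#' IoU >= 0.5, and the threshold maximizing the F1 of that labeling is
#' chosen. The confidence normalization range is set from isolated
#' reference discs at the slab edge (fully defocused) and the focal plane
#' (sharp).
#'
#' @param scene a [scene_config()].
#' @param config a [detector_config()] to update.
#' @param n_frames calibration frames to simulate.
#' @return the updated `detector_config`.
#' @export
calibrate_focus_threshold <- function(scene, config = detector_config(),
                                      n_frames = 4L) {
  stopifnot(inherits(scene, "scene_config"))
  cfg0 <- config
  cfg0$focus_score_threshold <- 0
  cfg0$score_norm_range <- c(0, 1)
  scores <- numeric(); positive <- logical()
  for (f in seq_len(n_frames)) {
    sc <- scene
    sc$seed <- as.integer((scene$seed + 7919L * f) %% 2147483647L)
    truth <- sample_scene(sc)
    fr <- render_frame(truth, sc)
    cand <- segment_in_focus(fr, cfg0, frame_id = "cal")
    if (!length(cand)) next
    tr <- truth_outlines(truth, frame_id = "cal")
    s <- vapply(cand, `[[`, 0, "confidence")  # raw scores under c(0, 1)
    pos <- vapply(cand, function(d) {
      length(tr) > 0 &&
        max(vapply(tr, function(t) iou(d, t), 0)) >= 0.5
    }, TRUE)
    scores <- c(scores, s); positive <- c(positive, pos)
  }
  s_far <- reference_disc_score(scene, scene$slab_depth_um)
  s_sharp <- reference_disc_score(scene, 0)
  thr <- if (any(positive) && any(!positive)) {
    # pick the cut with the best balanced operating point: maximize
    # min(precision, recall), break ties by F1
    cuts <- sort(unique(scores))
    stat <- vapply(cuts, function(ct) {
      tp <- sum(positive & scores >= ct)
      fp <- sum(!positive & scores >= ct)
      fn <- sum(positive & scores < ct)
      if (tp == 0) return(c(0, 0))
      pr <- tp / (tp + fp); rc <- tp / (tp + fn)
      c(min(pr, rc), 2 * pr * rc / (pr + rc))
    }, c(0, 0))
    cuts[order(stat[1L, ], stat[2L, ], decreasing = TRUE)[1L]]
  } else if (any(positive)) {
    min(scores)
  } else {
    mean(c(s_far, s_sharp))
  }
  config$focus_score_threshold <- thr
  config$score_norm_range <- c(s_far, s_sharp)
  config
}

#' Keep detections at or above a confidence threshold
#'
#' Detections with confidence below the threshold are excluded
#' (inclusive keep at the threshold); order is preserved.
#'
#' @param detections an `outline_set` or list of [particle_outline()]s.
#' @param threshold confidence threshold in `[0, 1]` (default 0.45).
#' @return filtered `outline_set`.
#' @export
filter_by_confidence <- function(detections, threshold = 0.45) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1)
    stop_config("threshold must be in [0, 1]")
  keep <- vapply(detections, function(d) d$confidence >= threshold, TRUE)
  outline_set(unclass(detections)[keep])
}

#' Extract truth outlines as a detection set
#'
#' Converts the in-focus, fully visible particles of a [sample_scene()]
#' truth into `particle_outline`s with confidence 1 — the annotation set a
#' human would produce under the rule that partially visible or defocused
#' particles are not annotated.
#'
#' @param truth a `scene_truth`.
#' @param frame_id frame identifier.
#' @param eligible_only keep only in-focus, fully visible particles.
#' @return an `outline_set` (`source = "truth"`).
#' @export
truth_outlines <- function(truth, frame_id = "frame", eligible_only = TRUE) {
  stopifnot(inherits(truth, "scene_truth"))
  sel <- if (eligible_only)
    which(truth$particles$in_focus & truth$particles$fully_visible)
  else seq_len(nrow(truth$particles))
  outline_set(lapply(sel, function(i)
    particle_outline(frame_id, truth$outlines[[i]], 1, source = "truth")))
}

#' Read a grayscale frame from a PNG or TIFF file
#'
#' @param path image path.
#' @return numeric matrix `[x, y]` in `[0, 1]`; RGB inputs are averaged to
#'   grayscale.
#' @export
read_frame <- function(path) {
  img <- EBImage::readImage(path)
  m <- EBImage::imageData(img)
  if (length(dim(m)) == 3L) m <- apply(m, c(1L, 2L), mean)
  m
}

#' Write a frame to a PNG or TIFF file
#'
#' @param frame numeric matrix in `[0, 1]`.
#' @param path output path; format follows the extension.
#' @export
write_frame <- function(frame, path) {
  EBImage::writeImage(EBImage::Image(clamp(frame, 0, 1)), path)
  invisible(path)
}
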