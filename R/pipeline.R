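# End-to-end convenience chain: generate frames, segment, measure. This is
# the in-silico analogue of pointing the probe at the process window for a
# few seconds.

#' Generate, segment and measure a series of synthetic frames
#'
#' For `n_frames` seeds derived from `scene$seed`, samples a scene, renders
#' it, runs [segment_in_focus()] (with a focus threshold calibrated once
#' against the scene configuration), and measures the detections. Truth
#' outlines and eligibility flags are kept alongside so detector quality
#' and size recovery can be scored against ground truth.
#'
#' @param scene a [scene_config()].
#' @param n_frames number of frames to simulate.
#' @param detector a [detector_config()]; its focus threshold and score
#'   normalization are calibrated against `scene` when unset.
#' @param use_truth_outlines measure the truth outlines of eligible
#'   particles instead of running the detector (isolates measurement from
#'   detection errors).
#' @return list with `metrics` (per-particle data frame as
#'   [shape_metrics()], plus `frame` and `time_s` at 50 frames per second),
#'   `detections`, `truths` (per-frame `outline_set`s of eligible truth),
#'   `scenes` (per-frame `scene_truth`), and the calibrated `detector`.
#' @export
run_measurement_series <- function(scene, n_frames = 10L,
                                   detector = detector_config(),
                                   use_truth_outlines = FALSE) {
  stopifnot(inherits(scene, "scene_config"))
  if (!use_truth_outlines &&
      (is.null(detector$focus_score_threshold) ||
       is.null(detector$score_norm_range)))
    detector <- calibrate_focus_threshold(scene, detector)
  cal <- calibration(scene$um_per_px)
  detections <- vector("list", n_frames)
  truths <- vector("list", n_frames)
  scenes <- vector("list", n_frames)
  metrics <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    sc <- scene
    sc$seed <- as.integer((scene$seed + f * 1009L) %% 2147483647L)
    fid <- sprintf("frame%04d", f)
    truth <- sample_scene(sc)
    scenes[[f]] <- truth
    truths[[f]] <- truth_outlines(truth, frame_id = fid)
    dets <- if (use_truth_outlines) truths[[f]] else
      segment_in_focus(render_frame(truth, sc), detector, frame_id = fid)
    detections[[f]] <- dets
    m <- shape_metrics(dets, cal)
    if (nrow(m)) {
      m$frame <- f
      m$time_s <- f / 50
    }
    metrics[[f]] <- m
  }
  met <- do.call(rbind, metrics[vapply(metrics, nrow, 0L) > 0])
  list(metrics = met, detections = detections, truths = truths,
       scenes = scenes, detector = detector)
}
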