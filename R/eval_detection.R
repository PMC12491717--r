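# Detection-quality evaluation against ground truth: IoU-based greedy
# matching in confidence order (COCO-style), precision/recall/F1 at the
# all-detections operating point, and 101-point interpolated average
# precision per IoU threshold.

#' Configure detection/truth matching
#'
#' @param iou_thresholds IoU thresholds in `(0, 1]`, sorted and unique.
#'   `coco_iou_thresholds()` gives the 0.50-0.95 step 0.05 grid.
#' @param iou_mode `"polygon"` (exact clipping areas) or `"raster"`
#'   (pixel-center rasterization).
#' @return an object of class `match_config`.
#' @export
match_config <- function(iou_thresholds = 0.5,
                         iou_mode = c("polygon", "raster")) {
  iou_mode <- match.arg(iou_mode)
  if (any(iou_thresholds <= 0 | iou_thresholds > 1))
    stop_config("iou_thresholds must lie in (0, 1]")
  iou_thresholds <- sort(unique(iou_thresholds))
  structure(list(iou_thresholds = iou_thresholds, iou_mode = iou_mode),
            class = "match_config")
}

#' @rdname match_config
#' @export
coco_iou_thresholds <- function() seq(0.5, 0.95, by = 0.05)

paths_area <- function(paths)
  sum(vapply(paths, function(p) abs(polygon_signed_area(cbind(p$x, p$y))), 0))

#' Intersection over union of two outlines
#'
#' Polygon mode clips the polygons exactly and uses shoelace areas; raster
#' mode rasterizes both on the union bounding box at 1 px resolution and
#' counts pixels.
#'
#' @param a,b polygons (n x 2 matrices) or [particle_outline()]s.
#' @param mode `"polygon"` or `"raster"`.
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(a, b, mode = c("polygon", "raster")) {
  mode <- match.arg(mode)
  pa <- as_polygon_matrix(if (inherits(a, "particle_outline")) a$outline else a)
  pb <- as_polygon_matrix(if (inherits(b, "particle_outline")) b$outline else b)
  if (nrow(pa) < 3L || nrow(pb) < 3L)
    stop_validation("degenerate polygon in IoU")
  area_a <- abs(polygon_signed_area(pa))
  area_b <- abs(polygon_signed_area(pb))
  if (area_a <= 0 || area_b <= 0)
    stop_validation("degenerate (zero-area) polygon in IoU")
  if (mode == "polygon") {
    inter <- polyclip::polyclip(list(x = pa[, 1L], y = pa[, 2L]),
                                list(x = pb[, 1L], y = pb[, 2L]),
                                op = "intersection")
    ai <- if (length(inter)) paths_area(inter) else 0
    return(ai / (area_a + area_b - ai))
  }
  x0 <- floor(min(pa[, 1L], pb[, 1L])); x1 <- ceiling(max(pa[, 1L], pb[, 1L]))
  y0 <- floor(min(pa[, 2L], pb[, 2L])); y1 <- ceiling(max(pa[, 2L], pb[, 2L]))
  fs <- c(x1 - x0 + 2L, y1 - y0 + 2L)
  sa <- sweep(pa, 2L, c(x0, y0)); sb <- sweep(pb, 2L, c(x0, y0))
  ma <- rasterize_polygon(sa, fs); mb <- rasterize_polygon(sb, fs)
  u <- sum(ma | mb)
  if (u == 0L) return(0)
  sum(ma & mb) / u
}

# IoU matrix between detections and truths of one frame
iou_matrix <- function(dets, truths, mode) {
  m <- matrix(0, length(dets), length(truths))
  for (i in seq_along(dets)) {
    for (j in seq_along(truths)) {
      m[i, j] <- iou(dets[[i]], truths[[j]], mode = mode)
    }
  }
  m
}

# greedy confidence-ordered matching at one threshold; dets already sorted
# by confidence descending; returns logical TP flags per detection
greedy_match <- function(iou_by_frame, det_frame, tau) {
  tp <- logical(length(det_frame))
  matched <- lapply(iou_by_frame, function(m) logical(ncol(m)))
  det_index_in_frame <- integer(length(det_frame))
  counter <- list()
  for (i in seq_along(det_frame)) {
    f <- det_frame[i]
    counter[[f]] <- (if (is.null(counter[[f]])) 0L else counter[[f]]) + 1L
    det_index_in_frame[i] <- counter[[f]]
  }
  for (i in seq_along(det_frame)) {
    f <- det_frame[i]
    m <- iou_by_frame[[f]]
    if (is.null(m) || ncol(m) == 0L) next
    row <- m[det_index_in_frame[i], ]
    row[matched[[f]]] <- -1
    j <- which.max(row)
    if (row[j] >= tau) {
      tp[i] <- TRUE
      matched[[f]][j] <- TRUE
    }
  }
  tp
}

ap_101 <- function(tp_flags, n_truth) {
  if (n_truth == 0L) return(NA_real_)
  if (!length(tp_flags)) return(0)
  ctp <- cumsum(tp_flags)
  cfp <- cumsum(!tp_flags)
  prec <- ctp / (ctp + cfp)
  rec <- ctp / n_truth
  grid <- seq(0, 1, by = 0.01)
  pint <- vapply(grid, function(r) {
    sel <- rec >= r
    if (any(sel)) max(prec[sel]) else 0
  }, 0)
  mean(pint)
}

#' Harmonic mean of precision and recall
#'
#' `F1 = 2 P R / (P + R)`, 0 when `P + R = 0`.
#'
#' @param precision,recall values in `[0, 1]`.
#' @return F1 score.
#' @export
f1_score <- function(precision, recall) {
  s <- precision + recall
  ifelse(s == 0, 0, 2 * precision * recall / s)
}

#' Match detections to ground truth and score them
#'
#' Per IoU threshold, detections are sorted by confidence (descending) and
#' greedily matched, each to the still-unmatched truth with the highest
#' IoU at or above the threshold, within the same frame. Unmatched
#' detections are false positives, unmatched truths false negatives.
#' Precision, recall and F1 are reported at the operating point that
#' includes all detections, at the lowest threshold; AP per threshold uses
#' 101-point interpolated precision over the recall grid.
#'
#' @param detections `outline_set` with confidences.
#' @param truths `outline_set` of annotated truth outlines.
#' @param config a [match_config()].
#' @return an object of class `eval_result`: `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`, `ap_per_threshold` (named numeric),
#'   `map50` (AP at 0.50 when evaluated), `map50_95` (mean AP over the
#'   0.50-0.95 grid when evaluated, otherwise the mean over the supplied
#'   thresholds).
#' @export
match_and_score <- function(detections, truths, config = match_config()) {
  stopifnot(inherits(config, "match_config"))
  detections <- unclass(detections); truths <- unclass(truths)
  conf <- vapply(detections, function(d) {
    if (is.null(d$confidence) || is.na(d$confidence))
      stop_validation("every detection needs a confidence value")
    d$confidence
  }, 0)
  ord <- order(conf, decreasing = TRUE)
  detections <- detections[ord]
  det_frame <- vapply(detections, `[[`, "", "frame_id")
  truth_frame <- vapply(truths, `[[`, "", "frame_id")
  frames <- unique(c(det_frame, truth_frame))
  iou_by_frame <- list()
  for (f in frames) {
    iou_by_frame[[f]] <- iou_matrix(detections[det_frame == f],
                                    truths[truth_frame == f],
                                    config$iou_mode)
  }
  n_truth <- length(truths)
  taus <- config$iou_thresholds
  ap <- numeric(length(taus)); names(ap) <- sprintf("%.2f", taus)
  tp_low <- NULL
  for (t in seq_along(taus)) {
    tp_flags <- greedy_match(iou_by_frame, det_frame, taus[t])
    if (t == 1L) tp_low <- tp_flags
    ap[t] <- ap_101(tp_flags, n_truth)
  }
  tp <- sum(tp_low); fp <- length(detections) - tp; fn <- n_truth - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  coco <- coco_iou_thresholds()
  map50 <- if ("0.50" %in% names(ap)) unname(ap[["0.50"]]) else NA_real_
  map50_95 <- if (length(taus) == length(coco) &&
                  all(abs(taus - coco) < 1e-9)) mean(ap)
              else mean(ap)
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1_score(precision, recall),
                 ap_per_threshold = ap, map50 = map50,
                 map50_95 = map50_95), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("Detection evaluation: TP %d, FP %d, FN %d\n", x$tp, x$fp, x$fn))
  cat(sprintf("  P %.3f | R %.3f | F1 %.3f | mAP50 %.3f | mAP50-95 %.3f\n",
              x$precision, x$recall, x$f1, x$map50, x$map50_95))
  invisible(x)
}
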