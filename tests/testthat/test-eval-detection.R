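sq <- function(cx, cy, s) {
  cbind(c(cx, cx + s, cx + s, cx), c(cy, cy, cy + s, cy + s))
}

test_that("IoU matches analytic overlaps in both modes", {
  a <- sq(0, 0, 1)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, sq(5, 5, 1)), 0)
  expect_equal(iou(a, sq(0.5, 0, 1)), 1 / 3, tolerance = 1e-6)

  big <- sq(0, 0, 40)
  half <- sq(20, 0, 40)
  expect_equal(iou(big, half, mode = "raster"), 1 / 3, tolerance = 0.05)
  expect_equal(iou(big, big, mode = "raster"), 1)
  expect_error(iou(cbind(c(0, 1, 2), c(0, 1, 2)), a), "degenerate")
})

test_that("the printed operating point reproduces its F1 score", {
  expect_equal(round(f1_score(0.689, 0.791), 3), 0.736)
  expect_equal(f1_score(0, 0), 0)
})

test_that("greedy matching resolves duplicates by confidence", {
  truth <- list(
    particle_outline("f1", sq(0, 0, 10), 1, "truth"))
  class(truth) <- "outline_set"
  one <- list(particle_outline("f1", sq(1, 1, 10), 0.9, "external"))
  class(one) <- "outline_set"
  ev1 <- match_and_score(one, truth, match_config(0.5))
  expect_equal(ev1$precision, 1)
  expect_equal(ev1$recall, 1)
  expect_equal(ev1$f1, 1)
  expect_equal(ev1$map50, 1)

  two <- list(particle_outline("f1", sq(1, 1, 10), 0.9, "external"),
              particle_outline("f1", sq(-1, 0, 10), 0.6, "external"))
  class(two) <- "outline_set"
  ev2 <- match_and_score(two, truth, match_config(0.5))
  expect_equal(ev2$tp, 1L)
  expect_equal(ev2$fp, 1L)
  expect_equal(ev2$precision, 0.5)
  expect_equal(ev2$recall, 1)
  expect_equal(ev2$f1, 2 / 3)
})

test_that("AP equals the naive all-operating-points oracle on small
           instances", {
  for (seed in 1:12) {
    inst <- random_eval_instance(seed + 400L)
    for (tau in c(0.5, 0.75)) {
      ev <- match_and_score(inst$dets, inst$truths, match_config(tau))
      expect_equal(unname(ev$ap_per_threshold[1L]),
                   oracle_ap(inst$dets, inst$truths, tau),
                   tolerance = 1e-12,
                   info = sprintf("seed %d tau %.2f", seed, tau))
    }
  }
})

test_that("precision and recall respond monotonically to FP removal and
           truth addition", {
  truth <- list(particle_outline("f1", sq(0, 0, 10), 1, "truth"))
  class(truth) <- "outline_set"
  dets <- list(particle_outline("f1", sq(1, 1, 10), 0.9, "external"),
               particle_outline("f1", sq(30, 30, 10), 0.8, "external"))
  class(dets) <- "outline_set"
  with_fp <- match_and_score(dets, truth, match_config(0.5))
  no_fp <- match_and_score(structure(dets[1L], class = "outline_set"),
                           truth, match_config(0.5))
  expect_gte(no_fp$precision, with_fp$precision)

  more_truth <- structure(c(unclass(truth),
                            list(particle_outline("f1", sq(60, 60, 10), 1,
                                                  "truth"))),
                          class = "outline_set")
  ev_more <- match_and_score(dets, more_truth, match_config(0.5))
  expect_lte(ev_more$recall, with_fp$recall)
})

test_that("mAP50-95 never exceeds mAP50 and self-evaluation is perfect", {
  for (seed in 1:6) {
    inst <- random_eval_instance(seed + 900L)
    ev <- match_and_score(inst$dets, inst$truths,
                          match_config(coco_iou_thresholds()))
    expect_lte(ev$map50_95, ev$map50 + 1e-12)
  }
  truth <- structure(lapply(1:4, function(i)
    particle_outline("f1", sq(i * 15, i * 10, 8), 1, "truth")),
    class = "outline_set")
  self <- match_and_score(truth, truth, match_config(coco_iou_thresholds()))
  expect_equal(self$precision, 1)
  expect_equal(self$recall, 1)
  expect_equal(self$f1, 1)
  expect_equal(self$map50, 1)
  expect_equal(self$map50_95, 1)
})

test_that("detections without confidence are rejected", {
  truth <- structure(list(particle_outline("f1", sq(0, 0, 10), 1, "truth")),
                     class = "outline_set")
  bad <- list(list(frame_id = "f1", outline = sq(0, 0, 10),
                   confidence = NA_real_))
  expect_error(match_and_score(bad, truth), "confidence")
})
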