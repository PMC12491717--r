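test_that("weighted quantiles follow the cumulative-midpoint convention", {
  s <- size_sample(rep(500, 20))
  expect_true(all(weighted_quantiles(s, c(0, 0.1, 0.5, 1)) == 500))

  # volume weights for diameters {1, 2} are {1/9, 8/9}: the midpoint grid
  # is {1/18, 1/9 + 4/9}, so the median interpolates between them
  s2 <- size_sample(c(1, 2))
  got <- weighted_quantiles(s2, 0.5)
  expect_equal(unname(got),
               oracle_weighted_quantile(c(1, 2), 0.5), tolerance = 1e-12)
  expect_equal(unname(got), 1 + (0.5 - 1 / 18) / (1 / 9 + 4 / 9 - 1 / 18),
               tolerance = 1e-12)

  set.seed(10)
  d <- rlnorm(10000, log(500), 0.2)
  expect_equal(unname(weighted_quantiles(size_sample(d), c(0.1, 0.5, 0.9))),
               oracle_weighted_quantile(d, c(0.1, 0.5, 0.9)),
               tolerance = 1e-9)
  d50_vol <- weighted_quantiles(size_sample(d), 0.5)
  d50_num <- weighted_quantiles(size_sample(d, weighting = "number"), 0.5)
  expect_gt(d50_vol, d50_num)

  expect_error(size_sample(numeric()), "non-empty")
  expect_error(size_sample(c(1, -2)), "> 0")
  expect_error(weighted_quantiles(s, c(-0.1)), "0, 1")
})

test_that("PSD summaries order D-values and reproduce reference spans", {
  set.seed(11)
  for (rep in 1:10) {
    s <- size_sample(rlnorm(200, log(400), runif(1, 0.05, 0.4)))
    ps <- psd_summary(s)
    expect_lte(ps$d10_um, ps$d50_um)
    expect_lte(ps$d50_um, ps$d90_um)
    expect_gte(ps$span, 0)
  }
  expect_equal(psd_summary(size_sample(rep(315, 50)))$span, 0)

  # published reference D-values for two sieve fractions
  expect_equal(round(span_from_dvalues(260.38, 314.78, 382.87), 2), 0.39)
  expect_equal(round(span_from_dvalues(677.03, 773.47, 883.49), 2), 0.27)
})

test_that("the KS statistic is exact on small samples and matches the
           reference implementation", {
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_equal(ks_two_sample(c(1, 2), c(3, 4))$statistic, 1)
  expect_equal(ks_two_sample(c(1, 2, 3, 4), c(2, 3, 4, 5))$statistic, 0.25)

  set.seed(12)
  for (rep in 1:10) {
    x <- rlnorm(60, log(300), 0.2); y <- rlnorm(80, log(330), 0.25)
    ours <- ks_two_sample(x, y)
    ref <- suppressWarnings(stats::ks.test(x, y))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  }
  # asymptotic p agrees with the reference at moderate n
  set.seed(13)
  x <- rlnorm(500, log(300), 0.2); y <- rlnorm(500, log(306), 0.2)
  expect_lt(abs(ks_two_sample(x, y)$p_value - stats::ks.test(x, y)$p.value),
            0.02)
  expect_error(ks_two_sample(numeric(), 1:3), "non-empty")
})

test_that("a 10% median shift at n = 5000 is essentially always detected", {
  set.seed(14)
  rejections <- vapply(1:200, function(i) {
    x <- rlnorm(5000, log(500), 0.2)
    y <- rlnorm(5000, log(550), 0.2)
    ks_two_sample(x, y)$reject
  }, TRUE)
  expect_gte(mean(rejections), 0.99)
})

test_that("the monitor windows a stream and fires its endpoint once", {
  const <- data.frame(ecd_um = rep(400, 1000), time_s = (1:1000) / 50)
  ms <- monitor_stream(const, monitor_config(window_particles = 200L))
  expect_equal(nrow(ms), 5L)
  expect_true(all(ms$d50_um == 400))
  expect_true(all(!ms$endpoint))

  expect_warning(
    empty <- monitor_stream(data.frame(ecd_um = rep(1, 10)),
                            monitor_config(window_particles = 50L)),
    "shorter")
  expect_equal(nrow(empty), 0L)

  # ramping stream: endpoint fires at the first window completing the
  # consecutive-window confirmation, exactly once
  ramp <- data.frame(ecd_um = seq(300, 400, length.out = 900))
  cfg <- monitor_config(window_particles = 100L, endpoint_d50_um = 350,
                        consecutive_windows = 2L)
  ms2 <- monitor_stream(ramp, cfg)
  expect_equal(sum(ms2$endpoint), 1L)
  fired <- attr(ms2, "endpoint_window")
  expect_true(all(ms2$d50_um[(fired - 1L):fired] >= 350))
  expect_true(fired == 2L || ms2$d50_um[fired - 2L] < 350)
})
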