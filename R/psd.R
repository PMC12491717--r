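# Particle size distribution statistics: volume-weighted quantiles,
# D-values and span, two-sample Kolmogorov-Smirnov comparison, and the
# rolling in-line D50 monitor.

#' Create a particle size sample
#'
#' @param diameters_um positive particle diameters (micrometers).
#' @param weighting `"volume"` (each particle contributes proportionally to
#'   its spherical volume, i.e. d^3) or `"number"` (equal weights). Sizing
#'   results for layered pellets are conventionally reported volume-based.
#' @param label optional text label.
#' @return an object of class `size_sample`.
#' @export
size_sample <- function(diameters_um, weighting = c("volume", "number"),
                        label = "") {
  weighting <- match.arg(weighting)
  if (!is.numeric(diameters_um) || !length(diameters_um))
    stop_validation("diameters_um must be a non-empty numeric vector")
  if (any(!is.finite(diameters_um)) || any(diameters_um <= 0))
    stop_validation("all diameters must be finite and > 0")
  structure(list(diameters_um = as.numeric(diameters_um),
                 weighting = weighting, label = label),
            class = "size_sample")
}

#' Weighted quantiles of a size sample
#'
#' Volume weighting assigns each particle weight proportional to d^3
#' (spherical volume); number weighting uses equal weights. Diameters are
#' sorted ascending and the quantile at probability q is obtained by linear
#' interpolation of diameter against cumulative-weight midpoints
#' `c_i = sum(w_j, j < i) + w_i / 2`, clamped to the observed diameter
#' range.
#'
#' @param sample a [size_sample()].
#' @param q probabilities in `[0, 1]`.
#' @return named numeric vector of diameters (micrometers).
#' @export
weighted_quantiles <- function(sample, q) {
  stopifnot(inherits(sample, "size_sample"))
  if (any(q < 0 | q > 1)) stop_validation("quantile probabilities must be in [0, 1]")
  d <- sort(sample$diameters_um)
  w <- if (sample$weighting == "volume") d^3 else rep(1, length(d))
  w <- w / sum(w)
  cmid <- cumsum(w) - w / 2
  out <- if (length(d) == 1L) rep(d, length(q)) else
    approx(cmid, d, xout = q, rule = 2, ties = "ordered")$y
  names(out) <- sprintf("q%g", q)
  out
}

#' Summarize a size sample as D-values and span
#'
#' D10/D50/D90 are the weighted quantiles at 0.1/0.5/0.9 and
#' `span = (D90 - D10) / D50`, the conventional width measure for pellet
#' size distributions.
#'
#' @param sample a [size_sample()].
#' @return an object of class `psd_summary` with fields `d10_um`, `d50_um`,
#'   `d90_um`, `span`, `n`, `weighting`, `label`.
#' @export
psd_summary <- function(sample) {
  qs <- weighted_quantiles(sample, c(0.1, 0.5, 0.9))
  out <- list(d10_um = unname(qs[1L]), d50_um = unname(qs[2L]),
              d90_um = unname(qs[3L]),
              span = unname((qs[3L] - qs[1L]) / qs[2L]),
              n = length(sample$diameters_um),
              weighting = sample$weighting, label = sample$label)
  stopifnot(out$d10_um <= out$d50_um, out$d50_um <= out$d90_um)
  structure(out, class = "psd_summary")
}

#' @export
print.psd_summary <- function(x, ...) {
  cat(sprintf("PSD summary (%s-weighted%s, n = %d)\n", x$weighting,
              if (nzchar(x$label)) paste0(", ", x$label) else "", x$n))
  cat(sprintf("  D10 %.2f um | D50 %.2f um | D90 %.2f um | span %.2f\n",
              x$d10_um, x$d50_um, x$d90_um, x$span))
  invisible(x)
}

#' Span from D-values
#'
#' `span = (D90 - D10) / D50`.
#'
#' @param d10,d50,d90 diameters in consistent units.
#' @return the span (dimensionless).
#' @export
span_from_dvalues <- function(d10, d50, d90) {
  if (any(d50 <= 0)) stop_validation("d50 must be > 0")
  (d90 - d10) / d50
}

# survival function of the Kolmogorov distribution
kolmogorov_sf <- function(lambda) {
  if (lambda < 1e-3) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  clamp(p, 0, 1)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' The statistic `D = sup |ECDF_x - ECDF_y|` is computed exactly over the
#' merged sorted values; the p-value uses the asymptotic Kolmogorov
#' distribution with the small-sample correction
#' `lambda = (sqrt(ne) + 0.12 + 0.11/sqrt(ne)) * D`,
#' `ne = n1 n2 / (n1 + n2)`. The test runs on the raw (number-based)
#' diameter values.
#'
#' @param x,y [size_sample()] objects or numeric vectors of diameters.
#' @param alpha significance level for the verdict flag (default 0.05).
#' @return an object of class `ks_result`: `statistic`, `p_value`, `n1`,
#'   `n2`, `reject` (at `alpha`).
#' @export
ks_two_sample <- function(x, y, alpha = 0.05) {
  dx <- if (inherits(x, "size_sample")) x$diameters_um else as.numeric(x)
  dy <- if (inherits(y, "size_sample")) y$diameters_um else as.numeric(y)
  if (!length(dx) || !length(dy)) stop_validation("both samples must be non-empty")
  n1 <- length(dx); n2 <- length(dy)
  v <- sort(unique(c(dx, dy)))
  fx <- findInterval(v, sort(dx)) / n1
  fy <- findInterval(v, sort(dy)) / n2
  D <- max(abs(fx - fy))
  ne <- n1 * n2 / (n1 + n2)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  p <- kolmogorov_sf(lambda)
  structure(list(statistic = D, p_value = p, n1 = n1, n2 = n2,
                 reject = p < alpha, alpha = alpha), class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("Two-sample KS test: D = %.4f, p = %.4f (n1 = %d, n2 = %d)\n",
              x$statistic, x$p_value, x$n1, x$n2))
  cat(sprintf("  H0 (same distribution) %s at %g%% level\n",
              if (x$reject) "rejected" else "not rejected", 100 * x$alpha))
  invisible(x)
}

#' Configure the in-line D50 monitor
#'
#' @param window_particles particles per tumbling window (default 5000, the
#'   sample size over which volumetric PSDs stabilize in-line).
#' @param endpoint_d50_um process endpoint specification for the windowed
#'   volume-weighted D50.
#' @param consecutive_windows number of consecutive windows that must meet
#'   the specification before the endpoint fires.
#' @return an object of class `monitor_config`.
#' @export
monitor_config <- function(window_particles = 5000L, endpoint_d50_um = Inf,
                           consecutive_windows = 3L) {
  check_number(window_particles, "window_particles", lower = 1)
  check_number(consecutive_windows, "consecutive_windows", lower = 1)
  structure(list(window_particles = as.integer(window_particles),
                 endpoint_d50_um = endpoint_d50_um,
                 consecutive_windows = as.integer(consecutive_windows)),
            class = "monitor_config")
}

#' Rolling in-line D50 monitor with endpoint detection
#'
#' Consumes a time-ordered stream of per-particle measurements, cuts it
#' into tumbling (disjoint) windows of `window_particles` particles,
#' computes the volume-weighted D50 of each window (stamped at the
#' window's last time), and flags the endpoint at the first window whose
#' D50 — together with the preceding `consecutive_windows - 1` windows —
#' meets or exceeds `endpoint_d50_um`.
#'
#' @param metrics data frame with at least an `ecd_um` column, ordered by
#'   time; optional `time_s` (or `frame`) column supplies the time stamps.
#' @param config a [monitor_config()].
#' @return an object of class `monitor_series`: data frame with `window`,
#'   `time_s`, `d50_um`, `n`, `endpoint` (TRUE at the single firing window,
#'   if any); attribute `endpoint_window` (NA if never fired).
#' @export
monitor_stream <- function(metrics, config) {
  stopifnot(inherits(config, "monitor_config"))
  if (!is.data.frame(metrics) || is.null(metrics$ecd_um))
    stop_validation("metrics must be a data frame with an ecd_um column")
  n <- nrow(metrics)
  w <- config$window_particles
  n_win <- n %/% w
  times <- if (!is.null(metrics$time_s)) metrics$time_s
           else if (!is.null(metrics$frame)) metrics$frame
           else seq_len(n)
  if (n_win == 0L) {
    warning("stream shorter than one monitor window; empty series")
    out <- data.frame(window = integer(), time_s = numeric(),
                      d50_um = numeric(), n = integer(), endpoint = logical())
    attr(out, "endpoint_window") <- NA_integer_
    class(out) <- c("monitor_series", class(out))
    return(out)
  }
  d50 <- numeric(n_win); tend <- numeric(n_win)
  for (i in seq_len(n_win)) {
    idx <- ((i - 1L) * w + 1L):(i * w)
    d50[i] <- unname(weighted_quantiles(
      size_sample(metrics$ecd_um[idx], weighting = "volume"), 0.5))
    tend[i] <- times[idx[w]]
  }
  meets <- d50 >= config$endpoint_d50_um
  k <- config$consecutive_windows
  fired <- NA_integer_
  run <- 0L
  for (i in seq_len(n_win)) {
    run <- if (meets[i]) run + 1L else 0L
    if (run >= k) { fired <- i; break }
  }
  out <- data.frame(window = seq_len(n_win), time_s = tend, d50_um = d50,
                    n = w, endpoint = seq_len(n_win) == fired &
                      !is.na(fired))
  attr(out, "endpoint_window") <- fired
  class(out) <- c("monitor_series", class(out))
  out
}
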