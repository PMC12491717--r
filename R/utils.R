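# Internal helpers shared across modules: seeded evaluation, polygon
# geometry on 0-based pixel coordinates (x right, y down, pixel centers at
# integers), and 8-connected labeling of binary masks.

# Evaluate expr under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_config <- function(...) stop(errorCondition(paste0(...),
  class = c("pelletscope_config_error", "error")))
stop_validation <- function(...) stop(errorCondition(paste0(...),
  class = c("pelletscope_validation_error", "error")))
stop_parse <- function(...) stop(errorCondition(paste0(...),
  class = c("pelletscope_parse_error", "error")))

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config(name, " must be a single finite number")
  if (x < lower || (strict_lower && x <= lower) || x > upper)
    stop_config(name, " out of range [", lower, ", ", upper, "]")
  invisible(x)
}

# ---- polygon helpers ------------------------------------------------------

as_polygon_matrix <- function(p) {
  if (is.list(p) && !is.null(p$x)) p <- cbind(p$x, p$y)
  p <- as.matrix(p)
  if (ncol(p) != 2L || !is.numeric(p))
    stop_validation("polygon must be an n x 2 numeric matrix of (x, y)")
  storage.mode(p) <- "double"
  # drop an explicitly repeated closing vertex; closure is implicit
  n <- nrow(p)
  if (n >= 2L && all(p[1L, ] == p[n, ])) p <- p[-n, , drop = FALSE]
  p
}

polygon_signed_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  sum(p[, 1L] * p[j, 2L] - p[j, 1L] * p[, 2L]) / 2
}

polygon_perimeter_px <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  sum(sqrt((p[j, 1L] - p[, 1L])^2 + (p[j, 2L] - p[, 2L])^2))
}

polygon_centroid <- function(p) {
  a <- polygon_signed_area(p)
  if (abs(a) < 1e-12) return(colMeans(p))
  n <- nrow(p)
  j <- c(2:n, 1L)
  cr <- p[, 1L] * p[j, 2L] - p[j, 1L] * p[, 2L]
  c(sum((p[, 1L] + p[j, 1L]) * cr), sum((p[, 2L] + p[j, 2L]) * cr)) / (6 * a)
}

# proper-crossing test for non-adjacent edge pairs (simple-polygon check)
polygon_is_simple <- function(p) {
  n <- nrow(p)
  if (n < 3L) return(FALSE)
  j <- c(2:n, 1L)
  ax <- p[, 1L]; ay <- p[, 2L]
  bx <- p[j, 1L]; by <- p[j, 2L]
  cross <- function(ox, oy, px1, py1, px2, py2)
    (px1 - ox) * (py2 - oy) - (py1 - oy) * (px2 - ox)
  for (i in seq_len(n - 1L)) {
    ks <- (i + 1L):n
    ks <- ks[ks != i & ks != (i %% n + 1L) & !(i == 1L & ks == n)]
    for (k in ks) {
      d1 <- cross(ax[i], ay[i], bx[i], by[i], ax[k], ay[k])
      d2 <- cross(ax[i], ay[i], bx[i], by[i], bx[k], by[k])
      d3 <- cross(ax[k], ay[k], bx[k], by[k], ax[i], ay[i])
      d4 <- cross(ax[k], ay[k], bx[k], by[k], bx[i], by[i])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(FALSE)
    }
  }
  TRUE
}

# regular polygon approximating a circle; 0-based pixel coordinates
circle_polygon <- function(cx, cy, r, n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# even-odd point-in-polygon for a grid of pixel centers; returns logical
# matrix in EBImage orientation [x, y] of size frame_size = c(nx, ny)
rasterize_polygon <- function(p, frame_size) {
  nx <- frame_size[1L]; ny <- frame_size[2L]
  xr <- range(p[, 1L]); yr <- range(p[, 2L])
  x0 <- max(0L, floor(xr[1L])); x1 <- min(nx - 1L, ceiling(xr[2L]))
  y0 <- max(0L, floor(yr[1L])); y1 <- min(ny - 1L, ceiling(yr[2L]))
  out <- matrix(FALSE, nx, ny)
  if (x0 > x1 || y0 > y1) return(out)
  xs <- x0:x1; ys <- y0:y1
  gx <- matrix(rep(xs, times = length(ys)), length(xs))
  gy <- matrix(rep(ys, each = length(xs)), length(xs))
  inside <- matrix(FALSE, length(xs), length(ys))
  n <- nrow(p)
  j <- c(n, seq_len(n - 1L))
  for (i in seq_len(n)) {
    xi <- p[i, 1L]; yi <- p[i, 2L]
    xj <- p[j[i], 1L]; yj <- p[j[i], 2L]
    crosses <- ((yi > gy) != (yj > gy)) &
      (gx < (xj - xi) * (gy - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
  }
  out[xs + 1L, ys + 1L] <- inside
  out
}

# 8-connected labeling of a logical matrix by iterative minimum-label
# propagation; adequate for particle-sized masks.
label8 <- function(mask) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- mask > 0
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  lab[mask] <- seq_len(sum(mask))
  shift <- function(m, dx, dy, fill = 0L) {
    out <- matrix(fill, nx, ny)
    xs <- max(1L, 1L + dx):min(nx, nx + dx)
    ys <- max(1L, 1L + dy):min(ny, ny + dy)
    out[xs, ys] <- m[xs - dx, ys - dy]
    out
  }
  big <- .Machine$integer.max
  repeat {
    cur <- lab
    cand <- lab
    cand[!mask] <- big
    cand[lab == 0L & mask] <- big
    m <- cand
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                   c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
      s <- shift(cand, d[1L], d[2L], fill = big)
      m <- pmin(m, s)
    }
    m[!mask] <- 0L
    m[m == big] <- 0L
    lab <- m
    if (identical(lab, cur)) break
  }
  # renumber labels 1..k
  u <- sort(unique(lab[lab > 0L]))
  if (length(u)) lab[lab > 0L] <- match(lab[lab > 0L], u)
  lab
}

# separable Gaussian blur of a plain matrix, zero-padded boundaries
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(v) {
    # v: matrix; convolve along rows (dim 1) with kernel k
    n <- nrow(v)
    out <- matrix(0, n, ncol(v))
    for (i in seq_along(k)) {
      off <- i - r - 1L
      xs <- max(1L, 1L - off):min(n, n - off)
      out[xs, ] <- out[xs, ] + k[i] * v[xs + off, ]
    }
    out
  }
  t(pad_conv(t(pad_conv(m))))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
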