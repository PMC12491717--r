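# Gray-level co-occurrence matrix texture features for micrograph-like
# grayscale images: contrast, correlation, energy, homogeneity. Smoother
# pellet surfaces show lower contrast and higher energy/homogeneity, which
# is what makes these features track coating progress on electron
# micrographs.

#' Configure GLCM computation
#'
#' Defaults follow the common MATLAB convention: 8 gray levels, a single
#' (0, 1) offset (horizontal neighbor), asymmetric counting, per-image
#' min-max linear quantization.
#'
#' @param n_levels number of gray levels (>= 2).
#' @param offsets list of `c(dy, dx)` integer pairs; `(0, 1)` is the pixel
#'   to the right.
#' @param symmetric if `TRUE`, pairs are counted in both orders.
#' @param range optional fixed `c(lo, hi)` quantization range for
#'   cross-image comparability; default is per-image min-max.
#' @return an object of class `glcm_config`.
#' @export
glcm_config <- function(n_levels = 8L, offsets = list(c(0L, 1L)),
                        symmetric = FALSE, range = NULL) {
  check_number(n_levels, "n_levels", lower = 2)
  if (!is.list(offsets) || !length(offsets)) offsets <- list(offsets)
  for (o in offsets) {
    if (length(o) != 2L || any(o != round(o)))
      stop_config("each offset must be an integer pair (dy, dx)")
    if (all(o == 0L)) stop_config("offsets must be non-zero")
  }
  if (!is.null(range) && (length(range) != 2L || range[2L] < range[1L]))
    stop_config("range must be c(lo, hi) with hi >= lo")
  structure(list(n_levels = as.integer(n_levels),
                 offsets = lapply(offsets, as.integer),
                 symmetric = isTRUE(symmetric), range = range),
            class = "glcm_config")
}

quantize_levels <- function(img, n_levels, range = NULL) {
  if (is.null(range)) range <- base::range(img)
  lo <- range[1L]; hi <- range[2L]
  if (hi <= lo) return(matrix(1L, nrow(img), ncol(img)))
  lev <- 1L + as.integer(floor((img - lo) / (hi - lo) * n_levels))
  lev <- clamp(lev, 1L, n_levels)
  matrix(lev, nrow(img), ncol(img))
}

#' Compute gray-level co-occurrence matrices
#'
#' The image is quantized to `n_levels` gray levels and, for each offset
#' `(dy, dx)`, the occurrences of level pairs (i at a pixel, j at the
#' offset neighbor) are counted over all valid pixels and normalized to
#' sum 1. Symmetric counting accumulates both orders.
#'
#' @param image numeric matrix, rows indexing y (down) and columns x
#'   (right).
#' @param config a [glcm_config()].
#' @return list of normalized `n_levels` x `n_levels` matrices, one per
#'   offset, with class `glcm`.
#' @export
compute_glcm <- function(image, config = glcm_config()) {
  stopifnot(inherits(config, "glcm_config"))
  if (!is.matrix(image) || !is.numeric(image))
    stop_validation("image must be a 2D numeric matrix")
  n <- config$n_levels
  lev <- quantize_levels(image, n, config$range)
  ny <- nrow(lev); nx <- ncol(lev)
  out <- lapply(config$offsets, function(off) {
    dy <- off[1L]; dx <- off[2L]
    if (abs(dy) >= ny || abs(dx) >= nx)
      stop_validation("offset (", dy, ", ", dx, ") larger than image")
    ys <- max(1L, 1L - dy):min(ny, ny - dy)
    xs <- max(1L, 1L - dx):min(nx, nx - dx)
    i <- lev[ys, xs, drop = FALSE]
    j <- lev[ys + dy, xs + dx, drop = FALSE]
    counts <- tabulate(i + n * (j - 1L), nbins = n * n)
    m <- matrix(counts, n, n)
    if (config$symmetric) m <- m + t(m)
    m / sum(m)
  })
  structure(out, class = "glcm", config = config)
}

#' Texture features from a GLCM
#'
#' Standard definitions over a normalized co-occurrence matrix p(i, j):
#' contrast `sum p (i - j)^2`; correlation
#' `sum p (i - mu_i)(j - mu_j) / (sigma_i sigma_j)` (reported as `NaN`
#' when a marginal standard deviation is zero rather than fabricating a
#' value); energy `sum p^2`; homogeneity `sum p / (1 + |i - j|)`.
#' Multi-offset input yields features averaged over offsets.
#'
#' @param glcm a [compute_glcm()] result, or a single normalized matrix.
#' @return list with `contrast`, `correlation`, `energy`, `homogeneity`.
#' @export
glcm_features <- function(glcm) {
  mats <- if (inherits(glcm, "glcm")) unclass(glcm)
          else if (is.matrix(glcm)) list(glcm)
          else stop_validation("glcm must be a glcm object or matrix")
  feats <- lapply(mats, function(p) {
    if (!is.matrix(p) || nrow(p) != ncol(p))
      stop_validation("GLCM must be a square matrix")
    if (abs(sum(p) - 1) > 1e-9)
      stop_validation("GLCM is not normalized (sum != 1)")
    n <- nrow(p)
    i <- matrix(rep(seq_len(n), times = n), n)
    j <- matrix(rep(seq_len(n), each = n), n)
    mu_i <- sum(p * i); mu_j <- sum(p * j)
    s_i <- sqrt(sum(p * (i - mu_i)^2)); s_j <- sqrt(sum(p * (j - mu_j)^2))
    corr <- if (s_i * s_j == 0) NaN else
      sum(p * (i - mu_i) * (j - mu_j)) / (s_i * s_j)
    list(contrast = sum(p * (i - j)^2),
         correlation = corr,
         energy = sum(p^2),
         homogeneity = sum(p / (1 + abs(i - j))))
  })
  avg <- function(name) mean(vapply(feats, `[[`, 0, name))
  list(contrast = avg("contrast"), correlation = avg("correlation"),
       energy = avg("energy"), homogeneity = avg("homogeneity"))
}
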