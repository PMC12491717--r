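# Calibrated size and shape metrics per particle outline. The primary
# measurement path works on polygon vertices (shoelace area, Euclidean
# perimeter) to minimize perimeter discretization bias; a raster path is
# exposed for mask-based workflows.

#' Pixel-to-micrometer calibration
#'
#' @param um_per_px micrometers per pixel, as determined for the imaging
#'   system (e.g. with a caliper target).
#' @return an object of class `calibration`.
#' @export
calibration <- function(um_per_px) {
  check_number(um_per_px, "um_per_px", lower = 0, strict_lower = TRUE)
  structure(list(um_per_px = um_per_px), class = "calibration")
}

#' Polygon area and perimeter in pixel units
#'
#' Area by the shoelace formula (absolute value), perimeter as the sum of
#' vertex-to-vertex Euclidean edge lengths. The polygon is implicitly
#' closed.
#'
#' @param outline n x 2 matrix of (x, y) vertices, n >= 3, simple.
#' @return list with `area_px2` and `perimeter_px`.
#' @export
polygon_area_perimeter <- function(outline) {
  p <- as_polygon_matrix(outline)
  if (nrow(p) < 3L) stop_validation("polygon needs at least 3 vertices")
  if (!polygon_is_simple(p))
    stop_validation("polygon is self-intersecting")
  list(area_px2 = abs(polygon_signed_area(p)),
       perimeter_px = polygon_perimeter_px(p))
}

#' Equivalent circular diameter
#'
#' Diameter of the circle with the same area as the particle's projected
#' area, converted to micrometers:
#' `ecd_um = 2 * sqrt(area_px2 / pi) * um_per_px`.
#'
#' @param area_px2 projected area in px^2, > 0.
#' @param cal a [calibration()].
#' @return diameter in micrometers.
#' @export
equivalent_circular_diameter <- function(area_px2, cal) {
  stopifnot(inherits(cal, "calibration"))
  if (any(!is.finite(area_px2)) || any(area_px2 <= 0))
    stop_validation("area must be positive")
  2 * sqrt(area_px2 / pi) * cal$um_per_px
}

#' Circularity
#'
#' `C = 4 * pi * A / P^2`: 1 for a perfect circle, smaller for irregular
#' outlines. Values marginally above 1 (discretization artifacts) are
#' clipped to 1 with a warning.
#'
#' @param area,perimeter in consistent units, both > 0.
#' @return circularity in `(0, 1]`.
#' @export
circularity <- function(area, perimeter) {
  if (any(!is.finite(perimeter)) || any(perimeter <= 0))
    stop_validation("perimeter must be positive")
  if (any(!is.finite(area)) || any(area <= 0))
    stop_validation("area must be positive")
  C <- 4 * pi * area / perimeter^2
  if (any(C > 1)) {
    warning("circularity > 1 clipped to 1 (discretization artifact)")
    C <- pmin(C, 1)
  }
  C
}

# Halir & Flusser numerically stable direct least-squares ellipse fit.
# Returns conic coefficients (a, b, c, d, e, f) or NULL when degenerate.
fit_ellipse_conic <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sc <- max(stats::sd(x), stats::sd(y))
  if (!is.finite(sc) || sc == 0) return(NULL)
  xs <- (x - mx) / sc; ys <- (y - my) / sc
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T0 <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(T0)) return(NULL)
  M <- S1 + S2 %*% T0
  M2 <- rbind(M[3L, ] / 2, -M[2L, ], M[1L, ] / 2)
  ev <- eigen(M2)
  vec <- Re(ev$vectors)
  cond <- 4 * vec[1L, ] * vec[3L, ] - vec[2L, ]^2
  k <- which(cond > 0)
  if (!length(k)) return(NULL)
  a1 <- vec[, k[1L]]
  coefs <- c(a1, as.vector(T0 %*% a1))  # a, b, c, d, e, f in scaled coords
  # undo normalization: substitute x -> (x - mx)/sc, y -> (y - my)/sc
  a <- coefs[1L] / sc^2; b <- coefs[2L] / sc^2; c2 <- coefs[3L] / sc^2
  d <- -2 * coefs[1L] * mx / sc^2 - coefs[2L] * my / sc^2 + coefs[4L] / sc
  e <- -2 * coefs[3L] * my / sc^2 - coefs[2L] * mx / sc^2 + coefs[5L] / sc
  f <- coefs[1L] * mx^2 / sc^2 + coefs[2L] * mx * my / sc^2 +
    coefs[3L] * my^2 / sc^2 - coefs[4L] * mx / sc - coefs[5L] * my / sc +
    coefs[6L]
  c(a, b, c2, d, e, f)
}

conic_axes <- function(k) {
  a <- k[1L]; b <- k[2L]; c2 <- k[3L]; d <- k[4L]; e <- k[5L]; f <- k[6L]
  A <- matrix(c(a, b / 2, b / 2, c2), 2L)
  ctr <- tryCatch(solve(2 * A, -c(d, e)), error = function(err) NULL)
  if (is.null(ctr)) return(NULL)
  f0 <- a * ctr[1L]^2 + b * ctr[1L] * ctr[2L] + c2 * ctr[2L]^2 +
    d * ctr[1L] + e * ctr[2L] + f
  lam <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (any(lam * -f0 <= 0)) return(NULL)
  semi <- sqrt(-f0 / lam)
  sort(2 * semi, decreasing = TRUE)  # full axis lengths, major first
}

# ellipse with the same second central area moments as the polygon
moment_ellipse_axes <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  cr <- p[, 1L] * p[j, 2L] - p[j, 1L] * p[, 2L]
  A <- sum(cr) / 2
  if (abs(A) < 1e-12) return(NULL)
  cx <- sum((p[, 1L] + p[j, 1L]) * cr) / (6 * A)
  cy <- sum((p[, 2L] + p[j, 2L]) * cr) / (6 * A)
  ixx <- sum(cr * (p[, 1L]^2 + p[, 1L] * p[j, 1L] + p[j, 1L]^2)) / 12
  iyy <- sum(cr * (p[, 2L]^2 + p[, 2L] * p[j, 2L] + p[j, 2L]^2)) / 12
  ixy <- sum(cr * (2 * p[, 1L] * p[, 2L] + p[, 1L] * p[j, 2L] +
                   p[j, 1L] * p[, 2L] + 2 * p[j, 1L] * p[j, 2L])) / 24
  mxx <- ixx / A - cx^2; myy <- iyy / A - cy^2; mxy <- ixy / A - cx * cy
  lam <- eigen(matrix(c(mxx, mxy, mxy, myy), 2L), symmetric = TRUE,
               only.values = TRUE)$values
  if (any(lam <= 0)) return(NULL)
  sort(4 * sqrt(lam), decreasing = TRUE)
}

#' Least-squares ellipse fit and aspect ratio of an outline
#'
#' Fits an ellipse to the outline vertices by direct algebraic
#' ellipse-specific least squares (Halir-Flusser formulation of the
#' Fitzgibbon fit) and returns the full major/minor axis lengths and their
#' ratio. When the direct fit is degenerate the ellipse with the same
#' second central area moments as the polygon (the regionprops-equivalent)
#' is used instead and flagged via the `method` field.
#'
#' @param outline n x 2 vertex matrix, n >= 5, not collinear.
#' @return list with `major_axis`, `minor_axis`, `aspect_ratio`
#'   (minor/major, in `(0, 1]`), `method` (`"direct"` or `"moments"`).
#' @export
fit_ellipse_aspect_ratio <- function(outline) {
  p <- as_polygon_matrix(outline)
  if (nrow(p) < 5L) stop_validation("ellipse fit needs at least 5 vertices")
  sv <- svd(sweep(p, 2L, colMeans(p)))$d
  if (sv[2L] < 1e-9 * max(sv[1L], 1e-12))
    stop_validation("vertices are collinear; no ellipse fit possible")
  k <- fit_ellipse_conic(p[, 1L], p[, 2L])
  axes <- if (!is.null(k)) conic_axes(k) else NULL
  method <- "direct"
  if (is.null(axes)) {
    axes <- moment_ellipse_axes(p)
    method <- "moments"
  }
  if (is.null(axes)) stop_validation("degenerate outline; no ellipse fit")
  list(major_axis = axes[1L], minor_axis = axes[2L],
       aspect_ratio = axes[2L] / axes[1L], method = method)
}

#' Rasterize an outline and label its 8-connected region
#'
#' Pixels whose centers lie inside the polygon form the mask; 8-connected
#' components are labeled and the largest retained if rasterization
#' fragments the region. The mask perimeter comes from the traced contour
#' of the retained component.
#'
#' @param outline polygon in pixel coordinates (0-based).
#' @param frame_size integer pair (width, height).
#' @return list with `mask` (logical `[x, y]`), `area_px2` (pixel count),
#'   `perimeter_px` (contour trace length), `n_components`.
#' @export
rasterize_and_label <- function(outline, frame_size) {
  p <- as_polygon_matrix(outline)
  mask <- rasterize_polygon(p, as.integer(frame_size))
  if (!any(mask))
    stop_validation("polygon covers no pixel centers inside the frame")
  lab <- label8(mask)
  n_comp <- max(lab)
  if (n_comp > 1L) {
    counts <- tabulate(lab[lab > 0L], nbins = n_comp)
    mask <- lab == which.max(counts)
  }
  ctr <- EBImage::ocontour(EBImage::Image(mask * 1))[[1L]]
  ctr <- smooth_contour(as_polygon_matrix(ctr))
  ctr <- expand_contour_half_px(ctr)
  list(mask = mask, area_px2 = sum(mask),
       perimeter_px = polygon_perimeter_px(ctr),
       n_components = n_comp)
}

#' Measure size and shape metrics for a set of outlines
#'
#' Runs the polygon measurement path on every outline: area and perimeter
#' (shoelace / edge sums), equivalent circular diameter, circularity, and
#' the least-squares-ellipse aspect ratio, all calibrated to micrometers.
#'
#' @param detections an `outline_set` or list of [particle_outline()]s.
#' @param cal a [calibration()].
#' @return data frame with one row per particle: `frame_id`, `confidence`,
#'   `area_um2`, `perimeter_um`, `ecd_um`, `circularity`, `aspect_ratio`,
#'   `major_axis_um`, `minor_axis_um`.
#' @export
shape_metrics <- function(detections, cal) {
  stopifnot(inherits(cal, "calibration"))
  rows <- lapply(detections, function(d) {
    ap <- polygon_area_perimeter(d$outline)
    ell <- fit_ellipse_aspect_ratio(d$outline)
    data.frame(
      frame_id = d$frame_id, confidence = d$confidence,
      area_um2 = ap$area_px2 * cal$um_per_px^2,
      perimeter_um = ap$perimeter_px * cal$um_per_px,
      ecd_um = equivalent_circular_diameter(ap$area_px2, cal),
      circularity = suppressWarnings(
        circularity(ap$area_px2, ap$perimeter_px)),
      aspect_ratio = ell$aspect_ratio,
      major_axis_um = ell$major_axis * cal$um_per_px,
      minor_axis_um = ell$minor_axis * cal$um_per_px)
  })
  if (!length(rows))
    return(data.frame(frame_id = character(), confidence = numeric(),
                      area_um2 = numeric(), perimeter_um = numeric(),
                      ecd_um = numeric(), circularity = numeric(),
                      aspect_ratio = numeric(), major_axis_um = numeric(),
                      minor_axis_um = numeric()))
  do.call(rbind, rows)
}
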