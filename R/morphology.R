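# Per-nucleus morphological features from the contour polygon.

# point-in-polygon (even-odd crossing number), vectorized over points
#' @keywords internal
point_in_polygon <- function(px, py, poly) {
  nv <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# distance from points to the closed polyline boundary
#' @keywords internal
dist_to_boundary <- function(px, py, poly) {
  nv <- nrow(poly)
  d2 <- rep(Inf, length(px))
  j <- nv
  for (i in seq_len(nv)) {
    ax <- poly[j, 1]; ay <- poly[j, 2]
    bx <- poly[i, 1]; by <- poly[i, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    t <- if (L2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
    j <- i
  }
  sqrt(d2)
}

#' Rasterize a contour polygon to a binary mask
#'
#' Pixel-center semantics: a pixel belongs to the mask when its integer-grid
#' center lies inside the polygon or on its boundary. The mask window is the
#' integer bounding box of the contour (optionally a supplied bbox).
#'
#' @param contour n x 2 matrix of (x, y) vertices.
#' @param bbox Optional numeric \code{c(xmin, ymin, xmax, ymax)}; default the
#'   contour's integer bounds.
#' @return List with \code{mask} (logical matrix, rows = y), \code{xs},
#'   \code{ys} (pixel coordinates of columns/rows).
#' @export
rasterize_contour <- function(contour, bbox = NULL) {
  if (is.null(bbox))
    bbox <- c(floor(min(contour[, 1])), floor(min(contour[, 2])),
              ceiling(max(contour[, 1])), ceiling(max(contour[, 2])))
  xs <- seq(floor(bbox[1]), ceiling(bbox[3]))
  ys <- seq(floor(bbox[2]), ceiling(bbox[4]))
  g <- expand.grid(x = xs, y = ys)
  inb <- point_in_polygon(g$x, g$y, contour)
  onb <- dist_to_boundary(g$x, g$y, contour) < 1e-9
  mask <- matrix(inb | onb, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  list(mask = mask, xs = xs, ys = ys)
}

#' @keywords internal
polygon_perimeter <- function(poly) {
  p2 <- rbind(poly, poly[1, , drop = FALSE])
  sum(sqrt(diff(p2[, 1])^2 + diff(p2[, 2])^2))
}

# signed area (shoelace); positive = counterclockwise in y-down coords
#' @keywords internal
polygon_signed_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# resample closed polyline to m points at uniform arc length
#' @keywords internal
resample_contour <- function(poly, m = 128) {
  p2 <- rbind(poly, poly[1, , drop = FALSE])
  seg <- sqrt(diff(p2[, 1])^2 + diff(p2[, 2])^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  t_new <- seq(0, total, length.out = m + 1)[-(m + 1)]
  x <- stats::approx(s, p2[, 1], xout = t_new)$y
  y <- stats::approx(s, p2[, 2], xout = t_new)$y
  cbind(x, y)
}

# circular gaussian smoothing of a numeric vector
#' @keywords internal
smooth_circular <- function(v, sigma) {
  if (sigma <= 0) return(v)
  h <- ceiling(3 * sigma)
  k <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- length(v)
  idx <- outer(seq_len(n), seq(-h, h), function(i, o) ((i + o - 1) %% n) + 1)
  as.numeric(matrix(v[idx], nrow = n) %*% k)
}

# curvature along a closed uniformly-sampled contour
#' @keywords internal
contour_curvature <- function(poly, m = 128, sigma = 2) {
  if (polygon_signed_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
  rs <- resample_contour(poly, m)
  x <- smooth_circular(rs[, 1], sigma)
  y <- smooth_circular(rs[, 2], sigma)
  n <- length(x)
  ip <- c(2:n, 1); im <- c(n, 1:(n - 1))
  xd <- (x[ip] - x[im]) / 2; yd <- (y[ip] - y[im]) / 2
  xdd <- x[ip] - 2 * x + x[im]; ydd <- y[ip] - 2 * y + y[im]
  den <- (xd^2 + yd^2)^1.5
  k <- ifelse(den > 0, (xd * ydd - yd * xdd) / den, 0)
  k
}

#' Morphological feature names
#' @return Character vector of the 14 morphology column names.
#' @export
morphology_feature_names <- function() {
  c("Area", "AreaBbox", "CellEccentricities", "Circularity", "Elongation",
    "Extent", "MajorAxisLength", "MinorAxisLength", "Perimeter", "Solidity",
    "CurvMean", "CurvMax", "CurvMin", "CurvStd")
}

#' Compute the 14 morphological features of one nucleus
#'
#' The contour is rasterized to a binary mask; region features follow the
#' standard region-property definitions: \code{Area} = mask pixel count,
#' \code{AreaBbox} = bounding-box pixel count, \code{Extent} = Area/AreaBbox,
#' \code{Solidity} = Area over the rasterized convex-hull area,
#' \code{Circularity} = 4 pi Area / Perimeter^2 with the perimeter of the
#' contour polygon, and axis lengths/eccentricity from the mask's central
#' second moments (ellipse of equal moments; lengths are 4 sqrt(eigenvalue)).
#' \code{Elongation} = 1 - Minor/Major. Curvature statistics are taken over
#' the contour resampled to uniform arc length and Gaussian-smoothed
#' (sigma = 2 samples), using
#' kappa = (x'y'' - y'x'') / (x'^2 + y'^2)^(3/2), with the contour oriented
#' so a circle has positive curvature.
#'
#' @param contour n x 2 matrix of (x, y) vertices (>= 3, non-collinear).
#' @param bbox Optional \code{c(xmin, ymin, xmax, ymax)}.
#' @param id Nucleus id used in error messages.
#' @param curv_samples,curv_sigma Curvature resampling length and smoothing.
#' @return Named numeric vector of the 14 features.
#' @export
compute_morphology <- function(contour, bbox = NULL, id = "?",
                               curv_samples = 128, curv_sigma = 2) {
  if (nrow(contour) < 3)
    stop("contour of nucleus ", id, " has fewer than 3 vertices")
  ras <- rasterize_contour(contour, bbox)
  mask <- ras$mask
  area <- sum(mask)
  if (area == 0 || abs(polygon_signed_area(contour)) < 1e-12)
    stop("degenerate (zero-area) contour for nucleus ", id)
  area_bbox <- length(ras$xs) * length(ras$ys)
  perim <- polygon_perimeter(contour)
  # mask pixel coordinates
  idx <- which(mask, arr.ind = TRUE)
  px <- ras$xs[idx[, 2]]; py <- ras$ys[idx[, 1]]
  mu20 <- mean((px - mean(px))^2)
  mu02 <- mean((py - mean(py))^2)
  mu11 <- mean((px - mean(px)) * (py - mean(py)))
  ev <- eigen(matrix(c(mu20, mu11, mu11, mu02), 2), symmetric = TRUE)$values
  ev <- pmax(ev, 0)
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2])
  ecc <- if (ev[1] > 0) sqrt(1 - ev[2] / ev[1]) else 0
  # solidity from the rasterized convex hull of the contour vertices
  hull <- contour[rev(grDevices::chull(contour)), , drop = FALSE]
  hull_area <- sum(rasterize_contour(hull, bbox)$mask)
  k <- contour_curvature(contour, m = curv_samples, sigma = curv_sigma)
  c(Area = area, AreaBbox = area_bbox,
    CellEccentricities = ecc,
    Circularity = 4 * pi * area / perim^2,
    Elongation = if (major > 0) 1 - minor / major else 0,
    Extent = area / area_bbox,
    MajorAxisLength = major, MinorAxisLength = minor,
    Perimeter = perim,
    Solidity = min(1, area / hull_area),
    CurvMean = mean(k), CurvMax = max(k), CurvMin = min(k),
    CurvStd = pop_sd(k))
}
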