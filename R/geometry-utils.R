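# Low-level geometry helpers shared by the morphology and synthetic modules.
# All coordinates are mm; angles in radians unless a function says degrees.

#' Trapezoidal integration
#'
#' @param x strictly increasing abscissae
#' @param y values at `x` (vector) or a matrix with one row per `x`
#' @return the integral; a scalar for a vector `y`, one value per column for
#'   a matrix
#' @keywords internal
trapz_int <- function(x, y) {
  dx <- diff(x)
  if (is.matrix(y)) {
    colSums(dx * (y[-nrow(y), , drop = FALSE] + y[-1, , drop = FALSE]) / 2)
  } else {
    sum(dx * (y[-length(y)] + y[-1]) / 2)
  }
}

#' Euclidean norms of matrix rows
#' @keywords internal
row_norms <- function(m) sqrt(rowSums(m * m))

#' Polyline arc length
#' @param pts n x 3 (or n x 2) matrix of ordered points
#' @keywords internal
polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(row_norms(diff(pts)))
}

#' Least-squares plane through a point cloud
#'
#' @param pts n x 3 matrix, n >= 3
#' @return list with `centroid` and unit `normal` (smallest-variance axis).
#'   Errors when the points are collinear (no unique plane).
#' @keywords internal
fit_plane <- function(pts) {
  ctr <- colMeans(pts)
  x <- sweep(pts, 2, ctr)
  sv <- svd(x, nu = 0)
  if (sv$d[2] < max(sv$d[1], 1) * 1e-9) {
    stop("degenerate (collinear) point set: no unique plane", call. = FALSE)
  }
  list(centroid = ctr, normal = sv$v[, 3])
}

#' Rotation matrix sending unit vector `a` onto unit vector `b`
#' @keywords internal
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (c_ < -1 + 1e-12) {
    # opposite vectors: rotate pi about any axis orthogonal to a
    axis <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- axis - sum(axis * a) * a
    axis <- axis / sqrt(sum(axis^2))
    return(2 * outer(axis, axis) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Apply a rigid transform v' = R (v - centre) + shift
#' @keywords internal
apply_rigid <- function(pts, R, centre = c(0, 0, 0), shift = c(0, 0, 0)) {
  sweep(sweep(pts, 2, centre) %*% t(R), 2, shift, `+`)
}

#' Random rotation matrix (uniform via QR of Gaussian matrix)
#' @keywords internal
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Shoelace area of a planar polygon
#' @param xy n x 2 matrix of ordered vertices (not repeated at the end)
#' @keywords internal
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  i2 <- c(2:nrow(xy), 1)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

#' Closed polygon perimeter
#' @keywords internal
polygon_perimeter <- function(pts) {
  polyline_length(rbind(pts, pts[1, , drop = FALSE]))
}

#' Do two closed-polygon edges (excluding shared endpoints) intersect?
#' @keywords internal
polygon_self_intersects <- function(xy) {
  n <- nrow(xy)
  seg <- cbind(xy, xy[c(2:n, 1), , drop = FALSE])  # x1 y1 x2 y2
  cross2 <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    if (i == 1) js <- js[js != n]  # skip edges adjacent to edge 1
    if (!length(js)) next
    d1 <- cross2(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4],
                 seg[js, 1], seg[js, 2])
    d2 <- cross2(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4],
                 seg[js, 3], seg[js, 4])
    d3 <- cross2(seg[js, 1], seg[js, 2], seg[js, 3], seg[js, 4],
                 rep(seg[i, 1], length(js)), rep(seg[i, 2], length(js)))
    d4 <- cross2(seg[js, 1], seg[js, 2], seg[js, 3], seg[js, 4],
                 rep(seg[i, 3], length(js)), rep(seg[i, 4], length(js)))
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Minimal width of a planar point set (rotating calipers)
#'
#' Exact minimal caliper width: the minimum over convex-hull edges of the
#' maximal point distance to the edge's supporting line.
#' @param xy n x 2 matrix
#' @keywords internal
min_caliper_width <- function(xy) {
  h <- grDevices::chull(xy)
  hp <- xy[h, , drop = FALSE]
  n <- nrow(hp)
  widths <- vapply(seq_len(n), function(i) {
    a <- hp[i, ]; b <- hp[if (i == n) 1 else i + 1, ]
    e <- b - a
    len <- sqrt(sum(e^2))
    if (len < 1e-12) return(Inf)
    nrm <- c(-e[2], e[1]) / len
    d <- (hp[, 1] - a[1]) * nrm[1] + (hp[, 2] - a[2]) * nrm[2]
    max(d) - min(d)
  }, numeric(1))
  min(widths)
}

#' Maximal pairwise distance (diameter) of a point set
#' @param pts n x d matrix
#' @keywords internal
max_pairwise_distance <- function(pts) {
  if (nrow(pts) > 3 && ncol(pts) == 2) {
    pts <- pts[grDevices::chull(pts), , drop = FALSE]
  }
  max(stats::dist(pts))
}

#' Distance from points to a closed polygon boundary (3D polyline segments)
#' @keywords internal
min_dist_point_to_polygon <- function(p, poly) {
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  ab <- b - a
  ap <- sweep(-a, 2, p, `+`)
  tt <- rowSums(ap * ab) / pmax(rowSums(ab * ab), 1e-300)
  tt <- pmin(pmax(tt, 0), 1)
  proj <- a + ab * tt
  min(row_norms(sweep(proj, 2, p)))
}

#' Resample a polyline at (approximately) uniform spacing
#'
#' @param pts n x 3 ordered points
#' @param spacing target spacing in the same units as `pts`
#' @return m x 3 matrix including both endpoints
#' @keywords internal
resample_polyline <- function(pts, spacing = 0.5) {
  seglen <- row_norms(diff(pts))
  s <- c(0, cumsum(seglen))
  total <- s[length(s)]
  if (total <= spacing) return(pts[c(1, nrow(pts)), , drop = FALSE])
  m <- max(2L, as.integer(round(total / spacing)) + 1L)
  si <- seq(0, total, length.out = m)
  out <- vapply(1:3, function(k) approx(s, pts[, k], xout = si)$y,
                numeric(m))
  matrix(out, ncol = 3)
}

#' Moving-average smoothing of a polyline, endpoints fixed
#' @param window odd window size (default 5)
#' @keywords internal
smooth_polyline <- function(pts, window = 5L) {
  n <- nrow(pts)
  if (n <= window) return(pts)
  half <- window %/% 2L
  out <- pts
  for (i in 2:(n - 1)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i, ] <- colMeans(pts[lo:hi, , drop = FALSE])
  }
  out
}
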