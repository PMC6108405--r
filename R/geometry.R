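#' Convert spherical scanner coordinates to Cartesian
#'
#' The frame is right-handed with origin at the optical centre and z up:
#' zenith 0 deg points along +z, zenith 90 deg lies in the horizontal
#' optical plane, and azimuth is measured counterclockwise from +x.
#'
#' @param distance_m Range(s) in metres, strictly positive.
#' @param zenith_deg Zenith angle(s) in degrees, 0 = up.
#' @param azimuth_deg Azimuth angle(s) in degrees.
#'
#' @return A tibble with columns `x`, `y`, `z` (metres).
#' @export
#'
#' @examples
#' spherical_to_cartesian(5, 90, 0)   # (5, 0, 0)
#' spherical_to_cartesian(5, 0, 123)  # (0, 0, 5)
spherical_to_cartesian <- function(distance_m, zenith_deg, azimuth_deg) {
  if (any(is.na(distance_m)) || any(distance_m <= 0)) {
    stop_validation("distance_m must be strictly positive")
  }
  zen <- zenith_deg * pi / 180
  az <- azimuth_deg * pi / 180
  tibble::tibble(
    x = distance_m * sin(zen) * cos(az),
    y = distance_m * sin(zen) * sin(az),
    z = distance_m * cos(zen)
  )
}

#' @rdname spherical_to_cartesian
#' @param x,y,z Cartesian coordinates in metres.
#' @return `cartesian_to_spherical()` returns a tibble with columns
#'   `distance_m`, `zenith_deg`, `azimuth_deg` (azimuth in `[0, 360)`).
#' @export
cartesian_to_spherical <- function(x, y, z) {
  d <- sqrt(x^2 + y^2 + z^2)
  if (any(d <= 0)) stop_validation("point at the origin has no direction")
  zen <- acos(pmin(1, pmax(-1, z / d))) * 180 / pi
  az <- atan2(y, x) * 180 / pi
  az <- ifelse(az < 0, az + 360, az)
  az <- ifelse(az >= 360, az - 360, az)
  tibble::tibble(distance_m = d, zenith_deg = zen, azimuth_deg = az)
}

# Signed shoelace area of a polygon given vertex coordinates in order.
# Returns |sum|/2; the polygon is closed implicitly (last joins first).
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))     # previous index
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Area of the convex hull of 2-D points (shoelace on grDevices::chull order).
convex_hull_area <- function(x, y) {
  keep <- grDevices::chull(x, y)
  if (length(keep) < 3) return(0)
  polygon_area(x[keep], y[keep])
}

# Area of a 3-D triangle from its vertex coordinates (cross-product norm / 2).
triangle_area_3d <- function(p1, p2, p3) {
  u <- p2 - p1
  v <- p3 - p1
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  sqrt(sum(cr^2)) / 2
}

# Delaunay triangulation of 2-D points, as a matrix of vertex indices
# (one triangle per row). Wraps interp::tri.mesh (Fortran, fast on the
# thousands of points in a zenith band); collinear inputs yield zero rows.
delaunay_triangles <- function(x, y) {
  if (length(x) < 3) return(matrix(integer(0), ncol = 3))
  # collinear projections have no triangulation
  if (qr(cbind(x - mean(x), y - mean(y)))$rank < 2) {
    return(matrix(integer(0), ncol = 3))
  }
  tri <- tryCatch(
    suppressWarnings(interp::triangles(interp::tri.mesh(x, y))[, 1:3, drop = FALSE]),
    error = function(e) NULL
  )
  if (is.null(tri)) {
    # highly regular (cocircular) configurations can defeat the sweep-hull;
    # fall back to deldir, which is slower but robust
    tri <- tryCatch(
      deldir::triMat(deldir::deldir(x, y, suppressMsge = TRUE)),
      error = function(e) matrix(integer(0), ncol = 3)
    )
  }
  tri
}

# Total area of the triangulated surface lifted to z, and of its 2-D
# footprint (convex hull). Used by the rugosity metaproperty. Coincident
# (x, y) projections are collapsed to their first occurrence.
triangulated_areas <- function(x, y, z) {
  keep <- !duplicated(cbind(x, y))
  x <- x[keep]; y <- y[keep]; z <- z[keep]
  tri <- delaunay_triangles(x, y)
  if (nrow(tri) == 0) {
    return(list(area_3d = 0, area_2d = 0, n_triangles = 0L))
  }
  # vectorized cross-product over all triangles
  u1 <- x[tri[, 2]] - x[tri[, 1]]; v1 <- x[tri[, 3]] - x[tri[, 1]]
  u2 <- y[tri[, 2]] - y[tri[, 1]]; v2 <- y[tri[, 3]] - y[tri[, 1]]
  u3 <- z[tri[, 2]] - z[tri[, 1]]; v3 <- z[tri[, 3]] - z[tri[, 1]]
  cx <- u2 * v3 - u3 * v2
  cy <- u3 * v1 - u1 * v3
  cz <- u1 * v2 - u2 * v1
  a3 <- sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
  list(area_3d = a3, area_2d = convex_hull_area(x, y),
       n_triangles = nrow(tri))
}
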