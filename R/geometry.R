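# Planar geometry and the local projection. All analysis runs in a
# colony-centred azimuthal equidistant plane (km); lon/lat only at the
# file boundary.

.EARTH_RADIUS_KM <- 6371.0088

#' Project lon/lat to a colony-centred azimuthal equidistant plane
#'
#' Distances from the projection centre are exact great-circle distances,
#' so step lengths in km near the colony are well defined.
#'
#' @param lon,lat WGS84 degrees.
#' @param lon0,lat0 projection centre (colony) in degrees.
#' @return list with numeric vectors `x`, `y` in km.
#' @export
aeqd_project <- function(lon, lat, lon0, lat0) {
  p <- pi / 180
  phi <- lat * p; lam <- lon * p
  phi0 <- lat0 * p; lam0 <- lon0 * p
  dl <- lam - lam0
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(dl)
  cosc <- pmin(1, pmax(-1, cosc))
  cc <- acos(cosc)
  k <- ifelse(cc < 1e-12, 1, cc / sin(cc))
  list(
    x = .EARTH_RADIUS_KM * k * cos(phi) * sin(dl),
    y = .EARTH_RADIUS_KM * k *
      (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(dl))
  )
}

#' Inverse azimuthal equidistant projection
#'
#' @param x,y plane coordinates in km.
#' @param lon0,lat0 projection centre in degrees.
#' @return list with numeric vectors `lon`, `lat` in degrees.
#' @export
aeqd_unproject <- function(x, y, lon0, lat0) {
  p <- pi / 180
  phi0 <- lat0 * p; lam0 <- lon0 * p
  rho <- sqrt(x^2 + y^2)
  cc <- rho / .EARTH_RADIUS_KM
  sinc <- sin(cc); cosc <- cos(cc)
  phi <- ifelse(rho < 1e-12, phi0,
                asin(cosc * sin(phi0) + y * sinc * cos(phi0) / rho))
  lam <- ifelse(rho < 1e-12, lam0,
                lam0 + atan2(x * sinc,
                             rho * cos(phi0) * cosc - y * sin(phi0) * sinc))
  list(lon = lam / p, lat = phi / p)
}

# Distance from points to a segment (a,b); all vectorized over points.
point_segment_distance <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  L2 <- vx^2 + vy^2
  t <- if (L2 < 1e-300) 0 else
    pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
  sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
}

# Even-odd ray casting point-in-polygon test. poly: matrix [n,2], open or
# closed ring.
point_in_polygon <- function(px, py, poly) {
  n0 <- nrow(poly)
  if (all(poly[1, ] == poly[n0, ])) poly <- poly[-n0, , drop = FALSE]
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Signed distance to a coastline polygon
#'
#' Euclidean distance in the projection plane from points to the polygon
#' boundary, positive offshore (outside the polygon) and negative on land.
#'
#' @param x,y point coordinates, km.
#' @param poly closed polygon matrix (n x 2), km.
#' @return numeric vector of signed distances, km.
#' @export
coast_distance <- function(x, y, poly) {
  n0 <- nrow(poly)
  ring <- if (all(poly[1, ] == poly[n0, ])) poly else rbind(poly, poly[1, ])
  d <- rep(Inf, length(x))
  for (i in seq_len(nrow(ring) - 1)) {
    d <- pmin(d, point_segment_distance(
      x, y, ring[i, 1], ring[i, 2], ring[i + 1, 1], ring[i + 1, 2]))
  }
  inside <- point_in_polygon(x, y, poly)
  ifelse(inside, -d, d)
}
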