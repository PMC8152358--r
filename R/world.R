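#' Construct a simulation world
#'
#' The world is a self-contained tropical seascape: a colony position, a single
#' island coastline polygon and a synthetic bathymetry raster on a regular
#' km grid. The bathymetry deepens smoothly with distance from the coast
#' (positive-down metres, declared in metadata), emulating a narrow-shelf
#' oceanic island.
#'
#' @param colony_lon,colony_lat colony position, WGS84 degrees.
#' @param island_semi_axes semi-axes (km) of the elliptical island.
#' @param extent_km half-width of the bathymetry raster, km; must exceed
#'   the maximum simulated foraging range.
#' @param grid_res_km raster resolution, km.
#' @param shelf_scale_km e-folding scale of depth increase offshore, km.
#' @param max_depth_m asymptotic basin depth, m.
#' @return object of class `cpf_world`: colony lon/lat, coastline polygon
#'   in projected km (closed ring), bathymetry raster (`x`, `y`, `z`
#'   positive-down metres; NA on land), and grid resolution.
#' @export
cpf_world <- function(colony_lon = -79.80, colony_lat = 19.70,
                      island_semi_axes = c(15, 4),
                      extent_km = 150, grid_res_km = 1,
                      shelf_scale_km = 8, max_depth_m = 1800) {
  th <- seq(0, 2 * pi, length.out = 121)
  poly <- cbind(island_semi_axes[1] * cos(th), island_semi_axes[2] * sin(th))
  # colony sits at the plane origin; ensure it is inside the island
  stopifnot(point_in_polygon(0, 0, poly))
  gx <- seq(-extent_km, extent_km, by = grid_res_km)
  gy <- gx
  pts <- expand.grid(x = gx, y = gy)
  d <- coast_distance(pts$x, pts$y, poly)
  z <- ifelse(d <= 0, NA_real_,
              30 + (max_depth_m - 30) * (1 - exp(-d / shelf_scale_km)))
  structure(list(
    colony = c(lon = colony_lon, lat = colony_lat),
    coastline = poly,
    bathymetry = list(x = gx, y = gy,
                      z = matrix(z, nrow = length(gx)),
                      convention = "positive_down_m"),
    grid_resolution = grid_res_km
  ), class = "cpf_world")
}

#' Sample bathymetry under points
#'
#' Bilinear interpolation of the world's depth raster; NA over land or
#' outside the raster.
#'
#' @param world a [cpf_world()].
#' @param x,y projected coordinates, km.
#' @return depths, positive-down metres.
#' @export
bathy_at <- function(world, x, y) {
  b <- world$bathymetry
  nx <- length(b$x); ny <- length(b$y)
  dx <- b$x[2] - b$x[1]
  fi <- (x - b$x[1]) / dx
  fj <- (y - b$y[1]) / dx
  i <- floor(fi); j <- floor(fj)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(i) & i >= 0 & i <= nx - 2 & j >= 0 & j <= ny - 2
  if (any(ok)) {
    i1 <- i[ok] + 1; j1 <- j[ok] + 1
    u <- fi[ok] - i[ok]; v <- fj[ok] - j[ok]
    z00 <- b$z[cbind(i1, j1)];     z10 <- b$z[cbind(i1 + 1, j1)]
    z01 <- b$z[cbind(i1, j1 + 1)]; z11 <- b$z[cbind(i1 + 1, j1 + 1)]
    out[ok] <- (1 - u) * (1 - v) * z00 + u * (1 - v) * z10 +
      (1 - u) * v * z01 + u * v * z11
  }
  out
}

# project lon/lat columns of a data frame into the world plane
world_project <- function(world, lon, lat) {
  aeqd_project(lon, lat, world$colony[["lon"]], world$colony[["lat"]])
}

world_unproject <- function(world, x, y) {
  aeqd_unproject(x, y, world$colony[["lon"]], world$colony[["lat"]])
}
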