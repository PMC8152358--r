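# Kernel utilization distributions on the projection plane: LSCV
# bandwidth selection for a full bivariate Gaussian kernel, gridded
# density surfaces, greedy isopleth masks and Bhattacharyya overlap,
# plus 5 x 5 km summary grids for dive rates and event counts.

#' Least-squares cross-validated bandwidth matrix
#'
#' Minimizes the LSCV criterion for a bivariate Gaussian kernel over
#' symmetric positive-definite matrices via a Cholesky parameterization,
#' started at the normal-reference bandwidth `n^(-1/3) * S`. When the
#' criterion is degenerate (the known LSCV pathology with duplicated
#' points driving H to zero), the reference bandwidth is returned with a
#' warning and attribute `fallback = TRUE`.
#'
#' @param points matrix or data.frame with columns x, y (km); >= 10
#'   distinct rows required.
#' @return 2x2 bandwidth matrix with attributes `fallback` and `crit`
#'   (criterion value at the returned H).
#' @export
lscv_bandwidth <- function(points) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  n <- nrow(pts)
  if (n < 10) stop("need at least 10 points for LSCV")
  if (all(apply(pts, 2, function(c) diff(range(c))) == 0))
    stop("all points identical")
  href <- cov(pts) * n^(-1 / 3)
  crit <- function(h) cpp_lscv_crit(pts[, 1], pts[, 2], solve(h), det(h))
  # Cholesky parameterization: H = L L', L = [[exp(a), 0], [b, exp(c)]]
  to_h <- function(p) {
    L <- matrix(c(exp(p[1]), p[2], 0, exp(p[3])), 2, 2)
    L %*% t(L)
  }
  L0 <- t(chol(href))
  p0 <- c(log(L0[1, 1]), L0[2, 1], log(L0[2, 2]))
  fit <- try(optim(p0, function(p) crit(to_h(p)), method = "Nelder-Mead",
                   control = list(maxit = 500, reltol = 1e-10)),
             silent = TRUE)
  degenerate <- inherits(fit, "try-error") || !is.finite(fit$value)
  if (!degenerate) {
    h <- to_h(fit$par)
    # H collapsing far below reference signals the duplicated-point
    # pathology: the criterion decreases without bound as H -> 0.
    shrink <- det(h) / det(href)
    if (shrink < 1e-4 || (anyDuplicated(pts) && shrink < 0.05) ||
        fit$value > crit(href) + 1e-12)
      degenerate <- TRUE
  }
  if (degenerate) {
    warning("LSCV criterion degenerate; falling back to reference bandwidth")
    h <- href
  }
  structure(h, fallback = degenerate, crit = crit(h))
}

#' Kernel density surface on a regular grid
#'
#' Bivariate Gaussian-kernel density with a full bandwidth matrix,
#' evaluated on a regular grid and renormalized so the discrete integral
#' over the grid equals 1.
#'
#' @param points matrix/data.frame of x, y (km).
#' @param bandwidth 2x2 SPD bandwidth matrix (e.g. [lscv_bandwidth()]).
#' @param grid_spec list with `xlim`, `ylim`, `n` (grid nodes per axis,
#'   default 512); NULL derives limits from the points with a 3.5-sd
#'   kernel margin. Supplied grids must cover the points with at least a
#'   3-sd margin.
#' @return object of class `cpf_density`: `x`, `y` node vectors, `z`
#'   density matrix (length(x) rows), `cell_area` km^2, `bandwidth`.
#' @export
kde_surface <- function(points, bandwidth, grid_spec = NULL) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  sdx <- sqrt(bandwidth[1, 1]); sdy <- sqrt(bandwidth[2, 2])
  if (is.null(grid_spec)) {
    grid_spec <- list(
      xlim = range(pts[, 1]) + c(-3.5, 3.5) * sdx,
      ylim = range(pts[, 2]) + c(-3.5, 3.5) * sdy,
      n = 512)
  }
  if (min(pts[, 1]) - grid_spec$xlim[1] < 3 * sdx ||
      grid_spec$xlim[2] - max(pts[, 1]) < 3 * sdx ||
      min(pts[, 2]) - grid_spec$ylim[1] < 3 * sdy ||
      grid_spec$ylim[2] - max(pts[, 2]) < 3 * sdy)
    stop("grid does not cover the points with a 3-bandwidth-sd margin")
  gx <- seq(grid_spec$xlim[1], grid_spec$xlim[2], length.out = grid_spec$n)
  gy <- seq(grid_spec$ylim[1], grid_spec$ylim[2], length.out = grid_spec$n)
  z <- cpp_kde_grid(pts[, 1], pts[, 2], gx, gy,
                    solve(bandwidth), det(bandwidth))
  cell <- (gx[2] - gx[1]) * (gy[2] - gy[1])
  z <- z / (sum(z) * cell)
  structure(list(x = gx, y = gy, z = z, cell_area = cell,
                 bandwidth = bandwidth), class = "cpf_density")
}

#' Isopleth mask of a density surface
#'
#' Greedy inclusion of grid cells in order of descending density until
#' the cumulative probability mass reaches the level: the minimal-area
#' highest-density region on the grid. Level 0.5 is the core area, 0.9
#' the main foraging area.
#'
#' @param surface a [kde_surface()].
#' @param level mass level in (0, 1).
#' @return list: `mask` (logical matrix), `area_km2`, `level`.
#' @export
isopleth <- function(surface, level) {
  if (level <= 0 || level >= 1) stop("isopleth level must be in (0, 1)")
  p <- as.vector(surface$z) * surface$cell_area
  o <- order(p, decreasing = TRUE)
  cum <- cumsum(p[o])
  k <- which(cum >= level)[1]
  if (is.na(k)) k <- length(p)
  mask <- logical(length(p))
  mask[o[seq_len(k)]] <- TRUE
  list(mask = matrix(mask, nrow = length(surface$x)),
       area_km2 = k * surface$cell_area, level = level)
}

#' Bhattacharyya affinity between two density surfaces
#'
#' BA = sum over cells of sqrt(p_i * q_i) with p, q the per-cell masses.
#' With `level` given, each density is first restricted to its own
#' level-isopleth mask and renormalized (the contour-overlap statistic);
#' `level = NULL` compares the full utilization distributions.
#'
#' @param surface_a,surface_b [kde_surface()] objects on identical grids.
#' @param level optional isopleth level in (0, 1).
#' @return scalar in \[0, 1\].
#' @export
bhattacharyya_overlap <- function(surface_a, surface_b, level = NULL) {
  if (!isTRUE(all.equal(surface_a$x, surface_b$x)) ||
      !isTRUE(all.equal(surface_a$y, surface_b$y)))
    stop("surfaces are not on identical grids")
  p <- as.vector(surface_a$z) * surface_a$cell_area
  q <- as.vector(surface_b$z) * surface_b$cell_area
  if (!is.null(level)) {
    ma <- as.vector(isopleth(surface_a, level)$mask)
    mb <- as.vector(isopleth(surface_b, level)$mask)
    p <- p * ma; q <- q * mb
    if (sum(p) == 0 || sum(q) == 0) return(0)
    p <- p / sum(p); q <- q / sum(q)
  }
  min(1, sum(sqrt(p * q)))
}

#' Per-cell summary grid (5 x 5 km by default)
#'
#' Assigns fixes to square cells anchored at the colony origin and
#' returns the per-cell mean of a value (e.g. dive rate) or the per-cell
#' sum (event counts). Cells with no fixes are absent, not zero.
#'
#' @param x,y fix coordinates, km.
#' @param values numeric values at fixes (for `mode = "sum"`, counts).
#' @param cell_km cell side, km.
#' @param mode `"mean"` or `"sum"`.
#' @param origin grid anchor (colony), km.
#' @return data.frame `cell_x`, `cell_y` (cell lower-left corners, km),
#'   `value`, `n`.
#' @export
grid_rate_map <- function(x, y, values, cell_km = 5,
                          mode = c("mean", "sum"), origin = c(0, 0)) {
  mode <- match.arg(mode)
  ix <- floor((x - origin[1]) / cell_km)
  iy <- floor((y - origin[2]) / cell_km)
  key <- paste(ix, iy, sep = ":")
  fun <- if (mode == "mean") mean else sum
  agg <- tapply(values, key, fun)
  cnt <- tapply(values, key, length)
  parts <- do.call(rbind, strsplit(names(agg), ":", fixed = TRUE))
  data.frame(
    cell_x = as.numeric(parts[, 1]) * cell_km + origin[1],
    cell_y = as.numeric(parts[, 2]) * cell_km + origin[2],
    value = as.numeric(agg), n = as.integer(cnt), row.names = NULL)
}
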