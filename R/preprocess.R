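# GPS preprocessing: speed filtering, central-place trip segmentation and
# regularization to a constant time step with a shape-preserving cubic
# Hermite (PCHIP) interpolant.

#' Filter implausible ground speeds
#'
#' Forward scan: a fix whose implied speed from the last retained fix
#' exceeds `vmax` is removed and the scan recomputes from the retained
#' predecessor, iterating until no implied speed exceeds the threshold.
#' The default 95 km/h matches reported instantaneous flight-speed limits
#' for sulids.
#'
#' @param fixes time-sorted data.frame with `timestamp`, `x`, `y` (km).
#' @param vmax speed threshold, km/h.
#' @return list: `fixes` (retained rows) and `removed` (original row
#'   indices that were dropped).
#' @export
speed_filter <- function(fixes, vmax = 95) {
  stopifnot(vmax > 0)
  n <- nrow(fixes)
  if (n < 2) return(list(fixes = fixes, removed = integer(0)))
  keep <- logical(n); keep[1] <- TRUE
  last <- 1L
  ts <- as.numeric(fixes$timestamp)
  for (i in 2:n) {
    dt_h <- (ts[i] - ts[last]) / 3600
    d_km <- sqrt((fixes$x[i] - fixes$x[last])^2 +
                   (fixes$y[i] - fixes$y[last])^2)
    if (dt_h > 0 && d_km / dt_h <= vmax) {
      keep[i] <- TRUE
      last <- i
    }
  }
  list(fixes = fixes[keep, , drop = FALSE], removed = which(!keep))
}

#' Segment a track into central-place foraging trips
#'
#' Contiguous runs of fixes beyond the colony radius become candidate
#' trips. Candidates whose boundary-crossing-to-crossing duration is below
#' `min_duration_min` are discarded (colony-based movements); runs that do
#' not re-enter the radius before the data end are flagged partial.
#' Complete trips keep one bounding within-radius fix on each side, so
#' their first and last fix lie inside the colony radius.
#'
#' @param fixes one bird's time-sorted fixes with `timestamp`, `x`, `y`
#'   (km, colony at the origin) and optionally `bird_id`.
#' @param radius_m colony radius, metres.
#' @param min_duration_min minimum trip duration, minutes.
#' @return object of class `cpf_trips`: list with `fixes` (rows assigned
#'   to trips, `trip_id` column added) and `summary` (one row per trip:
#'   departure/arrival times, completeness, duration in hours).
#' @export
segment_trips <- function(fixes, radius_m = 500, min_duration_min = 30) {
  bird <- if ("bird_id" %in% names(fixes)) fixes$bird_id[1] else "bird"
  n <- nrow(fixes)
  r_km <- radius_m / 1000
  outside <- sqrt(fixes$x^2 + fixes$y^2) > r_km
  runs <- rle(outside)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  fix_list <- list(); sum_list <- list(); k <- 0L
  for (i in seq_along(runs$values)) {
    if (!runs$values[i]) next
    s <- starts[i]; e <- ends[i]
    complete <- e < n
    dep <- fixes$timestamp[s]
    arr <- if (complete) fixes$timestamp[e + 1] else NA
    dur_min <- if (complete)
      as.numeric(difftime(arr, dep, units = "mins"))
    else as.numeric(difftime(fixes$timestamp[e], dep, units = "mins"))
    if (dur_min < min_duration_min) next
    k <- k + 1L
    idx <- seq(max(1, s - 1), if (complete) e + 1 else e)
    tf <- fixes[idx, , drop = FALSE]
    tf$trip_id <- sprintf("%s_T%02d", bird, k)
    fix_list[[k]] <- tf
    sum_list[[k]] <- data.frame(
      trip_id = tf$trip_id[1], bird_id = bird,
      departure_time = dep, arrival_time = arr, complete = complete,
      n_fixes = nrow(tf), duration_h = dur_min / 60,
      stringsAsFactors = FALSE)
  }
  structure(list(
    fixes = if (k) do.call(rbind, fix_list) else cbind(fixes[0, ],
                                                       trip_id = character(0)),
    summary = if (k) do.call(rbind, sum_list) else data.frame()
  ), class = "cpf_trips")
}

# PCHIP (Fritsch-Carlson) endpoint-adjusted derivative estimates
pchip_slopes <- function(x, y) {
  n <- length(x)
  h <- diff(x); m <- diff(y) / h
  d <- numeric(n)
  if (n == 2) return(rep(m, 2))
  for (k in 2:(n - 1)) {
    if (m[k - 1] * m[k] <= 0) d[k] <- 0
    else {
      w1 <- 2 * h[k] + h[k - 1]
      w2 <- h[k] + 2 * h[k - 1]
      d[k] <- (w1 + w2) / (w1 / m[k - 1] + w2 / m[k])
    }
  }
  edge <- function(h1, h2, m1, m2) {
    dd <- ((2 * h1 + h2) * m1 - h1 * m2) / (h1 + h2)
    if (sign(dd) != sign(m1)) 0
    else if (sign(m1) != sign(m2) && abs(dd) > 3 * abs(m1)) 3 * m1
    else dd
  }
  d[1] <- edge(h[1], h[2], m[1], m[2])
  d[n] <- edge(h[n - 1], h[n - 2], m[n - 1], m[n - 2])
  d
}

# evaluate the cubic Hermite interpolant with knots (x, y) and slopes d
pchip_eval <- function(x, y, d, xout) {
  i <- findInterval(xout, x, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1), length(x) - 1)
  h <- x[i + 1] - x[i]
  t <- (xout - x[i]) / h
  h00 <- (1 + 2 * t) * (1 - t)^2
  h10 <- t * (1 - t)^2
  h01 <- t^2 * (3 - 2 * t)
  h11 <- t^2 * (t - 1)
  h00 * y[i] + h10 * h * d[i] + h01 * y[i + 1] + h11 * h * d[i + 1]
}

#' Regularize a trip to a constant time step
#'
#' x(t) and y(t) are interpolated independently with a shape-preserving
#' piecewise cubic Hermite scheme (Fritsch-Carlson slopes) on the
#' projected plane. The output grid starts at the trip's first fix (or a
#' supplied start time) and never extrapolates beyond the last fix;
#' original knots are reproduced exactly.
#'
#' @param trip one trip's fixes: `timestamp`, `x`, `y`; >= 2 rows.
#' @param dt_s output time step, seconds.
#' @param start optional POSIXct grid origin (e.g. departure time).
#' @return data.frame `timestamp`, `x`, `y` on the regular grid, plus any
#'   constant `bird_id`/`trip_id` columns carried through.
#' @export
interpolate_track <- function(trip, dt_s = 30, start = NULL) {
  stopifnot(nrow(trip) >= 2)
  tt <- as.numeric(trip$timestamp)
  if (anyDuplicated(tt)) {
    dup <- which(duplicated(tt))
    stop("duplicate timestamps at fixes: ", paste(dup, collapse = ", "))
  }
  t0 <- if (is.null(start)) tt[1] else as.numeric(start)
  grid <- seq(t0, tt[length(tt)], by = dt_s)
  grid <- grid[grid >= tt[1]]
  dx <- pchip_slopes(tt, trip$x)
  dy <- pchip_slopes(tt, trip$y)
  out <- data.frame(
    timestamp = as.POSIXct(grid, origin = "1970-01-01", tz = "UTC"),
    x = pchip_eval(tt, trip$x, dx, grid),
    y = pchip_eval(tt, trip$y, dy, grid))
  for (col in c("bird_id", "trip_id"))
    if (col %in% names(trip)) out[[col]] <- trip[[col]][1]
  out
}

#' Departure and arrival clock times in local solar time
#'
#' Converts per-trip departure/arrival UTC instants to hour-of-day in
#' local solar time (UTC + longitude / 15 h). Partial trips get a missing
#' arrival.
#'
#' @param trip_summary the `summary` element of [segment_trips()].
#' @param lon longitude (degrees) defining local solar time.
#' @return the summary with `departure_local_h` and `arrival_local_h`
#'   columns (hours in \[0, 24)).
#' @export
departure_arrival_times <- function(trip_summary, lon) {
  off_h <- lon / 15
  tod <- function(t) {
    s <- as.numeric(t) %% 86400 / 3600
    (s + off_h) %% 24
  }
  trip_summary$departure_local_h <- tod(trip_summary$departure_time)
  trip_summary$arrival_local_h <-
    ifelse(trip_summary$complete, tod(trip_summary$arrival_time), NA_real_)
  trip_summary
}
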