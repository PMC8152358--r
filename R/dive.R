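# Time-depth-recorder processing: moving-quantile zero-offset correction,
# threshold dive detection, and matching of point events (dives,
# immersion samples) to centred 30 s track segments.

#' Zero-offset correct a 1 Hz depth trace
#'
#' Subtracts a rolling lower-quantile baseline from the raw depth so the
#' surface reads 0 m despite pressure-sensor drift; corrected values are
#' floored at 0. Defaults (600 s window, 0.05 quantile) assume dives much
#' shorter than the window, as for surface-feeding sulids (dive durations
#' of seconds).
#'
#' @param trace data.frame with `timestamp` (1 Hz) and `depth_m` (raw,
#'   positive down).
#' @param window_s rolling window, seconds (>= 60).
#' @param quantile baseline quantile in (0, 0.5].
#' @return the trace with a `corrected_m` column added.
#' @export
zero_offset_correct <- function(trace, window_s = 600, quantile = 0.05) {
  stopifnot(window_s >= 60, quantile > 0, quantile <= 0.5)
  if (nrow(trace) < window_s)
    stop("trace shorter than the ZOC window (", window_s, " s)")
  base <- cpp_rolling_quantile(trace$depth_m, as.integer(window_s), quantile)
  # a lower quantile of a drifting window estimates the baseline at the
  # window position q, not at its centre; shift by (0.5 - q) * window so
  # a linear drift is removed without lag bias
  off <- round((0.5 - quantile) * window_s)
  n <- nrow(trace)
  base <- base[pmin(seq_len(n) + off, n)]
  trace$corrected_m <- pmax(trace$depth_m - base, 0)
  trace
}

#' Detect dives in a corrected depth trace
#'
#' Maximal contiguous runs of samples deeper than the threshold become
#' dives, with start/end at the threshold crossings and per-dive maximum
#' depth and duration.
#'
#' @param trace output of [zero_offset_correct()] (uses `corrected_m`).
#' @param threshold_m dive threshold; depth must exceed it (> 0.25 m by
#'   default, so a 0.20 m excursion is not a dive).
#' @return data.frame `start`, `end`, `max_depth_m`, `duration_s` (one
#'   row per dive; zero rows when none).
#' @export
detect_dives <- function(trace, threshold_m = 0.25) {
  dep <- if ("corrected_m" %in% names(trace)) trace$corrected_m
  else trace$depth_m
  under <- dep > threshold_m
  if (!any(under)) return(empty_dive_table())
  r <- rle(under)
  e <- cumsum(r$lengths); s <- e - r$lengths + 1
  s <- s[r$values]; e <- e[r$values]
  data.frame(
    start = trace$timestamp[s], end = trace$timestamp[e],
    max_depth_m = vapply(seq_along(s),
                         function(i) max(dep[s[i]:e[i]]), 0.0),
    duration_s = as.numeric(trace$timestamp[e]) -
      as.numeric(trace$timestamp[s]) + 1)
}

# nearest-fix index for event times under centred windows of width dt_s;
# exact boundary ties go to the earlier fix; NA outside the track span.
match_times_to_fixes <- function(times, fix_times, dt_s) {
  t0 <- as.numeric(fix_times[1])
  rel <- (as.numeric(times) - t0) / dt_s
  idx <- as.integer(ceiling(rel - 0.5) + 1)
  n <- length(fix_times)
  idx[idx < 1 | idx > n] <- NA_integer_
  # reject events farther than half a window from their fix (gappy tracks)
  off <- abs(as.numeric(times) - as.numeric(fix_times[pmax(idx, 1)]))
  idx[!is.na(idx) & off > dt_s / 2 + 1e-9] <- NA_integer_
  idx
}

#' Match events to centred track segments
#'
#' Each event is assigned to the fix whose centred `dt_s` window contains
#' its start time (boundary ties to the earlier fix). Events outside the
#' track's temporal span are reported unmatched. Also returns per-fix
#' event counts and the whole-track event rate per hour.
#'
#' @param events data.frame with a `start` (or `timestamp`) column.
#' @param fixes regularized track with `timestamp`.
#' @param dt_s segment width, seconds (the track's step).
#' @return list: `events` (input + `fix_index`, NA if unmatched),
#'   `per_fix` (fix_index, n), `n_unmatched`, `rate_h`.
#' @export
match_to_track <- function(events, fixes, dt_s = 30) {
  tcol <- if ("start" %in% names(events)) "start" else "timestamp"
  idx <- match_times_to_fixes(events[[tcol]], fixes$timestamp, dt_s)
  events$fix_index <- idx
  span_h <- (as.numeric(fixes$timestamp[nrow(fixes)]) -
               as.numeric(fixes$timestamp[1])) / 3600
  tab <- table(idx)
  list(events = events,
       per_fix = data.frame(fix_index = as.integer(names(tab)),
                            n = as.integer(tab)),
       n_unmatched = sum(is.na(idx)),
       rate_h = if (span_h > 0) sum(!is.na(idx)) / span_h else NA_real_)
}

#' Parse an immersion log into wet/dry intervals
#'
#' @param log data.frame with `timestamp` and `state` in `{wet, dry}`.
#' @param resolution_s sampling resolution of the logger, seconds.
#' @param type `"samples"` (regular records every `resolution_s`; the
#'   default, as written by the simulator) or `"transitions"`
#'   (state-change events; consecutive identical states are merged with a
#'   warning).
#' @return data.frame of intervals: `start`, `end`, `state`,
#'   `duration_s`. For sample logs total wet time equals
#'   (number of wet records) x resolution.
#' @export
parse_immersion <- function(log, resolution_s = 6,
                            type = c("samples", "transitions")) {
  type <- match.arg(type)
  if (nrow(log) == 0)
    return(data.frame(start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      state = character(0), duration_s = numeric(0)))
  if (type == "transitions") {
    same <- c(FALSE, log$state[-1] == log$state[-nrow(log)])
    if (any(same)) {
      warning("merged ", sum(same),
              " consecutive identical states in transition log")
      log <- log[!same, , drop = FALSE]
    }
    ends <- c(log$timestamp[-1], log$timestamp[nrow(log)] + resolution_s)
    return(data.frame(start = log$timestamp, end = ends, state = log$state,
                      duration_s = as.numeric(ends) -
                        as.numeric(log$timestamp)))
  }
  r <- rle(log$state)
  e <- cumsum(r$lengths); s <- e - r$lengths + 1
  data.frame(start = log$timestamp[s],
             end = log$timestamp[s] + r$lengths * resolution_s,
             state = r$values,
             duration_s = r$lengths * resolution_s,
             stringsAsFactors = FALSE)
}
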