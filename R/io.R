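# Flat-file interfaces: CSV streams as produced by field loggers (or the
# simulator) and JSON sidecars for parameters and reports.

iso8601 <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
parse_time <- function(s) as.POSIXct(s, tz = "UTC",
                                     tryFormats = c("%Y-%m-%dT%H:%M:%OSZ",
                                                    "%Y-%m-%dT%H:%M:%OS",
                                                    "%Y-%m-%d %H:%M:%OS"))

#' Write / read GPS fix tables
#'
#' Columns `bird_id`, `timestamp` (ISO-8601 UTC), `lon`, `lat`. The
#' reader tolerates extra columns and, given a world, adds projected
#' `x`, `y` km columns.
#'
#' @param tracks data.frame of fixes.
#' @param path CSV path.
#' @rdname gps_csv
#' @export
write_gps_csv <- function(tracks, path) {
  out <- tracks
  out$timestamp <- iso8601(out$timestamp)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @param world optional [cpf_world()] used to project coordinates.
#' @rdname gps_csv
#' @export
read_gps_csv <- function(path, world = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  d$timestamp <- parse_time(d$timestamp)
  d <- d[order(if ("bird_id" %in% names(d)) d$bird_id else 0,
               d$timestamp), , drop = FALSE]
  if (!is.null(world) && !all(c("x", "y") %in% names(d))) {
    xy <- world_project(world, d$lon, d$lat)
    d$x <- xy$x; d$y <- xy$y
  }
  rownames(d) <- NULL
  d
}

#' Write a complete simulated dataset to a directory
#'
#' Emits every stream the pipeline consumes: `gps.csv` (with the hidden
#' truth state as a sidecar `gps_truth.csv`), per-bird `depth_*.csv` and
#' `immersion_*.csv` for the first `n_sensor` birds, `events.csv`,
#' `isotopes.csv`, `prey.csv`, `morpho.csv` and a `truth.json` metadata
#' sidecar (depth convention positive-down metres).
#'
#' @param world a [cpf_world()]; @param truth a [cpf_truth()].
#' @param dir output directory (created).
#' @param n_birds,trip_spec,seed,species forwarded to the generators.
#' @param n_sensor how many birds carry depth/immersion loggers.
#' @return invisible list of the generated objects.
#' @export
write_simulation <- function(world, truth, dir, n_birds = 4,
                             trip_spec = list(n_trips = 2, duration_h = 3,
                                              fix_interval_s = 30),
                             seed = 1L, species = "BB", n_sensor = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- generate_tracks(world, truth, n_birds, trip_spec, seed, species)
  write_gps_csv(sim$tracks[, c("bird_id", "timestamp", "lon", "lat")],
                file.path(dir, "gps.csv"))
  truthcsv <- sim$tracks[, c("bird_id", "timestamp", "state", "homing")]
  truthcsv$timestamp <- iso8601(truthcsv$timestamp)
  write.csv(truthcsv, file.path(dir, "gps_truth.csv"), row.names = FALSE)
  for (b in head(sim$birds$bird_id, n_sensor)) {
    st <- sim$tracks[sim$tracks$bird_id == b, c("timestamp", "state")]
    dv <- generate_dive_trace(st, truth, seed)
    tr <- dv$trace; tr$timestamp <- iso8601(tr$timestamp)
    write.csv(tr, file.path(dir, paste0("depth_", b, ".csv")),
              row.names = FALSE)
    im <- generate_immersion(st, truth, seed)
    im$timestamp <- iso8601(im$timestamp)
    write.csv(im, file.path(dir, paste0("immersion_", b, ".csv")),
              row.names = FALSE)
  }
  ip <- generate_isotope_and_prey(truth, seed = seed)
  write.csv(ip$isotopes, file.path(dir, "isotopes.csv"), row.names = FALSE)
  write.csv(ip$prey, file.path(dir, "prey.csv"), row.names = FALSE)
  km <- generate_klepto_and_morpho(truth, sim, seed)
  ev <- km$events
  if (nrow(ev)) { ev$start <- iso8601(ev$start); ev$end <- iso8601(ev$end) }
  write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  write.csv(km$morpho, file.path(dir, "morpho.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed, species = species, n_birds = n_birds,
         trip_spec = trip_spec, depth_convention = "positive_down_m",
         transition = truth$transition, step_gamma = truth$step_gamma,
         turn_vonmises = truth$turn_vonmises,
         dive_rate_forage = truth$dive_rate_forage),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(tracks = sim, isotope_prey = ip, klepto_morpho = km))
}
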