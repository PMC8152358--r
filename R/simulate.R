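# Seeded synthetic colony simulator. Every input stream of the pipeline
# (GPS, 1 Hz depth, 6 s immersion, kleptoparasitism events, isotopes,
# prey counts, morphometrics) is generated from a cpf_truth parameter
# set with the hidden state labels retained, so every downstream stage
# has a recovery-based test surface.

#' Simulate GPS tracks with known behavioural states
#'
#' Movement is a 3-state Markov chain (rest, forage, travel) in the
#' colony-centred plane: gamma step lengths and von Mises turn angles per
#' state at the fix interval. Each trip starts at the colony, runs the
#' free chain for the specified duration, then a biased-walk homing phase
#' returns the bird to the colony (labelled travel, flagged `homing` so
#' recovery tests can exclude it — the free phase keeps the emission
#' distributions exactly as specified). Departure hour is drawn once per
#' trip from N(7, 1) local solar time, one trip per day.
#'
#' @param world a [cpf_world()].
#' @param truth a [cpf_truth()].
#' @param n_birds number of birds (>= 1).
#' @param trip_spec list: `n_trips`, `duration_h` (free-chain phase) and
#'   `fix_interval_s` (30 or 120).
#' @param seed integer master seed.
#' @param species species label attached to every bird.
#' @param start_date UTC date of the first trip day.
#' @return list with `tracks` (bird_id, timestamp, lon, lat, x, y, state,
#'   homing, trip_true), `birds` (bird_id, sex, species) and the `world`.
#' @export
generate_tracks <- function(world, truth, n_birds,
                            trip_spec = list(n_trips = 2, duration_h = 4,
                                             fix_interval_s = 30),
                            seed = 1L, species = "BB",
                            start_date = "2018-02-01") {
  stopifnot(n_birds >= 1)
  dt <- trip_spec$fix_interval_s
  if (!dt %in% c(30, 120)) stop("fix_interval_s must be 30 or 120")
  n_steps <- floor(trip_spec$duration_h * 3600 / dt)
  if (is.null(n_steps) || n_steps < 1 || trip_spec$n_trips < 1)
    stop("invalid trip specification: implies zero fixes")
  day0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  solar_offset_s <- world$colony[["lon"]] / 15 * 3600

  stat <- stationary_distribution(truth$transition)
  birds <- data.frame(
    bird_id = sprintf("%s%02d", species, seq_len(n_birds)),
    sex = rep(c("F", "M"), length.out = n_birds),
    species = species, stringsAsFactors = FALSE)

  all <- vector("list", n_birds)
  for (b in seq_len(n_birds)) {
    rows <- with_seed(stream_seed(seed, "tracks", b), {
      trips <- vector("list", trip_spec$n_trips)
      for (tr in seq_len(trip_spec$n_trips)) {
        dep_local_h <- rnorm(1, 7, 1)
        t0 <- day0 + (tr - 1) * 86400 + dep_local_h * 3600 - solar_offset_s
        trips[[tr]] <- simulate_one_trip(truth, stat, n_steps, dt, t0, tr)
      }
      do.call(rbind, trips)
    })
    rows$bird_id <- birds$bird_id[b]
    all[[b]] <- rows
  }
  tracks <- do.call(rbind, all)
  ll <- world_unproject(world, tracks$x, tracks$y)
  tracks$lon <- ll$lon; tracks$lat <- ll$lat
  tracks <- tracks[, c("bird_id", "timestamp", "lon", "lat", "x", "y",
                       "state", "homing", "trip_true")]
  list(tracks = tracks, birds = birds, world = world)
}

# one trip: colony approach fixes, free Markov phase, biased homing walk
simulate_one_trip <- function(truth, stat, n_steps, dt, t0, trip_index) {
  pre <- 10L  # colony fixes before departure / after arrival
  # free phase
  states <- integer(n_steps)
  states[1] <- sample.int(3, 1, prob = stat)
  for (i in seq_len(n_steps - 1))
    states[i + 1] <- sample.int(3, 1, prob = truth$transition[states[i], ])
  g <- truth$step_gamma
  shp <- g[, "mean"]^2 / g[, "sd"]^2
  scl <- g[, "sd"]^2 / g[, "mean"]
  steps <- rgamma(n_steps, shape = shp[states], scale = scl[states])
  turns <- numeric(n_steps)
  for (s in 1:3) {
    idx <- which(states == s)
    if (length(idx))
      turns[idx] <- rvonmises(length(idx), truth$turn_vonmises[s, "mu"],
                              truth$turn_vonmises[s, "kappa"])
  }
  heading <- cumsum(c(runif(1, -pi, pi), turns[-1]))
  x <- cumsum(steps * cos(heading))
  y <- cumsum(steps * sin(heading))
  # homing phase: directed travel back to the colony
  hx <- numeric(0); hy <- numeric(0)
  cx <- x[n_steps]; cy <- y[n_steps]
  tstep_mean <- truth$step_gamma["travel", "mean"]
  tstep_sd <- truth$step_gamma["travel", "sd"]
  k <- 0L
  while (sqrt(cx^2 + cy^2) > 0.35 && k < 20000L) {
    ang <- atan2(-cy, -cx) + rvonmises(1, 0, 30)
    st <- min(rgamma(1, shape = tstep_mean^2 / tstep_sd^2,
                     scale = tstep_sd^2 / tstep_mean),
              sqrt(cx^2 + cy^2))
    cx <- cx + st * cos(ang); cy <- cy + st * sin(ang)
    hx <- c(hx, cx); hy <- c(hy, cy)
    k <- k + 1L
  }
  nh <- length(hx)
  jit <- function(n) runif(n, -0.05, 0.05)
  n_all <- pre + n_steps + nh + pre
  data.frame(
    timestamp = t0 + seq(-pre * dt, by = dt, length.out = n_all),
    x = c(jit(pre), x, hx, jit(pre)),
    y = c(jit(pre), y, hy, jit(pre)),
    state = c(rep("rest", pre), .cpf_states[states],
              rep("travel", nh), rep("rest", pre)),
    homing = c(rep(FALSE, pre + n_steps), rep(TRUE, nh), rep(FALSE, pre)),
    trip_true = trip_index, stringsAsFactors = FALSE)
}

#' Stationary distribution of a transition matrix
#'
#' Left eigenvector of the row-stochastic matrix for eigenvalue 1,
#' normalized to a probability vector.
#'
#' @param P row-stochastic square matrix.
#' @return stationary probability vector.
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

#' Simulate a 1 Hz depth trace with known dives
#'
#' Expands a fix-level state sequence to a 1 Hz clock (piecewise-constant
#' states), starts dives as a Poisson process restricted to forage-state
#' seconds, builds triangular dive profiles from a truncated lognormal
#' maximum-depth distribution, then adds linear sensor drift and Gaussian
#' noise *after* dive construction.
#'
#' @param states data.frame with `timestamp` (POSIXct) and `state`
#'   columns, time-sorted (typically one bird's track).
#' @param truth a [cpf_truth()].
#' @param seed integer seed.
#' @return list with `trace` (timestamp, depth_m raw) and `dives`
#'   (start, end, max_depth_m, duration_s) — the injected ground truth.
#' @export
generate_dive_trace <- function(states, truth, seed = 1L) {
  if (nrow(states) == 0)
    return(list(trace = data.frame(timestamp = as.POSIXct(character(),
                                                          tz = "UTC"),
                                   depth_m = numeric(0)),
                dives = empty_dive_table()))
  t0 <- states$timestamp[1]
  tn <- states$timestamp[nrow(states)]
  sec <- as.numeric(difftime(tn, t0, units = "secs"))
  tt <- seq(0, sec, by = 1)
  idx <- findInterval(tt, as.numeric(states$timestamp) - as.numeric(t0))
  st <- states$state[pmax(idx, 1)]
  depth <- numeric(length(tt))
  with_seed(stream_seed(seed, "dives"), {
    rate_s <- truth$dive_rate_forage / 3600
    starts <- integer(0); ends <- integer(0); maxd <- numeric(0)
    i <- 1L; n <- length(tt)
    while (i <= n) {
      if (st[i] == "forage" && runif(1) < rate_s) {
        dur <- max(2L, round(rgamma(1, shape = truth$dive_duration$shape,
                                    scale = truth$dive_duration$mean_s /
                                      truth$dive_duration$shape)))
        if (i + dur <= n && all(st[i:(i + dur)] == "forage")) {
          md <- rtrunc_lnorm(1, truth$dive_depth$meanlog,
                             truth$dive_depth$sdlog,
                             truth$dive_depth$max_depth_m)
          k <- 0:dur
          prof <- md * (1 - abs(2 * k / dur - 1))
          # every true dive must be detectable: the depth attained on
          # the 1 Hz clock stays clear of the 0.25 m threshold
          pk <- max(prof)
          if (pk < 0.35) prof <- prof * (0.35 / pk)
          depth[i + k] <- pmax(depth[i + k], prof)
          starts <- c(starts, i); ends <- c(ends, i + dur)
          maxd <- c(maxd, max(prof))  # depth attained on the 1 Hz clock
          i <- i + dur + 2L
          next
        }
      }
      i <- i + 1L
    }
    drift <- truth$sensor_drift$slope_m_h * tt / 3600
    noise <- if (truth$sensor_drift$noise_sd_m > 0)
      rnorm(length(tt), 0, truth$sensor_drift$noise_sd_m) else 0
    trace <- data.frame(timestamp = t0 + tt, depth_m = depth + drift + noise)
    dives <- if (length(starts))
      data.frame(start = t0 + tt[starts], end = t0 + tt[ends],
                 max_depth_m = maxd, duration_s = tt[ends] - tt[starts])
    else empty_dive_table()
    list(trace = trace, dives = dives)
  })
}

empty_dive_table <- function() {
  data.frame(start = as.POSIXct(character(), tz = "UTC"),
             end = as.POSIXct(character(), tz = "UTC"),
             max_depth_m = numeric(0), duration_s = numeric(0))
}

#' Simulate a 6 s wet/dry immersion log
#'
#' Each 6 s sample is wet with the state-conditional probability in
#' `truth$immersion_rule` (piecewise-constant states from the track).
#'
#' @inheritParams generate_dive_trace
#' @return data.frame with `timestamp` and `state` in `{wet, dry}`.
#' @export
generate_immersion <- function(states, truth, seed = 1L) {
  if (nrow(states) == 0)
    return(data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
                      state = character(0)))
  t0 <- states$timestamp[1]
  sec <- as.numeric(difftime(states$timestamp[nrow(states)], t0,
                             units = "secs"))
  tt <- seq(0, sec, by = 6)
  idx <- findInterval(tt, as.numeric(states$timestamp) - as.numeric(t0))
  st <- states$state[pmax(idx, 1)]
  with_seed(stream_seed(seed, "immersion"), {
    wet <- runif(length(tt)) < truth$immersion_rule[st]
    data.frame(timestamp = t0 + tt,
               state = ifelse(wet, "wet", "dry"),
               stringsAsFactors = FALSE)
  })
}

#' Simulate isotope samples and prey-count tables
#'
#' Isotope observations are bivariate normal per group with the truth
#' means/covariances; prey counts are multinomial per species with the
#' truth composition probabilities.
#'
#' @param truth a [cpf_truth()].
#' @param n_per_group named integer vector of isotope sample sizes; names
#'   must be groups of `truth$isotope_model`.
#' @param prey_n named integer vector of total prey items per species row
#'   of `truth$prey_probs`.
#' @param seed integer seed.
#' @return list with `isotopes` (sample_id, group, tissue, d13C, d15N,
#'   cn_ratio) and `prey` (long-format species, family, count).
#' @export
generate_isotope_and_prey <- function(truth,
                                      n_per_group = c(RFB_F = 27, RFB_M = 32,
                                                      BB_F = 10, BB_M = 20,
                                                      prey_flyingfish = 60,
                                                      prey_ballyhoo = 60,
                                                      prey_other = 30),
                                      prey_n = c(RFB = 100, BB = 96),
                                      seed = 1L) {
  bad <- setdiff(names(n_per_group), names(truth$isotope_model))
  if (length(bad)) stop("unknown isotope group(s): ",
                        paste(bad, collapse = ", "))
  iso <- with_seed(stream_seed(seed, "isotope"), {
    do.call(rbind, lapply(names(n_per_group), function(gp) {
      n <- n_per_group[[gp]]
      m <- truth$isotope_model[[gp]]
      xy <- rmvn(n, m$mean, m$cov)
      prey <- startsWith(gp, "prey_")
      data.frame(
        sample_id = paste0(gp, "_", seq_len(n)), group = gp,
        tissue = if (prey) "prey_muscle" else "blood_RBC",
        d13C = xy[, 1], d15N = xy[, 2],
        cn_ratio = if (prey) runif(n, 3.2, 5.0) else NA_real_,
        stringsAsFactors = FALSE)
    }))
  })
  bad_sp <- setdiff(names(prey_n), rownames(truth$prey_probs))
  if (length(bad_sp)) stop("unknown prey species group(s): ",
                           paste(bad_sp, collapse = ", "))
  prey <- with_seed(stream_seed(seed, "prey"), {
    do.call(rbind, lapply(names(prey_n), function(sp) {
      cnt <- as.vector(rmultinom(1, prey_n[[sp]], truth$prey_probs[sp, ]))
      data.frame(species = sp, family = colnames(truth$prey_probs),
                 count = cnt, stringsAsFactors = FALSE)
    }))
  })
  list(isotopes = iso, prey = prey)
}

#' Simulate kleptoparasitism events and morphometrics
#'
#' Attack risk is Bernoulli per forage-state fix with logistic probability
#' in (sex, distance-to-coast); no events are generated outside the forage
#' state. Morphometrics are multivariate normal per sex.
#'
#' @param truth a [cpf_truth()].
#' @param tracks output of [generate_tracks()] (carries sex labels and the
#'   world geometry).
#' @param seed integer seed.
#' @return list with `events` (bird_id, start, end, attacker_class) and
#'   `morpho` (bird_id, sex, six measurements).
#' @export
generate_klepto_and_morpho <- function(truth, tracks, seed = 1L) {
  tr <- tracks$tracks
  sex <- setNames(tracks$birds$sex, tracks$birds$bird_id)
  fg <- tr[tr$state == "forage" & !tr$homing, , drop = FALSE]
  events <- with_seed(stream_seed(seed, "klepto"), {
    if (nrow(fg)) {
      cd <- pmax(0, coast_distance(fg$x, fg$y, tracks$world$coastline))
      male <- sex[fg$bird_id] == "M"
      eta <- truth$klepto_model[["intercept"]] +
        truth$klepto_model[["coast_km"]] * cd
      # added separately so a -Inf male coefficient (risk clamped to
      # zero) cannot produce -Inf * 0 = NaN for females
      eta[male] <- eta[male] + truth$klepto_model[["male"]]
      p <- plogis(eta)
      hit <- runif(nrow(fg)) < p
      if (any(hit)) {
        h <- fg[hit, , drop = FALSE]
        dur <- runif(nrow(h), 4, 45)
        data.frame(bird_id = h$bird_id, start = h$timestamp,
                   end = h$timestamp + dur,
                   attacker_class = sample(c("adult_female", "juvenile"),
                                           nrow(h), TRUE, c(0.8, 0.2)),
                   stringsAsFactors = FALSE)
      } else empty_event_table()
    } else empty_event_table()
  })
  morpho <- with_seed(stream_seed(seed, "morpho"), {
    do.call(rbind, lapply(seq_len(nrow(tracks$birds)), function(i) {
      m <- truth$morpho_model[[tracks$birds$sex[i]]]
      v <- rmvn(1, m$mean, m$cov)
      cbind(data.frame(bird_id = tracks$birds$bird_id[i],
                       sex = tracks$birds$sex[i],
                       stringsAsFactors = FALSE),
            as.data.frame(v))
    }))
  })
  list(events = events, morpho = morpho)
}

empty_event_table <- function() {
  data.frame(bird_id = character(0),
             start = as.POSIXct(character(), tz = "UTC"),
             end = as.POSIXct(character(), tz = "UTC"),
             attacker_class = character(0), stringsAsFactors = FALSE)
}
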