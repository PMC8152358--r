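# Shared fixtures and independent oracles. Everything is built in code;
# oracles are deliberately naive re-implementations kept independent of
# the package's computational path.

fix_world <- function() cpf_world(extent_km = 120)
fix_truth <- function(tactic = "coastal") cpf_truth(tactic)

truth_hmm_params <- function(truth = fix_truth()) {
  hmm_params(truth$step_gamma, truth$turn_vonmises, truth$transition)
}

# a simple regularized track data.frame at 30 s from x/y paths
make_track <- function(x, y, t0 = as.POSIXct("2018-02-01 12:00:00",
                                             tz = "UTC"), dt = 30) {
  data.frame(timestamp = t0 + seq_along(x) * dt - dt, x = x, y = y)
}

# --- oracle: brute-force HMM path enumeration (short sequences) -----------
enum_hmm <- function(params, step, turn) {
  n <- length(step)
  S <- 3
  ld <- matrix(0, n, S)
  g <- params$step_gamma
  for (s in 1:S) {
    ld[, s] <- dgamma(pmax(step, 0.001), shape = g[s, 1]^2 / g[s, 2]^2,
                      scale = g[s, 2]^2 / g[s, 1], log = TRUE)
    ok <- !is.na(turn)
    ld[ok, s] <- ld[ok, s] +
      dvonmises(turn[ok], params$turn_vm[s, 1], params$turn_vm[s, 2],
                log = TRUE)
  }
  paths <- as.matrix(expand.grid(rep(list(1:S), n)))
  lp <- apply(paths, 1, function(pp) {
    v <- log(params$initial[pp[1]]) + ld[1, pp[1]]
    if (n > 1) for (t in 2:n)
      v <- v + log(params$transition[pp[t - 1], pp[t]]) + ld[t, pp[t]]
    v
  })
  m <- max(lp)
  list(loglik = m + log(sum(exp(lp - m))),
       viterbi = paths[which.max(lp), ])
}

# --- oracle: direct Gaussian kernel sum at single points ------------------
kde_point_oracle <- function(pts, h, x, y) {
  hinv <- solve(h)
  n <- nrow(pts)
  vapply(seq_along(x), function(i) {
    d <- cbind(x[i] - pts[, 1], y[i] - pts[, 2])
    q <- rowSums((d %*% hinv) * d)
    sum(exp(-q / 2)) / (n * 2 * pi * sqrt(det(h)))
  }, 0.0)
}

# --- oracle: independently coded cubic Hermite evaluation -----------------
hermite_oracle <- function(x, y, d, xq) {
  vapply(xq, function(t) {
    i <- max(which(x <= t)); i <- min(i, length(x) - 1)
    h <- x[i + 1] - x[i]; s <- (t - x[i]) / h
    y[i] * (2 * s^3 - 3 * s^2 + 1) + h * d[i] * (s^3 - 2 * s^2 + s) +
      y[i + 1] * (-2 * s^3 + 3 * s^2) + h * d[i + 1] * (s^3 - s^2)
  }, 0.0)
}

# two-tactic synthetic trip table at realistic field scales
# (coastal/neritic short trips vs pelagic extensive trips)
two_cluster_trips <- function(n_per = 60, seed = 17) {
  set.seed(seed)
  coastal <- data.frame(
    duration_h = rnorm(n_per, 3.6, 0.8),
    mean_coast_distance_km = rnorm(n_per, 7, 2),
    max_distance_km = rnorm(n_per, 18, 4))
  pelagic <- data.frame(
    duration_h = rnorm(n_per, 12.7, 2.5),
    mean_coast_distance_km = rnorm(n_per, 33, 6),
    max_distance_km = rnorm(n_per, 62, 10))
  list(metrics = rbind(coastal, pelagic),
       truth = rep(1:2, each = n_per))
}
two_cluster_trips_accept <- function() two_cluster_trips(100, seed = 55)

# End-to-end pipeline on a two-species, two-sex synthetic colony system:
# simulate, preprocess, decode, map space use, cluster tactics and test
# the sex effect. The two species breed on neighbouring islands with
# colonies ~30 km apart, each simulated in its
# own colony-centred frame and mapped into a common frame for overlap.
# Returns the core-isopleth overlap and the tactic test.
run_segregation_pipeline <- function(seed = 42) {
  w <- cpf_world(colony_lon = -79.80, colony_lat = 19.70,
                 extent_km = 150)                      # BB island
  w_rfb <- cpf_world(colony_lon = -80.08, colony_lat = 19.66,
                     extent_km = 150)                  # RFB island
  spec_short <- list(n_trips = 2, duration_h = 2.5, fix_interval_s = 30)
  spec_long <- list(n_trips = 2, duration_h = 7, fix_interval_s = 30)
  gen <- function(world, truth, n, spec, species, sex, tag, sd_offset) {
    s <- generate_tracks(world, truth, n, spec, seed + sd_offset, species)
    s$birds$sex <- sex
    s$birds$bird_id <- paste0(tag, s$birds$bird_id)
    s$tracks$bird_id <- paste0(tag, s$tracks$bird_id)
    s
  }
  coastal <- fix_truth("coastal"); pelagic <- fix_truth("pelagic")
  bb_f <- gen(w, coastal, 7, spec_short, "BB", "F", "f", 1)
  bb_fx <- gen(w, coastal, 2, spec_long, "BB", "F", "g", 2)  # mixed females
  bb_m <- gen(w, coastal, 7, spec_long, "BB", "M", "m", 3)
  rfb <- gen(w_rfb, pelagic, 6, spec_long, "RFB", rep(c("F", "M"), 3),
             "r", 4)

  prep <- function(sim) {
    out <- list()
    for (b in unique(sim$tracks$bird_id)) {
      f <- speed_filter(sim$tracks[sim$tracks$bird_id == b, ])$fixes
      tr <- segment_trips(f)
      if (!nrow(tr$summary)) next
      reg <- lapply(split(tr$fixes, tr$fixes$trip_id), interpolate_track)
      out[[b]] <- do.call(rbind, reg)
    }
    do.call(rbind, out)
  }
  bb_fix <- rbind(prep(bb_f), prep(bb_fx), prep(bb_m))
  rfb_fix <- prep(rfb)
  decode_species <- function(fixes, n_restarts = 2, fit_seed = 1) {
    sat <- do.call(rbind, lapply(split(fixes, fixes$trip_id),
                                 steps_and_turns))
    fit <- fit_hmm(sat, n_restarts = n_restarts, seed = fit_seed)
    dec <- decode_states(fit$params, sat)
    # steps refer to the segment starting at each fix; align to fixes
    keep <- unlist(lapply(split(seq_len(nrow(fixes)), fixes$trip_id),
                          function(i) i[-length(i)]), use.names = FALSE)
    list(fixes = fixes[keep, , drop = FALSE], decoded = dec, fit = fit)
  }
  bb_dec <- decode_species(bb_fix)
  rfb_dec <- decode_species(rfb_fix)
  forage_of <- function(d) extract_foraging(d$decoded, d$fixes)$foraging
  fa <- forage_of(bb_dec); fb <- forage_of(rfb_dec)
  # map the RFB fixes (RFB-colony frame) into the common BB frame
  ll <- aeqd_unproject(fb$x, fb$y, w_rfb$colony[["lon"]],
                       w_rfb$colony[["lat"]])
  xy <- aeqd_project(ll$lon, ll$lat, w$colony[["lon"]], w$colony[["lat"]])
  fb$x <- xy$x; fb$y <- xy$y
  sub <- function(p) p[seq(1, nrow(p), length.out = min(500, nrow(p))), ]
  ha <- lscv_bandwidth(sub(fa[, c("x", "y")]))
  hb <- lscv_bandwidth(sub(fb[, c("x", "y")]))
  allx <- range(c(fa$x, fb$x)); ally <- range(c(fa$y, fb$y))
  gs <- list(xlim = allx + c(-20, 20), ylim = ally + c(-20, 20), n = 160)
  ba50 <- bhattacharyya_overlap(kde_surface(fa[, c("x", "y")], ha, gs),
                                kde_surface(fb[, c("x", "y")], hb, gs),
                                level = 0.5)
  # BB trip tactics
  bb_trips <- split(bb_fix, bb_fix$trip_id)
  mets <- do.call(rbind, lapply(bb_trips, trip_metrics, world = w))
  gmm <- fit_gmm(mets, K_range = 1:3, n_init = 5, seed = seed)
  pel <- as.numeric(gmm$labels == gmm$K)   # longest-duration component
  bird <- vapply(bb_trips, function(t) t$bird_id[1], "")
  sex <- ifelse(startsWith(bird, "m"), "M", "F")
  tact <- tactic_sex_test(pel, bird, sex)
  list(ba50 = ba50, gmm = gmm, tactic = tact,
       fits = list(bb = bb_dec$fit, rfb = rfb_dec$fit))
}

# adjusted Rand index (independent implementation for cluster recovery)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab))); sj <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  exp_ <- si * sj / n
  (sij - exp_) / ((si + sj) / 2 - exp_)
}
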