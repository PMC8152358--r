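# HMM correctness against enumeration oracles, decoding, and the
# validation cross-tabulation. The heavy parameter-recovery run lives in
# test-acceptance.R.

test_that("steps and turns follow the geometry", {
  # unit square: steps 1, turns +pi/2
  sq <- make_track(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))
  st <- steps_and_turns(sq)
  expect_equal(st$step, rep(1, 4), tolerance = 1e-12)
  expect_equal(st$turn[-1], rep(pi / 2, 3), tolerance = 1e-12)
  expect_true(is.na(st$turn[1]))
  # straight line: zero turns
  ln <- make_track(0:5, (0:5) * 2)
  expect_equal(steps_and_turns(ln)$turn[-1], rep(0, 4), tolerance = 1e-12)
  expect_error(steps_and_turns(ln[1:2, ]), "at least 3")
  # random track vs direct trigonometric recomputation
  set.seed(3)
  rt <- make_track(cumsum(rnorm(30)), cumsum(rnorm(30)))
  st2 <- steps_and_turns(rt)
  dx <- diff(rt$x); dy <- diff(rt$y)
  expect_equal(st2$step, sqrt(dx^2 + dy^2), tolerance = 1e-12)
  h <- atan2(dy, dx)
  turn_o <- atan2(sin(diff(h)), cos(diff(h)))
  expect_equal(st2$turn[-1], turn_o, tolerance = 1e-12)
})

test_that("forward log-likelihood matches brute-force enumeration", {
  p <- truth_hmm_params()
  for (seed in 1:3) {
    d <- simulate_hmm_data(p, 8, seed = seed)
    o <- enum_hmm(p, d$step, d$turn)
    expect_equal(hmm_loglik(p, d), o$loglik, tolerance = 1e-8)
  }
})

test_that("likelihood collapses to iid density for a dominant state", {
  p <- truth_hmm_params()
  # make states 1 and 3 impossible a priori and unreachable
  p$initial <- c(0, 1, 0)
  p$transition <- matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), 3, 3)
  d <- simulate_hmm_data(truth_hmm_params(), 50, seed = 2)
  ll <- hmm_loglik(p, d)
  g <- p$step_gamma
  iid <- sum(dgamma(pmax(d$step, 0.001), shape = g[2, 1]^2 / g[2, 2]^2,
                    scale = g[2, 2]^2 / g[2, 1], log = TRUE)) +
    sum(dvonmises(d$turn[-1], p$turn_vm[2, 1], p$turn_vm[2, 2], log = TRUE))
  expect_equal(ll, iid, tolerance = 1e-8)
})

test_that("likelihood is invariant under state relabelling", {
  p <- truth_hmm_params()
  d <- simulate_hmm_data(p, 40, seed = 5)
  perm <- c(3, 1, 2)
  q <- hmm_params(p$step_gamma[perm, ], p$turn_vm[perm, ],
                  p$transition[perm, perm], p$initial[perm])
  expect_equal(hmm_loglik(p, d), hmm_loglik(q, d), tolerance = 1e-10)
})

test_that("invalid parameters are rejected", {
  p <- truth_hmm_params()
  p$transition[1, ] <- c(0.5, 0.6, 0.2)
  expect_error(validate_hmm_params(p), "invalid")
})

test_that("Viterbi equals brute-force argmax on short sequences", {
  p <- truth_hmm_params()
  for (seed in 4:6) {
    d <- simulate_hmm_data(p, 9, seed = seed)
    o <- enum_hmm(p, d$step, d$turn)
    dec <- decode_states(p, d)
    expect_identical(match(dec$state, c("rest", "forage", "travel")),
                     as.integer(o$viterbi))
    # posterior rows sum to 1
    expect_equal(rowSums(dec[, c("p_rest", "p_forage", "p_travel")]),
                 rep(1, 9), tolerance = 1e-9)
  }
})

test_that("disjoint emission supports give exact decoding", {
  p <- hmm_params(
    step_gamma = cbind(mean = c(0.001, 1, 100), sd = c(0.0001, 0.01, 0.1)),
    turn_vm = cbind(mu = c(0, 0, 0), kappa = c(1, 1, 1)),
    transition = matrix(1 / 3, 3, 3))
  d <- simulate_hmm_data(p, 300, seed = 8)
  dec <- decode_states(p, d)
  expect_identical(dec$state, d$state)
})

test_that("ascent property: fit from the truth never degrades it", {
  p <- truth_hmm_params()
  d <- simulate_hmm_data(p, 2000, seed = 12)
  fit <- fit_hmm(d, init_params = p, maxit = 100)
  expect_gte(fit$loglik, hmm_loglik(p, d) - 1e-6)
  # canonical ordering always holds
  sg <- fit$params$step_gamma
  expect_true(sg["rest", "mean"] <= sg["forage", "mean"])
  expect_true(sg["forage", "mean"] <= sg["travel", "mean"])
})

test_that("foraging extraction returns label proportions exactly", {
  dec <- data.frame(
    state = rep(c("forage", "travel"), 10),
    trip_id = rep(c("a", "b"), each = 10))
  fixes <- data.frame(x = 1:20, y = 1:20)
  out <- extract_foraging(dec, fixes)
  expect_identical(nrow(out$foraging), 10L)
  expect_equal(out$proportions$forage, c(0.5, 0.5))
  expect_equal(rowSums(out$proportions[, c("rest", "forage", "travel")]),
               c(1, 1))
  # all-forage decode
  dec2 <- data.frame(state = rep("forage", 6), trip_id = "a")
  out2 <- extract_foraging(dec2, fixes[1:6, ])
  expect_identical(nrow(out2$foraging), 6L)
  expect_equal(out2$proportions$forage, 1)
  # random decode matches counting oracle
  set.seed(9)
  st <- sample(c("rest", "forage", "travel"), 200, TRUE)
  dec3 <- data.frame(state = st, trip_id = "t")
  out3 <- extract_foraging(dec3, data.frame(x = 1:200, y = 1:200))
  expect_equal(out3$proportions$rest, mean(st == "rest"))
})

test_that("state validation cross-tabulates dives by decoded state", {
  t0 <- as.POSIXct("2018-02-01 08:00:00", tz = "UTC")
  fixes <- data.frame(
    timestamp = t0 + seq(0, by = 30, length.out = 240),
    state = rep(c("forage", "travel"), each = 120))
  # dives only during the forage half
  dives <- data.frame(start = t0 + sort(sample(0:3500, 20)))
  v <- validate_states(fixes, dives = dives)
  expect_true(v$evaluable)
  expect_true(v$pass)
  expect_equal(unname(v$dive_rate_h[["forage"]]), 20 / 1, tolerance = 1e-9)
  expect_identical(unname(v$dive_rate_h[["travel"]]), 0)
  # empty dive list -> not evaluable
  v0 <- validate_states(fixes, dives = dives[0, , drop = FALSE])
  expect_false(v0$evaluable)
  # known 10% confusion attenuates the contrast predictably
  conf <- fixes
  flip <- seq(1, 120, by = 10)  # relabel 12 of 120 forage fixes as travel
  conf$state[flip] <- "travel"
  vc <- validate_states(conf, dives = dives)
  expect_true(vc$dive_rate_h[["travel"]] > 0)
  # closed-form mixing: total dives are conserved across the two states
  h_f <- sum(conf$state == "forage") * 30 / 3600
  h_t <- sum(conf$state == "travel") * 30 / 3600
  expect_equal(vc$dive_rate_h[["forage"]] * h_f +
                 vc$dive_rate_h[["travel"]] * h_t, 20, tolerance = 1e-9)
})

test_that("wet fractions follow the immersion log by state", {
  t0 <- as.POSIXct("2018-02-01 08:00:00", tz = "UTC")
  fixes <- data.frame(
    timestamp = t0 + seq(0, by = 30, length.out = 120),
    state = rep(c("rest", "travel"), each = 60))
  imm <- data.frame(
    timestamp = t0 + seq(0, by = 6, length.out = 590),
    state = c(rep("wet", 295), rep("dry", 295)))
  v <- validate_states(fixes, immersion = imm)
  expect_true(v$evaluable)
  expect_gt(v$wet_fraction[["rest"]], 0.9)
  expect_lt(v$wet_fraction[["travel"]], 0.1)
})
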