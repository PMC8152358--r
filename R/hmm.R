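# Three-state hidden Markov model for behavioural segmentation of
# regularized tracks: gamma step lengths, von Mises turn angles, direct
# likelihood maximization over a multi-restart unconstrained
# parameterization, Viterbi decoding and forward-backward posteriors.
# States are canonically ordered by ascending mean step length
# (rest < forage < travel) so fits are comparable across runs.

.STEP_FLOOR_KM <- 0.001  # zero steps floored at 1 m before gamma evaluation

#' Step lengths and turn angles of a regularized trip
#'
#' Step i is the Euclidean distance from fix i to i+1 in the projection
#' plane; turn i is the signed heading change at fix i+1, wrapped to
#' `(-pi, pi]`. The first turn of a trip is undefined (NA), not zero.
#'
#' @param trip data.frame with `x`, `y` (km) at a constant time step
#'   (at least 3 rows).
#' @return data.frame with `step` (km, length n-1) and `turn` (rad, NA
#'   first), plus `trip_id` if present on the input.
#' @export
steps_and_turns <- function(trip) {
  if (nrow(trip) < 3) stop("need at least 3 fixes for steps and turns")
  dx <- diff(trip$x); dy <- diff(trip$y)
  step <- sqrt(dx^2 + dy^2)
  heading <- atan2(dy, dx)
  turn <- c(NA_real_, wrap_angle(diff(heading)))
  out <- data.frame(step = step, turn = turn)
  if ("trip_id" %in% names(trip)) out$trip_id <- trip$trip_id[1]
  out
}

#' Construct/validate HMM parameters
#'
#' @param step_gamma 3x2 matrix (`mean`, `sd` in km) per state.
#' @param turn_vm 3x2 matrix (`mu` rad, `kappa` >= 0) per state.
#' @param transition 3x3 row-stochastic matrix.
#' @param initial length-3 simplex; default the stationary distribution
#'   of `transition`.
#' @return object of class `cpf_hmm_params`.
#' @export
hmm_params <- function(step_gamma, turn_vm, transition, initial = NULL) {
  if (is.null(initial)) initial <- stationary_distribution(transition)
  p <- structure(list(step_gamma = step_gamma, turn_vm = turn_vm,
                      transition = transition, initial = initial),
                 class = "cpf_hmm_params")
  validate_hmm_params(p)
  p
}

#' Validate HMM parameters
#'
#' Checks the structural invariants (row-stochastic transition matrix,
#' positive gamma moments, nonnegative concentrations, simplex initial
#' distribution); errors on violation.
#'
#' @param p an [hmm_params()] (or modified copy).
#' @return the object, invisibly.
#' @export
validate_hmm_params <- function(p) {
  ok <- is.matrix(p$transition) && all(dim(p$transition) == 3) &&
    all(abs(rowSums(p$transition) - 1) < 1e-8) && all(p$transition >= 0) &&
    all(p$step_gamma[, 1] > 0) && all(p$step_gamma[, 2] > 0) &&
    all(p$turn_vm[, 2] >= 0) &&
    abs(sum(p$initial) - 1) < 1e-8 && all(p$initial >= 0)
  if (!ok) stop("invalid HMM parameters (check simplex/positivity invariants)")
  invisible(p)
}

# T x 3 matrix of per-observation log emission densities; missing turns
# contribute the step density only.
hmm_emission_logdens <- function(params, step, turn) {
  step <- pmax(step, .STEP_FLOOR_KM)
  g <- params$step_gamma
  v <- params$turn_vm
  shp <- g[, 1]^2 / g[, 2]^2
  scl <- g[, 2]^2 / g[, 1]
  ld <- matrix(0, length(step), 3)
  for (s in 1:3) {
    ld[, s] <- dgamma(step, shape = shp[s], scale = scl[s], log = TRUE)
    has_turn <- !is.na(turn)
    ld[has_turn, s] <- ld[has_turn, s] +
      dvonmises(turn[has_turn], v[s, 1], v[s, 2], log = TRUE)
  }
  ld
}

#' Simulate step/turn data from HMM parameters
#'
#' Draws a state path from the Markov chain and state-conditional gamma
#' steps and von Mises turns: the direct emission-level generator used
#' for parameter-recovery testing (no geometry involved).
#'
#' @param params a [hmm_params()].
#' @param n number of steps.
#' @param seed integer seed.
#' @return data.frame `step`, `turn`, `state` (true labels).
#' @export
simulate_hmm_data <- function(params, n, seed = 1L) {
  validate_hmm_params(params)
  with_seed(stream_seed(seed, "sim"), {
    states <- integer(n)
    states[1] <- sample.int(3, 1, prob = params$initial)
    for (i in seq_len(n - 1))
      states[i + 1] <- sample.int(3, 1,
                                  prob = params$transition[states[i], ])
    g <- params$step_gamma
    shp <- g[, 1]^2 / g[, 2]^2
    scl <- g[, 2]^2 / g[, 1]
    step <- rgamma(n, shape = shp[states], scale = scl[states])
    turn <- numeric(n)
    for (s in 1:3) {
      idx <- which(states == s)
      if (length(idx))
        turn[idx] <- rvonmises(length(idx), params$turn_vm[s, 1],
                               params$turn_vm[s, 2])
    }
    turn[1] <- NA_real_
    data.frame(step = step, turn = turn, state = .cpf_states[states])
  })
}

#' HMM log-likelihood (forward algorithm)
#'
#' Per-trip forward recursions with per-step rescaling, summed over
#' trips; independent chain restarts at trip boundaries (the initial
#' distribution is re-applied).
#'
#' @param params a [hmm_params()].
#' @param data data.frame with `step` (km), `turn` (rad, NA allowed) and
#'   optionally `trip_id`.
#' @return scalar log-likelihood.
#' @export
hmm_loglik <- function(params, data) {
  validate_hmm_params(params)
  trips <- if ("trip_id" %in% names(data)) split(data, data$trip_id)
  else list(data)
  g <- params$step_gamma
  -sum(vapply(trips, function(d) {
    cpp_hmm_nll(pmax(d$step, .STEP_FLOOR_KM), d$turn,
                g[, 1]^2 / g[, 2]^2, g[, 2]^2 / g[, 1],
                params$turn_vm[, 1], params$turn_vm[, 2],
                params$transition, params$initial)
  }, 0.0))
}

# ---- unconstrained working parameterization -------------------------------
# theta = (log mean x3, log sd x3, mu x3 (raw angle), log kappa x3,
#          off-diagonal multinomial logits x6); initial = stationary.
hmm_theta_to_params <- function(theta) {
  mean_ <- exp(theta[1:3]); sd_ <- exp(theta[4:6])
  mu <- wrap_angle(theta[7:9]); kap <- exp(theta[10:12])
  lo <- matrix(theta[13:18], 3, 2, byrow = TRUE)
  tr <- matrix(0, 3, 3)
  for (i in 1:3) {
    e <- exp(lo[i, ])
    off <- e / (1 + sum(e))
    tr[i, -i] <- off
    tr[i, i] <- 1 - sum(off)
  }
  hmm_params(cbind(mean = mean_, sd = sd_), cbind(mu = mu, kappa = kap), tr)
}

hmm_params_to_theta <- function(p) {
  lo <- numeric(6); k <- 1
  for (i in 1:3) {
    off <- p$transition[i, -i] / p$transition[i, i]
    lo[k:(k + 1)] <- log(pmax(off, 1e-12)); k <- k + 2
  }
  c(log(p$step_gamma[, 1]), log(p$step_gamma[, 2]),
    p$turn_vm[, 1], log(pmax(p$turn_vm[, 2], 1e-6)), lo)
}

#' Fit the 3-state HMM by multi-restart direct likelihood maximization
#'
#' Quasi-Newton (BFGS) search in an unconstrained working space (logs for
#' gamma moments and concentrations, multinomial logits for transition
#' rows, raw angle for the turn mean), best of `n_restarts` random
#' initializations drawn uniformly within realistic limits. The returned
#' states are relabelled so mean step length increases rest < forage <
#' travel.
#'
#' @param data as for [hmm_loglik()]; pooled steps/turns from >= 1 trip.
#' @param n_restarts number of random restarts.
#' @param seed integer seed for the restart draws.
#' @param limits list of ranges for the restart draws: `step_mean`,
#'   `step_sd` (km), `kappa`.
#' @param maxit BFGS iteration cap per restart.
#' @param init_params optional [hmm_params()] used as the single
#'   starting point (overrides the random restarts).
#' @return list: `params` (canonically ordered), `loglik`, and
#'   `restarts` (per-restart convergence diagnostics).
#' @export
fit_hmm <- function(data, n_restarts = 25, seed = 1L,
                    limits = list(step_mean = c(0.01, 2),
                                  step_sd = c(0.01, 2),
                                  kappa = c(0.1, 10)),
                    maxit = 300, init_params = NULL) {
  trips <- if ("trip_id" %in% names(data)) split(data, data$trip_id)
  else list(data)
  steps <- lapply(trips, function(d) pmax(d$step, .STEP_FLOOR_KM))
  turns <- lapply(trips, function(d) d$turn)
  nll <- function(theta) {
    p <- try(hmm_theta_to_params(theta), silent = TRUE)
    if (inherits(p, "try-error")) return(1e10)
    g <- p$step_gamma
    v <- sum(vapply(seq_along(steps), function(i)
      cpp_hmm_nll(steps[[i]], turns[[i]],
                  g[, 1]^2 / g[, 2]^2, g[, 2]^2 / g[, 1],
                  p$turn_vm[, 1], p$turn_vm[, 2],
                  p$transition, p$initial), 0.0))
    if (!is.finite(v)) 1e10 else v
  }
  lower <- c(rep(log(1e-4), 6), rep(-2 * pi, 3), rep(log(1e-3), 3),
             rep(-15, 6))
  upper <- c(rep(log(10), 6), rep(2 * pi, 3), rep(log(500), 3),
             rep(15, 6))
  inits <- if (!is.null(init_params)) {
    list(hmm_params_to_theta(init_params))
  } else with_seed(stream_seed(seed, "hmm_init"), {
    lapply(seq_len(n_restarts), function(i) {
      m <- sort(runif(3, limits$step_mean[1], limits$step_mean[2]))
      s <- runif(3, limits$step_sd[1], limits$step_sd[2])
      k <- runif(3, limits$kappa[1], limits$kappa[2])
      c(log(m), log(s), rep(0, 3), log(k), rep(log(0.1), 6))
    })
  })
  fits <- lapply(seq_along(inits), function(i) {
    f <- try(optim(inits[[i]], nll, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = maxit, factr = 1e9)),
             silent = TRUE)
    if (inherits(f, "try-error")) list(ok = FALSE, value = Inf, error = f)
    else list(ok = is.finite(f$value), value = f$value, par = f$par,
              convergence = f$convergence)
  })
  vals <- vapply(fits, function(f) f$value, 0.0)
  if (!any(is.finite(vals)))
    stop("all HMM restarts failed; diagnostics: ",
         paste(vapply(fits, function(f) as.character(f$value), ""),
               collapse = ", "))
  best <- fits[[which.min(vals)]]
  params <- canonical_state_order(hmm_theta_to_params(best$par))
  list(params = params, loglik = -best$value,
       restarts = data.frame(
         restart = seq_along(fits),
         nll = vals,
         converged = vapply(fits, function(f)
           isTRUE(f$ok) && identical(f$convergence, 0L), TRUE)))
}

# permute states to ascending gamma mean and relabel rest/forage/travel
canonical_state_order <- function(p) {
  o <- order(p$step_gamma[, 1])
  sg <- p$step_gamma[o, , drop = FALSE]
  tv <- p$turn_vm[o, , drop = FALSE]
  rownames(sg) <- rownames(tv) <- .cpf_states
  tr <- p$transition[o, o]
  dimnames(tr) <- list(.cpf_states, .cpf_states)
  hmm_params(sg, tv, tr, p$initial[o])
}

#' Decode behavioural states
#'
#' Viterbi most-probable path plus forward-backward posterior state
#' probabilities, per trip (independent chains across trips).
#'
#' @inheritParams hmm_loglik
#' @return data.frame aligned to `data`: `state` label, `p_rest`,
#'   `p_forage`, `p_travel` posteriors (rows sum to 1), and `trip_id`.
#' @export
decode_states <- function(params, data) {
  validate_hmm_params(params)
  if (!"trip_id" %in% names(data)) data$trip_id <- "trip"
  parts <- split(seq_len(nrow(data)), data$trip_id)
  out <- data.frame(state = character(nrow(data)),
                    p_rest = 0, p_forage = 0, p_travel = 0,
                    trip_id = data$trip_id, stringsAsFactors = FALSE)
  for (idx in parts) {
    d <- data[idx, ]
    ld <- hmm_emission_logdens(params, d$step, d$turn)
    path <- cpp_viterbi(ld, log(params$transition), log(params$initial))
    post <- forward_backward(ld, params$transition, params$initial)
    out$state[idx] <- .cpf_states[path]
    out[idx, c("p_rest", "p_forage", "p_travel")] <- post
  }
  out
}

# scaled forward-backward smoother; returns T x 3 posterior matrix
forward_backward <- function(logdens, trans, init) {
  T_ <- nrow(logdens); S <- ncol(logdens)
  dens <- exp(logdens - apply(logdens, 1, max))
  alpha <- matrix(0, T_, S); beta <- matrix(0, T_, S)
  cvec <- numeric(T_)
  a <- init * dens[1, ]; cvec[1] <- sum(a); alpha[1, ] <- a / cvec[1]
  if (T_ > 1) for (t in 2:T_) {
    a <- (alpha[t - 1, ] %*% trans) * dens[t, ]
    cvec[t] <- sum(a)
    alpha[t, ] <- a / cvec[t]
  }
  beta[T_, ] <- 1
  if (T_ > 1) for (t in (T_ - 1):1) {
    b <- trans %*% (dens[t + 1, ] * beta[t + 1, ])
    beta[t, ] <- b / cvec[t + 1]
  }
  post <- alpha * beta
  post / rowSums(post)
}

#' Extract foraging fixes and per-trip time-in-state proportions
#'
#' Implements the discard rule: locations decoded as directed travel or
#' rest are dropped, keeping the foraging bouts that feed the space-use
#' analyses.
#'
#' @param decoded output of [decode_states()], row-aligned to `fixes`.
#' @param fixes the fixes the decode refers to (same row order).
#' @return list: `foraging` (fix rows decoded forage) and `proportions`
#'   (per trip_id, columns rest/forage/travel summing to 1).
#' @export
extract_foraging <- function(decoded, fixes) {
  stopifnot(nrow(decoded) == nrow(fixes))
  keep <- decoded$state == "forage"
  tab <- table(decoded$trip_id, factor(decoded$state, levels = .cpf_states))
  prop <- sweep(unclass(tab), 1, rowSums(tab), `/`)
  list(foraging = fixes[keep, , drop = FALSE],
       proportions = data.frame(trip_id = rownames(prop),
                                rest = prop[, "rest"],
                                forage = prop[, "forage"],
                                travel = prop[, "travel"],
                                row.names = NULL))
}

#' Validate decoded states against dive and immersion data
#'
#' Cross-tabulates sensor evidence by decoded state: dive rate (dives per
#' hour of time in state, dives assigned to fixes by centred 30 s
#' windows) and wet fraction from the immersion log. The decode passes
#' when the forage-state dive rate exceeds the travel-state dive rate.
#'
#' @param decoded_fixes fixes with `timestamp` and decoded `state`, at a
#'   constant time step.
#' @param dives dive-event table (`start`, ...) or NULL.
#' @param immersion wet/dry log (`timestamp`, `state`) or NULL.
#' @return list: `evaluable`, per-state `dive_rate_h`, `wet_fraction`,
#'   and `pass` (forage dive rate > travel dive rate).
#' @export
validate_states <- function(decoded_fixes, dives = NULL, immersion = NULL) {
  dt_s <- as.numeric(median(diff(as.numeric(decoded_fixes$timestamp))))
  hours_in_state <- table(decoded_fixes$state) * dt_s / 3600
  dive_rate <- setNames(rep(NA_real_, 3), .cpf_states)
  wet_frac <- setNames(rep(NA_real_, 3), .cpf_states)
  evaluable <- FALSE
  if (!is.null(dives) && nrow(dives) > 0) {
    m <- match_to_track(dives, decoded_fixes, dt_s = dt_s)$events
    ok <- !is.na(m$fix_index)
    if (any(ok)) {
      evaluable <- TRUE
      st <- decoded_fixes$state[m$fix_index[ok]]
      cnt <- table(factor(st, levels = .cpf_states))
      for (s in .cpf_states)
        dive_rate[s] <- if (s %in% names(hours_in_state) &&
                            hours_in_state[[s]] > 0)
          cnt[[s]] / hours_in_state[[s]] else NA_real_
    }
  }
  if (!is.null(immersion) && nrow(immersion) > 0) {
    idx <- match_times_to_fixes(immersion$timestamp,
                                decoded_fixes$timestamp, dt_s)
    ok <- !is.na(idx)
    if (any(ok)) {
      evaluable <- TRUE
      st <- decoded_fixes$state[idx[ok]]
      wet <- immersion$state[ok] == "wet"
      for (s in .cpf_states) {
        sel <- st == s
        wet_frac[s] <- if (any(sel)) mean(wet[sel]) else NA_real_
      }
    }
  }
  pass <- evaluable && !is.na(dive_rate["forage"]) &&
    (is.na(dive_rate["travel"]) || dive_rate["forage"] > dive_rate["travel"])
  list(evaluable = evaluable, dive_rate_h = dive_rate,
       wet_fraction = wet_frac, pass = pass)
}
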