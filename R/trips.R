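# Per-trip characteristics, Gaussian-mixture clustering of foraging
# tactics, and a random-intercept binomial test of sex differences in
# tactic probability (adaptive Gauss-Hermite quadrature).

#' Per-trip movement characteristics
#'
#' Total distance (summed projected steps), maximum distance from the
#' colony, duration, mean distance to the nearest coastline, median
#' underlying bathymetry (fixes without bathymetry excluded from the
#' median, with a warning) and time-in-state proportions.
#'
#' @param trip regularized fixes of one trip (`timestamp`, `x`, `y`).
#' @param world a [cpf_world()] providing coastline and bathymetry.
#' @param decoded optional [decode_states()] rows aligned to `trip` for
#'   the state proportions.
#' @return one-row data.frame of class-free metrics: `total_distance_km`,
#'   `max_distance_km`, `duration_h`, `mean_coast_distance_km`,
#'   `median_bathymetry_m`, `prop_rest/forage/travel`.
#' @export
trip_metrics <- function(trip, world, decoded = NULL) {
  d <- sqrt(diff(trip$x)^2 + diff(trip$y)^2)
  cd <- coast_distance(trip$x, trip$y, world$coastline)
  bt <- bathy_at(world, trip$x, trip$y)
  if (anyNA(bt)) warning(sum(is.na(bt)),
                         " fixes without bathymetry excluded from median")
  props <- c(rest = NA_real_, forage = NA_real_, travel = NA_real_)
  if (!is.null(decoded)) {
    tab <- table(factor(decoded$state, levels = .cpf_states))
    props <- as.numeric(tab) / sum(tab)
    names(props) <- .cpf_states
  }
  data.frame(
    trip_id = if ("trip_id" %in% names(trip)) trip$trip_id[1] else NA,
    total_distance_km = sum(d),
    max_distance_km = max(sqrt(trip$x^2 + trip$y^2)),
    duration_h = as.numeric(difftime(trip$timestamp[nrow(trip)],
                                     trip$timestamp[1], units = "hours")),
    mean_coast_distance_km = mean(pmax(cd, 0)),
    median_bathymetry_m = median(bt, na.rm = TRUE),
    prop_rest = props[["rest"]], prop_forage = props[["forage"]],
    prop_travel = props[["travel"]], stringsAsFactors = FALSE)
}

#' Gaussian mixture clustering of trips
#'
#' EM with full per-component covariances on z-scored variables,
#' `n_init` seeded restarts per K, K selected by lowest BIC
#' (`-2 logL + p log n`). Components are canonically ordered by ascending
#' mean (z-scored) trip duration, so the later component is the longer,
#' more pelagic tactic. Singular covariances during EM are ridged and
#' reported.
#'
#' @param metrics trip metrics table (>= 10 rows).
#' @param vars variables to cluster on; the default trio is the one used
#'   for tactic discovery.
#' @param K_range candidate component counts.
#' @param n_init EM restarts per K.
#' @param seed integer seed.
#' @return list: `K`, `weights`, `means`, `covariances` (z-score space),
#'   `bic` (per K), `loglik`, `labels` (hard assignment by maximum
#'   responsibility), `responsibilities`, `scaling` (means/sds for
#'   back-transform), `regularized`.
#' @export
fit_gmm <- function(metrics,
                    vars = c("duration_h", "mean_coast_distance_km",
                             "max_distance_km"),
                    K_range = 1:5, n_init = 10, seed = 1L) {
  X <- as.matrix(metrics[, vars])
  if (nrow(X) < 10) stop("need at least 10 trips for mixture clustering")
  ctr <- colMeans(X); scl <- apply(X, 2, sd)
  Z <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  n <- nrow(Z); p <- ncol(Z)
  best_by_k <- list(); bics <- setNames(rep(NA_real_, length(K_range)),
                                        paste0("K", K_range))
  for (ki in seq_along(K_range)) {
    K <- K_range[ki]
    best <- NULL
    for (init in seq_len(n_init)) {
      fit <- with_seed(stream_seed(seed, "gmm_init", ki * 1000 + init),
                       gmm_em(Z, K))
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    npar <- (K - 1) + K * p + K * p * (p + 1) / 2
    bics[ki] <- -2 * best$loglik + npar * log(n)
    best_by_k[[ki]] <- best
  }
  kbest <- which.min(bics)
  fit <- best_by_k[[kbest]]
  # canonical order: ascending mean duration (first clustering variable)
  o <- order(vapply(seq_len(K_range[kbest]),
                    function(k) fit$means[[k]][1], 0.0))
  fit$means <- fit$means[o]; fit$covs <- fit$covs[o]
  fit$weights <- fit$weights[o]
  fit$resp <- fit$resp[, o, drop = FALSE]
  labels <- max.col(fit$resp)
  list(K = K_range[kbest], weights = fit$weights, means = fit$means,
       covariances = fit$covs, bic = bics, loglik = fit$loglik,
       labels = labels, responsibilities = fit$resp,
       scaling = list(center = ctr, scale = scl),
       regularized = fit$regularized)
}

# one EM run on z-scored data; random-point initialization
gmm_em <- function(Z, K, max_iter = 300, tol = 1e-8) {
  n <- nrow(Z); p <- ncol(Z)
  mu <- lapply(sample.int(n, K), function(i) Z[i, ])
  sig <- replicate(K, cov(Z) + diag(1e-6, p), simplify = FALSE)
  w <- rep(1 / K, K)
  ll_old <- -Inf; regularized <- FALSE
  for (it in seq_len(max_iter)) {
    lp <- sapply(seq_len(K), function(k)
      log(w[k]) + dmvnorm_log(Z, mu[[k]], sig[[k]]))
    lp <- matrix(lp, n, K)
    m <- apply(lp, 1, max)
    lse <- m + log(rowSums(exp(lp - m)))
    ll <- sum(lse)
    resp <- exp(lp - lse)
    if (is.finite(ll_old) && ll - ll_old < tol * abs(ll)) break
    ll_old <- ll
    nk <- colSums(resp)
    w <- nk / n
    for (k in seq_len(K)) {
      mu[[k]] <- colSums(resp[, k] * Z) / nk[k]
      C <- sweep(Z, 2, mu[[k]])
      S <- t(C) %*% (resp[, k] * C) / nk[k]
      if (rcond(S) < 1e-10) { S <- S + diag(1e-4, p); regularized <- TRUE }
      sig[[k]] <- S
    }
  }
  list(loglik = ll, weights = w, means = mu, covs = sig, resp = resp,
       regularized = regularized)
}

# ---- random-intercept logistic regression (adaptive Gauss-Hermite) -------

# marginal log-likelihood; beta: fixed effects on X, log_sigma: log RE sd.
# AGQ: per-cluster Laplace mode/curvature recentre the GH nodes.
# Vectorized across clusters (Newton for all modes simultaneously).
agq_logistic_loglik <- function(beta, log_sigma, y, X, cluster, nodes) {
  sigma <- exp(log_sigma)
  eta0 <- as.vector(X %*% beta)
  cl <- as.integer(factor(cluster))
  G <- max(cl)
  gh <- gauss_hermite(nodes)
  b <- numeric(G)
  for (it in 1:30) {
    p <- plogis(eta0 + b[cl])
    g <- as.vector(rowsum(y - p, cl)) - b / sigma^2
    h <- -as.vector(rowsum(p * (1 - p), cl)) - 1 / sigma^2
    step <- g / h
    b <- b - step
    if (max(abs(step)) < 1e-10) break
  }
  p <- plogis(eta0 + b[cl])
  hh <- as.vector(rowsum(p * (1 - p), cl)) + 1 / sigma^2  # -f''(mode)
  s <- 1 / sqrt(hh)
  logf <- matrix(0, G, nodes)
  for (k in seq_len(nodes)) {
    bb <- b + sqrt(2) * s * gh$x[k]
    pp <- plogis(eta0 + bb[cl])
    logf[, k] <- as.vector(rowsum(dbinom_log(y, pp), cl)) +
      dnorm(bb, 0, sigma, log = TRUE) + gh$x[k]^2
  }
  m <- apply(logf, 1, max)
  sum(log(sqrt(2) * s * as.vector(exp(logf - m) %*% gh$w)) + m)
}

dbinom_log <- function(y, p) y * log(p) + (1 - y) * log1p(-p)

# Golub-Welsch Gauss-Hermite nodes/weights (physicists' convention)
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b; J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

# plain logistic regression by IRLS (used as the zero-variance limit)
irls_logistic <- function(y, X, max_iter = 100, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    beta_new <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  as.vector(beta)
}

fit_agq_logistic <- function(y, X, cluster, nodes = 15) {
  beta0 <- irls_logistic(y, X)
  npar <- ncol(X)
  fit <- optim(c(beta0, log(0.5)), function(p)
    -agq_logistic_loglik(p[seq_len(npar)], p[npar + 1], y, X, cluster,
                         nodes),
    method = "BFGS", control = list(maxit = 200, reltol = 1e-10))
  out <- list(beta = fit$par[seq_len(npar)], sigma = exp(fit$par[npar + 1]),
              loglik = -fit$value, convergence = fit$convergence)
  # sigma = 0 boundary: the marginal model collapses to plain logistic
  # regression; prefer the boundary when it is at least as good
  eta <- as.vector(X %*% beta0)
  ll0 <- sum(dbinom_log(y, plogis(eta)))
  if (ll0 >= out$loglik - 1e-8)
    out <- list(beta = beta0, sigma = 0, loglik = ll0,
                convergence = fit$convergence)
  out
}

#' Sex difference in tactic probability (random-intercept binomial GLMM)
#'
#' Fits logit P(pelagic tactic) = b0 + b1 male + u(bird), u ~ N(0,
#' sigma^2), by maximum likelihood with adaptive Gauss-Hermite quadrature
#' (default 15 nodes), and tests the sex effect with a likelihood-ratio
#' chi-squared (df = 1) against the intercept-only model with the same
#' random intercept. Complete separation (a sex with all one tactic) is
#' flagged.
#'
#' @param tactic binary vector (1 = pelagic/longer tactic) per trip.
#' @param bird_id bird identifier per trip (the random-effect grouping).
#' @param sex `"F"`/`"M"` per trip.
#' @param nodes quadrature nodes (>= 15 recommended).
#' @return list: `lrt` statistic, `df`, `p_value`, `beta` (intercept,
#'   male effect), `sigma` (random-intercept sd), `prop_by_sex`,
#'   `separation` flag.
#' @export
tactic_sex_test <- function(tactic, bird_id, sex, nodes = 15) {
  y <- as.numeric(tactic)
  if (length(unique(y)) < 2) stop("no variation in tactic labels")
  stopifnot(length(y) == length(bird_id), length(y) == length(sex))
  male <- as.numeric(sex == "M")
  if (min(table(sex[!duplicated(bird_id)])) < 2)
    stop("need at least 2 birds per sex")
  prop <- tapply(y, sex, mean)
  separation <- any(tapply(y, sex, function(v)
    all(v == 0) || all(v == 1)))
  X1 <- cbind(1, male)
  X0 <- matrix(1, length(y), 1)
  f1 <- fit_agq_logistic(y, X1, bird_id, nodes)
  f0 <- fit_agq_logistic(y, X0, bird_id, nodes)
  lrt <- max(0, 2 * (f1$loglik - f0$loglik))
  list(lrt = lrt, df = 1, p_value = pchisq(lrt, 1, lower.tail = FALSE),
       beta = f1$beta, sigma = f1$sigma,
       loglik_full = f1$loglik, loglik_null = f0$loglik,
       prop_by_sex = prop, separation = separation)
}
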