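# Circular and multivariate draws used across the simulator and the HMM.

#' von Mises density
#'
#' @param x angles, radians.
#' @param mu mean direction, radians.
#' @param kappa concentration (>= 0); `kappa = 0` is the circular uniform.
#' @param log return log density?
#' @return density values on `(-pi, pi]`.
#' @export
dvonmises <- function(x, mu, kappa, log = FALSE) {
  # log I0(kappa) via the exponentially scaled Bessel for stability
  logI0 <- log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
  ld <- kappa * cos(x - mu) - log(2 * pi) - logI0
  if (log) ld else exp(ld)
}

#' von Mises random deviates (Best & Fisher rejection sampler)
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration (>= 0).
#' @return angles wrapped to `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-10) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_angle(out + mu)
}

# wrap angles to (-pi, pi]
wrap_angle <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  ifelse(w == -pi, pi, w)
}

# multivariate normal draws via Cholesky (upper); mean vector + covariance
rmvn <- function(n, mean, cov) {
  p <- length(mean)
  if (all(cov == 0)) return(matrix(rep(mean, each = n), n, p,
                                   dimnames = list(NULL, names(mean))))
  L <- chol(cov)
  z <- matrix(rnorm(n * p), n, p)
  out <- sweep(z %*% L, 2, mean, `+`)
  colnames(out) <- names(mean)
  out
}

# bivariate/multivariate normal log density (used by the GMM)
dmvnorm_log <- function(x, mean, cov) {
  p <- length(mean)
  L <- chol(cov)
  z <- forwardsolve(t(L), t(x) - mean)
  -0.5 * p * log(2 * pi) - sum(log(diag(L))) - 0.5 * colSums(z^2)
}

# truncated lognormal on (0, upper]; rejection with analytic fallback
rtrunc_lnorm <- function(n, meanlog, sdlog, upper) {
  pmax_u <- stats::plnorm(upper, meanlog, sdlog)
  u <- runif(n, 0, pmax_u)
  stats::qlnorm(u, meanlog, sdlog)
}
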