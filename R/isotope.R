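# Isotopic niche estimation: lipid normalization hook, trophic
# enrichment correction into prey space, standard ellipse areas with
# the small-sample correction, heteroscedastic group-variance linear
# models, and prey-composition contingency tests.

#' Lipid-normalize d13C values
#'
#' Applies a configurable parametric correction d13C' = d13C + f(C:N)
#' through a pluggable interface; the published normalization equations
#' vary by taxon, so the functional form and coefficients are supplied by
#' the caller. The identity model leaves values unchanged.
#'
#' @param d13C raw d13C values, per mil.
#' @param cn_ratio C:N ratios (required for non-identity models).
#' @param model `"identity"` or `"linear"`
#'   (f = beta0 + beta1 * C:N), or a function `(d13C, cn_ratio) ->
#'   corrected`.
#' @param params numeric coefficients for the named models (for
#'   `"linear"`: `c(beta0, beta1)`).
#' @return corrected d13C vector.
#' @export
lipid_normalize <- function(d13C, cn_ratio = NULL, model = "identity",
                            params = NULL) {
  if (is.function(model)) return(model(d13C, cn_ratio))
  model <- match.arg(model, c("identity", "linear"))
  if (model == "identity") return(d13C)
  if (is.null(cn_ratio) || anyNA(cn_ratio))
    stop("cn_ratio required for a non-identity lipid model")
  stopifnot(all(cn_ratio > 0), length(params) == 2)
  d13C + params[1] + params[2] * cn_ratio
}

#' Trophic enrichment correction into prey isotope space
#'
#' Subtracts the mean trophic enrichment factors from consumer-tissue
#' values (d13C - dC_mean, d15N - dN_mean) and reports the uncertainty
#' box: corrected group mean plus/minus the TEF standard deviations.
#'
#' @param d13C,d15N consumer values, per mil.
#' @param tef list with `dN_mean`, `dN_sd`, `dC_mean`, `dC_sd` (defaults
#'   are literature discrimination factors for similar seabirds).
#' @return list: `d13C`, `d15N` corrected vectors; `box` with the
#'   corrected means and half-widths (`c(lo, hi)` per axis).
#' @export
tef_correct <- function(d13C, d15N,
                        tef = list(dN_mean = 1.96, dN_sd = 0.79,
                                   dC_mean = 0.32, dC_sd = 0.86)) {
  cc <- d13C - tef$dC_mean
  nn <- d15N - tef$dN_mean
  list(d13C = cc, d15N = nn,
       box = list(
         d13C = c(mean(cc) - tef$dC_sd, mean(cc) + tef$dC_sd),
         d15N = c(mean(nn) - tef$dN_sd, mean(nn) + tef$dN_sd)))
}

#' Standard ellipse area of an isotope group
#'
#' SEA = pi * sqrt(lambda1 * lambda2) with lambda the eigenvalues of the
#' sample covariance of (d13C, d15N) (n - 1 divisor); SEAc applies the
#' small-sample correction (n - 1)/(n - 2). The ellipse polygon is the
#' 1-sd contour.
#'
#' @param d13C,d15N group observations, per mil (n >= 3).
#' @param n_polygon vertices of the returned ellipse polygon.
#' @return list: `n`, `centroid`, `covariance`, `SEA`, `SEAc` (per mil
#'   squared), `degenerate` flag, `polygon` (n_polygon x 2).
#' @export
sea_ellipse <- function(d13C, d15N, n_polygon = 100) {
  n <- length(d13C)
  stopifnot(n >= 3, length(d15N) == n)
  S <- cov(cbind(d13C, d15N))
  ev <- eigen(S, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  sea <- pi * sqrt(lam[1] * lam[2])
  degenerate <- sea <= .Machine$double.eps * 100
  th <- seq(0, 2 * pi, length.out = n_polygon)
  axes <- ev$vectors %*% diag(sqrt(lam))
  poly <- t(axes %*% rbind(cos(th), sin(th))) +
    matrix(c(mean(d13C), mean(d15N)), n_polygon, 2, byrow = TRUE)
  list(n = n, centroid = c(d13C = mean(d13C), d15N = mean(d15N)),
       covariance = S, SEA = sea, SEAc = sea * (n - 1) / (n - 2),
       degenerate = degenerate, polygon = poly)
}

#' Heteroscedastic group-variance linear model
#'
#' Maximum-likelihood fit of a linear mean model with a separate residual
#' variance per level of a grouping factor (the varIdent-style weighted
#' regression): iterates weighted least squares and per-group variance
#' updates to convergence. `lrt_heteroscedastic_lm()` compares nested
#' mean models at matched variance structure.
#'
#' @param formula mean-model formula.
#' @param data data.frame.
#' @param variance_group name of the factor defining variance groups.
#' @param tol convergence tolerance on the log-likelihood.
#' @return list: `coefficients`, `group_variances`, `loglik`, `fitted`,
#'   `residuals`, `formula`, `variance_group`, `n`.
#' @export
heteroscedastic_lm <- function(formula, data, variance_group,
                               tol = 1e-8, max_iter = 200) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, data)
  g <- factor(data[[variance_group]])
  ng <- table(g)
  if (any(ng < 2))
    stop("unidentifiable variance group(s): ",
         paste(names(ng)[ng < 2], collapse = ", "))
  v <- rep(var(y), nlevels(g))
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    w <- 1 / v[as.integer(g)]
    beta <- solve(crossprod(X, w * X), crossprod(X, w * y))
    r <- y - as.vector(X %*% beta)
    v <- as.vector(tapply(r^2, g, mean))   # ML variance estimates
    ll <- sum(dnorm(r, 0, sqrt(v[as.integer(g)]), log = TRUE))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(coefficients = setNames(as.vector(beta), colnames(X)),
       group_variances = setNames(as.vector(v), levels(g)),
       loglik = ll, fitted = as.vector(X %*% beta), residuals = r,
       formula = formula, variance_group = variance_group, n = length(y))
}

#' Likelihood-ratio test between nested heteroscedastic mean models
#'
#' @param full,reduced fits from [heteroscedastic_lm()] on the same data
#'   and variance grouping.
#' @return list: `statistic`, `df`, `p_value`.
#' @export
lrt_heteroscedastic_lm <- function(full, reduced) {
  stopifnot(full$n == reduced$n,
            identical(full$variance_group, reduced$variance_group))
  df <- length(full$coefficients) - length(reduced$coefficients)
  stopifnot(df > 0)
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Prey-composition chi-squared test
#'
#' Pearson chi-squared on a groups x prey-types count table with
#' df = (r-1)(c-1); expected counts are reported and a warning is issued
#' when any expected count is below 5.
#'
#' @param counts nonnegative integer matrix (groups x prey families).
#' @return list: `statistic`, `df`, `p_value`, `expected`.
#' @export
prey_composition_test <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero row or column margin in prey table")
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  stat <- sum((counts - E)^2 / E)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  if (any(E < 5)) warning("expected counts below 5; chi-squared ",
                          "approximation may be poor")
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE), expected = E)
}

#' Keep only the first sample per repeated individual
#'
#' Repeated-measures rule for isotope modelling: when an individual was
#' sampled in several years, only the earliest record is retained.
#'
#' @param samples data.frame with a `bird_id` column and an ordering
#'   column (`year` or `timestamp`).
#' @param order_col column to order within individuals.
#' @return the filtered data.frame.
#' @export
first_sample_per_individual <- function(samples, order_col = "year") {
  o <- order(samples$bird_id, samples[[order_col]])
  s <- samples[o, , drop = FALSE]
  s[!duplicated(s$bird_id), , drop = FALSE]
}
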