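# Kleptoparasitism event processing (discretization, exact contingency
# tests, behavioural context) and morphometric discrimination.

#' Discretize raw interaction intervals into events
#'
#' Per-bird, time-sorted intervals separated by a gap strictly shorter
#' than `gap_s` are merged into one discrete event (durations summed via
#' the merged span); overlapping raw intervals are merged with a warning.
#'
#' @param intervals data.frame: `bird_id`, `start`, `end`.
#' @param gap_s gap defining discreteness, seconds.
#' @return data.frame of merged events: `bird_id`, `start`, `end`,
#'   `duration_s`, `n_raw` (raw intervals merged in).
#' @export
discretize_events <- function(intervals, gap_s = 30) {
  if (nrow(intervals) == 0)
    return(cbind(intervals, duration_s = numeric(0), n_raw = integer(0)))
  out <- lapply(split(intervals, intervals$bird_id), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1 &&
        any(as.numeric(d$start[-1]) < as.numeric(d$end[-nrow(d)])))
      warning("overlapping raw intervals merged")
    s <- as.numeric(d$start); e <- as.numeric(d$end)
    cs <- s[1]; ce <- e[1]; k <- 1L
    starts <- numeric(0); ends <- numeric(0); ns <- integer(0)
    for (i in seq_len(nrow(d))[-1]) {
      if (s[i] - ce < gap_s) {  # strictly-less-than rule
        ce <- max(ce, e[i]); k <- k + 1L
      } else {
        starts <- c(starts, cs); ends <- c(ends, ce); ns <- c(ns, k)
        cs <- s[i]; ce <- e[i]; k <- 1L
      }
    }
    starts <- c(starts, cs); ends <- c(ends, ce); ns <- c(ns, k)
    data.frame(bird_id = d$bird_id[1],
               start = as.POSIXct(starts, origin = "1970-01-01", tz = "UTC"),
               end = as.POSIXct(ends, origin = "1970-01-01", tz = "UTC"),
               duration_s = ends - starts, n_raw = ns,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric enumeration with both margins fixed. The
#' two-sided p-value is the sum of probabilities of all tables no more
#' probable than the observed one (the convention of standard software);
#' a doubling rule (2 x one-sided, capped at 1) is available by flag.
#' The reported odds ratio is the conditional maximum-likelihood
#' estimate.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @param method `"minlike"` (default) or `"doubling"`.
#' @return list: `p_value`, `odds_ratio`.
#' @export
fisher_exact <- function(table, method = c("minlike", "doubling")) {
  method <- match.arg(method)
  tb <- as.matrix(table)
  stopifnot(all(dim(tb) == 2))
  if (any(tb < 0) || any(tb != round(tb)))
    stop("table entries must be nonnegative integers")
  m <- sum(tb[1, ]); n2 <- sum(tb[2, ]); K <- sum(tb[, 1])
  lo <- max(0, K - n2); hi <- min(K, m)
  support <- lo:hi
  logp <- stats::dhyper(support, m, n2, K, log = TRUE)
  x <- tb[1, 1]
  pobs <- logp[support == x]
  p <- if (method == "minlike") {
    sum(exp(logp[logp <= pobs + 1e-7]))
  } else {
    lower <- sum(exp(logp[support <= x]))
    upper <- sum(exp(logp[support >= x]))
    min(1, 2 * min(lower, upper))
  }
  list(p_value = min(p, 1), odds_ratio = cml_odds_ratio(tb, support, m, n2, K))
}

# conditional ML odds ratio under the noncentral hypergeometric
cml_odds_ratio <- function(tb, support, m, n2, K) {
  x <- tb[1, 1]
  if (x == min(support)) return(0)
  if (x == max(support)) return(Inf)
  logdc <- stats::dhyper(support, m, n2, K, log = TRUE)
  mean_x <- function(log_psi) {
    lw <- logdc + support * log_psi
    w <- exp(lw - max(lw))
    sum(support * w) / sum(w)
  }
  f <- function(lp) mean_x(lp) - x
  uniroot(f, c(-50, 50), tol = 1e-12)$root |> exp()
}

#' Behavioural context of kleptoparasitism events
#'
#' Events matched to decoded fixes are labelled `during_forage` when the
#' matched fix is decoded forage, `near_forage` when any forage-decoded
#' fix lies within the time window of the event start (default 2.4 min),
#' else `other`; unmatched events get `missing_context`. Coast distances
#' are attached when a world is supplied.
#'
#' @param events event table with `start` (and `bird_id`).
#' @param decoded_fixes regularized fixes with `timestamp`, decoded
#'   `state`, and `x`, `y` if coast distance is wanted.
#' @param window_min near-forage window, minutes.
#' @param world optional [cpf_world()] for coast distances.
#' @param dt_s track time step, seconds.
#' @return events with `context` and optional `coast_distance_km`.
#' @export
event_context <- function(events, decoded_fixes, window_min = 2.4,
                          world = NULL, dt_s = 30) {
  idx <- match_times_to_fixes(events$start, decoded_fixes$timestamp, dt_s)
  forage_t <- as.numeric(decoded_fixes$timestamp[
    decoded_fixes$state == "forage"])
  ctx <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    if (is.na(idx[i])) { ctx[i] <- "missing_context"; next }
    if (decoded_fixes$state[idx[i]] == "forage") {
      ctx[i] <- "during_forage"
    } else if (length(forage_t) &&
               min(abs(forage_t - as.numeric(events$start[i]))) <=
               window_min * 60) {
      ctx[i] <- "near_forage"
    } else ctx[i] <- "other"
  }
  events$fix_index <- idx
  events$context <- ctx
  if (!is.null(world)) {
    events$coast_distance_km <- NA_real_
    ok <- !is.na(idx)
    events$coast_distance_km[ok] <- pmax(0, coast_distance(
      decoded_fixes$x[idx[ok]], decoded_fixes$y[idx[ok]], world$coastline))
  }
  events
}

#' Linear discriminant sexing from morphometrics
#'
#' Two-class linear discriminant with pooled covariance trained on birds
#' of known sex; returns predictions with posterior probabilities
#' (ambiguous zone 0.4-0.6 flagged), discriminant coefficients
#' proportional to pooledSigma^-1 (mu_F - mu_M), and leave-one-out
#' cross-validated accuracy on the training set.
#'
#' @param train data.frame with `sex` (`"F"`/`"M"`) and numeric predictor
#'   columns; >= 5 per sex, no missing predictors.
#' @param newdata optional data.frame of unknowns (same predictors).
#' @param predictors predictor column names; default all numeric columns
#'   of `train` except `sex`.
#' @return list: `coefficients`, `loo_accuracy`, `predictions`
#'   (data.frame with `sex_pred`, `posterior_F`, `ambiguous`) for
#'   `newdata`.
#' @export
sex_discriminant <- function(train, newdata = NULL, predictors = NULL) {
  if (is.null(predictors))
    predictors <- names(train)[vapply(train, is.numeric, TRUE) &
                                 names(train) != "sex"]
  X <- as.matrix(train[, predictors])
  if (anyNA(X)) stop("missing predictor values in training data")
  sex <- factor(train$sex, levels = c("F", "M"))
  stopifnot(all(table(sex) >= 5))
  fit_lda <- function(X, sex) {
    muF <- colMeans(X[sex == "F", , drop = FALSE])
    muM <- colMeans(X[sex == "M", , drop = FALSE])
    nF <- sum(sex == "F"); nM <- sum(sex == "M")
    Sp <- ((nF - 1) * cov(X[sex == "F", , drop = FALSE]) +
             (nM - 1) * cov(X[sex == "M", , drop = FALSE])) / (nF + nM - 2)
    if (rcond(Sp) < 1e-12)
      stop("singular pooled covariance; drop collinear predictors")
    w <- solve(Sp, muF - muM)
    # log posterior odds for F vs M at x (equal-cost rule)
    b0 <- -0.5 * sum(w * (muF + muM)) + log(nF / nM)
    list(w = w, b0 = b0)
  }
  mod <- fit_lda(X, sex)
  post_F <- function(mod, Xn) plogis(as.vector(Xn %*% mod$w) + mod$b0)
  loo <- vapply(seq_len(nrow(X)), function(i) {
    m <- fit_lda(X[-i, , drop = FALSE], sex[-i])
    pf <- post_F(m, X[i, , drop = FALSE])
    (pf >= 0.5) == (sex[i] == "F")
  }, TRUE)
  predictions <- NULL
  if (!is.null(newdata)) {
    Xn <- as.matrix(newdata[, predictors])
    pf <- post_F(mod, Xn)
    predictions <- data.frame(
      sex_pred = ifelse(pf >= 0.5, "F", "M"),
      posterior_F = pf,
      ambiguous = pf > 0.4 & pf < 0.6)
  }
  list(coefficients = mod$w, intercept = mod$b0,
       loo_accuracy = mean(loo), predictions = predictions)
}

#' Cohen's d standardized mean difference
#'
#' d = (mean_a - mean_b) / pooled sd, with the pooled sd using the
#' (n_a + n_b - 2) denominator.
#'
#' @param a,b numeric samples (n >= 2 each).
#' @return scalar d; NA with a warning when the pooled sd is zero.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2, nb >= 2)
  sp <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
  if (sp == 0) { warning("zero pooled sd; d undefined"); return(NA_real_) }
  (mean(a) - mean(b)) / sp
}

#' Column-standardize morphometrics
#'
#' The (x - mean)/sd transform behind radial morphometric plots; each
#' numeric column gets mean 0, sd 1.
#'
#' @param morpho data.frame of measurements.
#' @param cols columns to scale (default all numeric).
#' @return the data.frame with scaled columns.
#' @export
standardize_morpho <- function(morpho, cols = NULL) {
  if (is.null(cols))
    cols <- names(morpho)[vapply(morpho, is.numeric, TRUE)]
  for (cc in cols) morpho[[cc]] <- as.vector(scale(morpho[[cc]]))
  morpho
}
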