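# Event discretization, exact contingency tests, event context and
# morphometric discrimination.

t0 <- as.POSIXct("2018-02-01 10:00:00", tz = "UTC")

iv <- function(s, e, bird = "b1") {
  data.frame(bird_id = bird, start = t0 + s, end = t0 + e,
             stringsAsFactors = FALSE)
}

test_that("interval merging applies the 30 s gap rule", {
  # gap 15 s -> one event
  one <- discretize_events(rbind(iv(0, 10), iv(25, 40)))
  expect_identical(nrow(one), 1L)
  expect_equal(one$duration_s, 40)
  expect_identical(one$n_raw, 2L)
  # gap 45 s -> two events
  two <- discretize_events(rbind(iv(0, 10), iv(55, 70)))
  expect_identical(nrow(two), 2L)
  # boundary: exactly 30 s gap stays discrete (strictly-less-than rule)
  expect_identical(nrow(discretize_events(rbind(iv(0, 10), iv(40, 50)))), 2L)
  # overlap warns and merges
  expect_warning(ov <- discretize_events(rbind(iv(0, 20), iv(10, 30))),
                 "overlapping")
  expect_identical(nrow(ov), 1L)
})

test_that("merging matches a sweep-line oracle and is idempotent", {
  set.seed(28)
  s <- sort(runif(60, 0, 3000))
  raw <- iv(s, s + runif(60, 1, 20))
  merged <- suppressWarnings(discretize_events(raw))
  # sweep-line oracle: union of intervals inflated by the gap
  ss <- sort(as.numeric(raw$start)); ee <- as.numeric(raw$end)[order(raw$start)]
  cnt <- 1L
  for (i in 2:60) if (ss[i] - max(ee[1:(i - 1)]) >= 30) cnt <- cnt + 1L
  expect_identical(nrow(merged), cnt)
  again <- suppressWarnings(
    discretize_events(merged[, c("bird_id", "start", "end")]))
  expect_equal(again$start, merged$start)
  expect_equal(again$end, merged$end)
  # order independence
  shuf <- suppressWarnings(discretize_events(raw[sample(60), ]))
  expect_equal(shuf$start, merged$start)
})

test_that("Fisher exact matches enumeration and the reference test", {
  # trivial symmetric table
  expect_equal(fisher_exact(matrix(c(1, 0, 0, 1), 2, 2))$p_value, 1)
  # transpose invariance and range
  set.seed(29)
  for (i in 1:20) {
    tb <- matrix(rpois(4, 4), 2, 2)
    if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) next
    got <- fisher_exact(tb)
    ref <- fisher.test(tb)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(fisher_exact(t(tb))$p_value, got$p_value,
                 tolerance = 1e-12)
    expect_true(got$p_value > 0 && got$p_value <= 1)
    if (is.finite(got$odds_ratio) && got$odds_ratio > 0)
      expect_equal(got$odds_ratio, unname(ref$estimate), tolerance = 1e-4)
  }
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2, 2)), "nonnegative")
})

test_that("event context follows the decode and the 2.4 min window", {
  fixes <- data.frame(
    timestamp = t0 + seq(0, by = 30, length.out = 60),
    state = c(rep("travel", 20), rep("forage", 20), rep("travel", 20)),
    x = seq(20, 50, length.out = 60), y = 0)
  w <- fix_world()
  ev <- data.frame(bird_id = "b1",
                   start = t0 + c(20 * 30 + 10,  # inside forage block
                                  19 * 30,       # 30 s before forage
                                  5 * 30,        # far from forage
                                  1e6))          # outside span
  out <- event_context(ev, fixes, world = w)
  expect_identical(out$context,
                   c("during_forage", "near_forage", "other",
                     "missing_context"))
  expect_true(all(!is.na(out$coast_distance_km[1:3])))
  # brute-force scan oracle over a random batch
  set.seed(30)
  evr <- data.frame(bird_id = "b1", start = t0 + runif(100, 0, 1770))
  got <- event_context(evr, fixes)
  forage_t <- as.numeric(fixes$timestamp[fixes$state == "forage"])
  oracle <- vapply(seq_len(100), function(i) {
    tm <- as.numeric(evr$start[i])
    d <- abs(as.numeric(fixes$timestamp) - tm)
    fi <- which(d <= 15)
    if (!length(fi)) return("missing_context")
    fi <- min(fi)
    if (fixes$state[fi] == "forage") "during_forage"
    else if (min(abs(forage_t - tm)) <= 144) "near_forage"
    else "other"
  }, "")
  expect_identical(got$context, oracle)
})

morpho_sample <- function(n_per, sep = 3, seed = 31) {
  set.seed(seed)
  mu_f <- c(100, 50); mu_m <- mu_f - sep
  d <- rbind(
    data.frame(sex = "F", m1 = rnorm(n_per, mu_f[1]),
               m2 = rnorm(n_per, mu_f[2])),
    data.frame(sex = "M", m1 = rnorm(n_per, mu_m[1]),
               m2 = rnorm(n_per, mu_m[2])))
  d
}

test_that("discriminant sexing recovers well-separated sexes", {
  d <- morpho_sample(40, sep = 3)
  fit <- sex_discriminant(d, newdata = d)
  expect_gte(fit$loo_accuracy, 0.95)
  expect_true(all(c("sex_pred", "posterior_F", "ambiguous") %in%
                    names(fit$predictions)))
  # direction proportional to pooled-Sigma^-1 (mu_F - mu_M)
  X <- as.matrix(d[, c("m1", "m2")])
  sex <- factor(d$sex)
  muF <- colMeans(X[sex == "F", ]); muM <- colMeans(X[sex == "M", ])
  Sp <- ((39) * cov(X[sex == "F", ]) + (39) * cov(X[sex == "M", ])) / 78
  w_o <- solve(Sp, muF - muM)
  ratio <- fit$coefficients / w_o
  expect_lt(diff(range(ratio)), 1e-9)
})

test_that("no signal gives chance-level LOO accuracy", {
  d <- morpho_sample(50, sep = 0, seed = 32)
  fit <- sex_discriminant(d)
  expect_lt(abs(fit$loo_accuracy - 0.5), 4 * sqrt(0.25 / 100) + 0.05)
})

test_that("LDA agrees with the MASS reference", {
  skip_if_not_installed("MASS")
  d <- morpho_sample(30, sep = 2, seed = 33)
  fit <- sex_discriminant(d, newdata = d)
  ref <- MASS::lda(sex ~ m1 + m2, data = d)
  pr <- predict(ref, d)
  expect_identical(fit$predictions$sex_pred, as.character(pr$class))
  expect_equal(fit$predictions$posterior_F, unname(pr$posterior[, "F"]),
               tolerance = 1e-9)
})

test_that("Cohen's d is the standardized mean difference", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  # means 10 vs 8 with pooled sd 2 -> d = 1
  a <- c(8, 12); b <- c(6, 10)   # sds = 2*sqrt(2)... construct directly
  a <- c(9, 11); b <- c(7, 9)    # means 10, 8; pooled sd = sqrt(2)
  expect_equal(cohens_d(a, b), 2 / sqrt(2), tolerance = 1e-12)
  # population limit
  set.seed(34)
  x <- rnorm(20000, 1, 2); y <- rnorm(20000, 0, 2)
  expect_lt(abs(cohens_d(x, y) - 0.5), 0.03)
  expect_warning(dd <- cohens_d(c(1, 1), c(1, 1)), "zero pooled sd")
  expect_true(is.na(dd))
})

test_that("morphometric standardization yields mean 0 sd 1", {
  d <- morpho_sample(20)
  s <- standardize_morpho(d, c("m1", "m2"))
  expect_equal(mean(s$m1), 0, tolerance = 1e-12)
  expect_equal(sd(s$m2), 1, tolerance = 1e-12)
})
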