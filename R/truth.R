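#' Ground-truth parameter set for the synthetic colony simulator
#'
#' Bundles every distribution the generator draws from, so downstream
#' estimators can be tested by parameter recovery. Defaults describe a
#' plunge-diving tropical booby: three behavioural states (rest on water,
#' area-restricted foraging, directed travel) switching as a Markov chain
#' at the fix interval, gamma step lengths and von Mises turn angles per
#' state, shallow dives (< 2 m) at a fixed rate while foraging, a slowly
#' drifting pressure sensor, state-dependent leg immersion, sex- and
#' coast-distance-dependent kleptoparasitic attack risk, two-source
#' isotope mixing with trophic enrichment, multinomial prey composition
#' and sex-dimorphic morphometrics.
#'
#' @param tactic `"coastal"` (short neritic trips) or `"pelagic"`
#'   (faster, more persistent travel; longer-range trips).
#' @return object of class `cpf_truth` (a validated parameter list).
#' @export
cpf_truth <- function(tactic = c("coastal", "pelagic")) {
  tactic <- match.arg(tactic)
  trans <- matrix(c(
    0.95, 0.03, 0.02,
    0.02, 0.93, 0.05,
    0.02, 0.06, 0.92), 3, 3, byrow = TRUE,
    dimnames = list(.cpf_states, .cpf_states))
  step <- rbind(rest   = c(mean = 0.005, sd = 0.004),
                forage = c(mean = 0.120, sd = 0.070),
                travel = c(mean = 0.330, sd = 0.100))
  turn <- rbind(rest   = c(mu = 0, kappa = 0.3),
                forage = c(mu = 0, kappa = 0.9),
                travel = c(mu = 0, kappa = 18))
  if (tactic == "pelagic") {
    step["travel", ] <- c(mean = 0.380, sd = 0.110)
    trans["travel", ] <- c(0.015, 0.035, 0.95)
  }
  iso_groups <- list(
    RFB_F = list(mean = c(d13C = -16.9, d15N = 7.7), cov = diag(c(0.2, 0.3)^2)),
    RFB_M = list(mean = c(d13C = -17.2, d15N = 7.5), cov = diag(c(0.2, 0.2)^2)),
    BB_F  = list(mean = c(d13C = -16.5, d15N = 7.5), cov = diag(c(0.3, 0.1)^2)),
    BB_M  = list(mean = c(d13C = -16.9, d15N = 7.2), cov = diag(c(0.5, 0.1)^2)),
    prey_flyingfish = list(mean = c(d13C = -17.3, d15N = 5.5),
                           cov = diag(c(0.86, 0.79)^2)),
    prey_ballyhoo   = list(mean = c(d13C = -17.4, d15N = 5.6),
                           cov = diag(c(0.86, 0.79)^2)),
    prey_other      = list(mean = c(d13C = -16.8, d15N = 6.0),
                           cov = diag(c(0.9, 0.9)^2)))
  prey_probs <- rbind(
    RFB = c(flyingfish = 0.55, ballyhoo = 0.30, other = 0.15),
    BB  = c(flyingfish = 0.30, ballyhoo = 0.50, other = 0.20))
  morpho_names <- c("mass_g", "wing_mm", "bill_length_mm", "bill_depth_mm",
                    "tarsus_mm", "tail_mm")
  msd <- c(80, 8, 2.5, 1.0, 1.5, 8)
  morpho <- list(
    F = list(mean = setNames(c(1320, 425, 103, 30, 47, 200), morpho_names),
             cov = diag(msd^2)),
    M = list(mean = setNames(c(980, 400, 97, 27, 44, 198), morpho_names),
             cov = diag(msd^2)))
  out <- structure(list(
    transition = trans,
    step_gamma = step,
    turn_vonmises = turn,
    dive_rate_forage = 14,          # dives h^-1 while in the forage state
    dive_depth = list(meanlog = log(0.6), sdlog = 0.5, max_depth_m = 2),
    dive_duration = list(mean_s = 4, shape = 4),
    sensor_drift = list(slope_m_h = 0.3, noise_sd_m = 0.02),
    immersion_rule = c(rest = 0.95, forage = 0.50, travel = 0.02),
    klepto_model = c(intercept = -4.0, male = -3.0, coast_km = -0.5),
    isotope_model = iso_groups,
    tef = list(dN_mean = 1.96, dN_sd = 0.79, dC_mean = 0.32, dC_sd = 0.86),
    prey_probs = prey_probs,
    morpho_model = morpho,
    tactic = tactic
  ), class = "cpf_truth")
  validate_truth(out)
  out
}

#' Validate a truth parameter set
#'
#' Checks the structural invariants: row-stochastic transition matrix,
#' positive gamma moments, nonnegative concentrations, positive dive
#' depths and row-stochastic prey composition.
#'
#' @param truth a [cpf_truth()] (or modified copy).
#' @return the object, invisibly; errors on violation.
#' @export
validate_truth <- function(truth) {
  stopifnot(
    is.matrix(truth$transition), nrow(truth$transition) == 3,
    all(abs(rowSums(truth$transition) - 1) < 1e-10),
    all(truth$transition >= 0),
    all(truth$step_gamma[, "mean"] > 0), all(truth$step_gamma[, "sd"] > 0),
    all(truth$turn_vonmises[, "kappa"] > 0),
    truth$dive_depth$max_depth_m > 0,
    all(abs(rowSums(truth$prey_probs) - 1) < 1e-10),
    all(truth$prey_probs >= 0),
    all(truth$immersion_rule >= 0 & truth$immersion_rule <= 1),
    truth$tef$dN_sd >= 0, truth$tef$dC_sd >= 0
  )
  invisible(truth)
}
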