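---
title: "Methods: behavioural segmentation, space use and trophic niche of central-place foragers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioural segmentation, space use and trophic niche of central-place foragers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cpforage` implements a complete multi-sensor analysis pipeline for
studies of foraging segregation in central-place foraging seabirds:
GPS tracks are filtered, segmented into trips and regularized; a hidden
Markov model decodes behavioural states; foraging locations feed kernel
utilization distributions whose overlap is quantified; depth and
immersion loggers validate the decode and yield dive metrics; trip
tactics are clustered and tested for sex differences; and stable
isotopes summarize trophic niche. Because tracking datasets of this
kind are rarely deposited, the package ships a seeded synthetic colony
simulator whose ground truth makes every stage testable by parameter
recovery. This vignette records the models, the defaults and why, the
numerical choices, and what the synthetic world does and does not
establish.

## The simulated world

All simulation and analysis run in a local azimuthal equidistant plane
centred on the colony, so step lengths in km are exact great-circle
distances near the colony and match the HMM's emission metric; lon/lat
appear only at the file boundary. The default world is an oceanic
island: an elliptical coastline (semi-axes 15 x 4 km) with the colony
at the origin, and a bathymetry raster (1 km resolution, positive-down
metres) that deepens exponentially away from the coast towards an
1800 m basin — the narrow-shelf profile typical of tropical islands.
Distance to coast is the Euclidean distance to the polygon boundary,
positive offshore, which gives simple exact oracles for the tests.

Movement is a three-state Markov chain (rest, forage, travel) at the
fix interval with gamma step lengths and von Mises turn angles per
state. Defaults are chosen for a plunge-diving booby sampled at 30 s:
rest steps of 5 m (drifting on water), foraging steps of 120 m
(area-restricted search, low turn concentration), travel steps of
330 m (~40 km/h directed flight, kappa = 18). Trips start at the
colony, run the free chain for a specified duration, then return by a
biased walk towards the colony. The homing phase is flagged rather
than blended into the chain: conditioning the chain on return would
distort the emission distributions, and recovery tests exclude the
flagged tail. Departure times are drawn from N(7, 1) hours local solar
time, one trip per day; night-time rest is treated as ordinary rest
state (no separate rafting process).

Dives occur only in the forage state, as a Poisson process
(14 h^-1 while foraging, matching an overall rate near 7 h^-1 at ~50%
foraging time) with triangular profiles, truncated-lognormal maximum
depths capped at 2 m (nearly all foraging within the top 2 m), and
durations of a few seconds. Sensor drift (0.3 m/h default, well inside
the 1 m/h design envelope of the correction) and Gaussian noise are
added after dive construction, so the true dive list is exact.
Kleptoparasitic attacks are Bernoulli per forage fix with logistic
probability in sex and distance-to-coast (female-biased, coastal-
concentrated); isotopes are bivariate normal per species-sex group
with means in the range typical of tropical seabird blood and prey;
prey counts are multinomial; morphometrics are normal per sex with
females larger.

One integer master seed feeds documented per-stream sub-seeds
(`stream_seed()`), so adding birds does not perturb the isotope draws
and every generator is bit-reproducible.

What a green test establishes: that each estimator recovers the
parameters of this stated world at the stated tolerances. What it does
not: robustness to location error, gappy sampling, tides, wind, prey
patchiness or behavioural states outside the three-state repertoire —
none of which the generator emulates.

## Preprocessing

Speeds above 95 km/h are treated as implausible. The filter is a
forward scan that removes the later fix of an offending pair and
recomputes from the retained predecessor, iterating until no implied
speed exceeds the threshold; this is deterministic and idempotent. The
iteration choice (single pass vs to-fixpoint) is genuinely open;
to-fixpoint was chosen so the output satisfies the speed bound
unconditionally.

Trips are contiguous runs of fixes beyond 500 m of the colony;
candidates shorter than 30 min between boundary crossings are
discarded as colony-based movement, and runs that never re-enter
before the data end are flagged partial. Complete trips keep one
bounding within-radius fix per side so the trip starts and ends at the
colony. The 30 min rule is applied to crossing-to-crossing time, not
fix counts, so 30 s and 2 min sampling behave identically.

Regularization to 30 s uses a shape-preserving piecewise cubic Hermite
interpolant (Fritsch–Carlson slopes, the PCHIP construction) applied
to x(t) and y(t) independently; knots are reproduced exactly, linear
motion stays linear, and no extrapolation occurs beyond the first and
last fix.

## The hidden Markov model

Emissions are gamma (step length, mean/sd parameterized) and von Mises
(turn angle) per state; turns at trip starts are missing, contributing
only the step density. Zero-length steps are floored at 1 m — the
gamma density is undefined at zero and 1 m is far below any
behavioural scale at 30 s sampling. Trips are independent chains: the
initial distribution (the stationary distribution of the transition
matrix) is re-applied at each trip boundary.

Fitting is direct maximization of the forward-algorithm log-likelihood
(computed in C++ with per-step rescaling) over an unconstrained
working space: logs for gamma moments and concentrations, multinomial
logits for transition rows, the raw angle for the turn mean. The
search is quasi-Newton (L-BFGS-B) with wide box constraints in the
working space; the boxes exist because unbounded quasi-Newton can send
a state that has lost all its posterior mass to a degenerate corner.
Twenty-five random restarts are drawn uniformly within realistic
limits (step means and sds 0.01–2 km, kappa 0.1–10; the limits are
config-exposed rather than hard-coded).
States are relabelled after fitting by ascending mean step length
(rest < forage < travel), which makes fits comparable across runs.
Direct maximization rather than EM keeps the circular parameter and
the model-comparison workflow (negative log-likelihood across
candidate fits) straightforward.

Decoding returns both the Viterbi path and forward–backward
posteriors; the behavioural validation cross-tabulates dive rate and
wet fraction by decoded state and passes when foraging fixes out-dive
travelling fixes. One model is fitted per species by default (the
pooled-vs-per-species choice is left to the caller; both run through
the same interface).

## Space use

Utilization distributions are Gaussian-kernel densities with a full
2 x 2 bandwidth matrix selected by least-squares cross-validation
(Cholesky-parameterized Nelder–Mead on the exact pairwise criterion,
started at the normal-reference bandwidth). LSCV is known to
degenerate under duplicated points — the criterion decreases without
bound as H collapses — so a collapse of det(H) below 10^-4 of the
reference (or any failure to improve on it) triggers a plug-in
fallback with a warning and a flag. Surfaces are evaluated on a
512 x 512 grid by default (sub-km resolution at study scale) and
renormalized to integrate to one on the grid.

Isopleths are greedy highest-density regions: cells enter in order of
descending density until the target mass (0.5 core, 0.9 main) is
reached. Overlap uses Bhattacharyya's affinity, sum of sqrt(p q) over
cells. Because the reported statistic refers to overlap of the 50%
and 90% contours, the default restricts each density to its own
isopleth mask and renormalizes before computing the affinity; the
textbook full-support variant is exposed via `level = NULL`. Dive
rates and event counts are summarized on 5 x 5 km grids anchored at
the colony (anchoring fixes cell identity across runs); empty cells
are absent, not zero.

## Dives and immersion

The zero-offset correction subtracts a rolling lower-quantile baseline
(default 600 s window, 0.05 quantile — the window is two orders of
magnitude above the seconds-scale dives of surface feeders, and the
low quantile resists dive contamination; both are config-exposed). A
lower quantile of a drifting window estimates the baseline at the
window's q-position rather than its centre, so the baseline series is
shifted by (0.5 − q) x window before subtraction; this removes a
linear drift without lag bias and makes the correction idempotent.
Dives are maximal runs of corrected depth strictly above 0.25 m.
Events (dives, immersion samples) are matched to the fix whose centred
30 s window contains their start, with exact boundary ties going to
the earlier fix for determinism.

## Trip structure

Trip metrics are total path length, maximum colony distance, duration,
mean coast distance, median bathymetry under the fixes (missing cells
excluded with a warning) and time-in-state proportions. Tactic
clustering is a Gaussian mixture with full covariances fitted by EM on
z-scored duration, coast distance and maximum distance (the final
variable set is taken as given; standardization is used because the
variables differ by an order of magnitude in scale, and the choice is
config-visible through the stored scaling). K is selected by BIC over
1–5 with seeded restarts; components are ordered by ascending mean
duration so the last component is the pelagic tactic. Singular
covariances during EM are ridged and reported.

The sex test is a random-intercept binomial model,
logit P(pelagic) = b0 + b1 male + u(bird), fitted by maximum
likelihood with adaptive Gauss–Hermite quadrature (15 nodes; each
cluster's nodes are recentred at its Laplace mode). The likelihood
ratio against the intercept-only model (same random structure) is
referred to chi-squared with one degree of freedom. The sigma = 0
boundary is handled explicitly: when plain logistic regression
achieves at least the quadrature optimum, the boundary fit is
returned, which also makes the zero-variance limit exactly reproduce
the IRLS solution. Complete separation is flagged.

## Isotopic niche and diet

Lipid normalization is a pluggable hook (identity default, linear
delta13C' = delta13C + b0 + b1 C:N available, arbitrary functions
accepted) because published normalization equations are taxon-specific
and should be supplied by the analyst.
Trophic enrichment correction subtracts the configured factors
(defaults 1.96 per mil d15N, 0.32 per mil d13C, SDs 0.79 and 0.86)
and reports the mean +/- SD uncertainty box in prey space.

The standard ellipse area is pi sqrt(lambda1 lambda2) from the
eigenvalues of the group covariance of (d13C, d15N), with the
small-sample correction SEAc = SEA (n-1)/(n-2). The covariance divisor
is pinned to n-1 (the choice is config-visible in the returned
covariance); collinear groups return SEA = 0 with a degenerate flag.
A repeated-individual rule (`first_sample_per_individual()`) keeps the
earliest record per bird before modelling.

Group differences in delta values use a linear mean model with one
residual variance per factor level, fitted by ML via iterated weighted
least squares to a 1e-8 log-likelihood tolerance; nested mean models
are compared by likelihood ratio at matched variance structure. Prey
composition uses the Pearson chi-squared with expected counts reported
and a small-expected-count warning.

## Kleptoparasitism and morphometrics

Raw interaction intervals merge when separated by strictly less than
30 s (the boundary case — exactly 30 s — stays discrete). The sex-bias
test is the exact hypergeometric 2 x 2 test; the two-sided p-value
sums all tables no more probable than the observed one, the convention
that reproduces standard software, with the doubling rule available by
flag. The reported odds ratio is the conditional ML estimate under the
noncentral hypergeometric. Event context is `during_forage` when the
matched fix is decoded forage, `near_forage` when any forage fix lies
within 2.4 min, else `other`.

Morphometric sexing is a two-class linear discriminant with pooled
covariance, leave-one-out accuracy, and posterior probabilities with
an ambiguous zone (0.4–0.6) flagged — predictions are meant to be
applied only outside that zone. Effect sizes are Cohen's d with the
(n_a + n_b - 2) pooled denominator.

## Numerical notes and limitations

* Forward recursions rescale per step; enumeration oracles verify the
  implementation to 1e-8 on short sequences.
* The LSCV criterion is evaluated exactly (all pairs) in C++; at very
  large n a subsample is advisable before bandwidth selection.
* The GMM's BIC counts K-1 + Kp + Kp(p+1)/2 free parameters.
* Quadrature log-likelihoods are stable to ~1e-5 between 15 and 25
  nodes on the test fixtures.
* No boundary-corrected (coastline-clipped) KDE is provided; densities
  can spill over land, as in the uncorrected workflow it mirrors.
* The simulator's world has no wind, currents, tides, prey fields or
  frigatebird agents; kleptoparasitism risk is a static logistic
  surface.
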