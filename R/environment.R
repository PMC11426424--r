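#' Draw basic payoffs for the bandit arms
#'
#' Each behavior's basic payoff is `round(2 * X^2)` with `X ~ Exponential(1)`:
#' most payoffs fall in 0-50 with a long right tail. Rounding is half away
#' from zero so results are bit-stable across platforms.
#'
#' @param n_behaviors Number of behaviors (arms) to draw.
#' @return Integer vector of non-negative payoffs.
#' @examples
#' set.seed(1); draw_basic_payoffs(10)
#' @export
draw_basic_payoffs <- function(n_behaviors) {
  stopifnot(n_behaviors >= 1)
  x <- stats::rexp(n_behaviors, rate = 1)
  as.integer(floor(2 * x^2 + 0.5))
}

#' Create a restless-bandit payoff environment
#'
#' One payoff table per deme: a vector of basic integer payoffs over a shared
#' behavior index space. Tables are drawn independently across demes. Each
#' round, every payoff is independently redrawn with probability `change_prob`
#' (the "restless" dynamic).
#'
#' @param n_behaviors Number of behaviors (default 100).
#' @param n_demes Number of demes (1, or 3 under the spatial extension).
#' @param change_prob Per-behavior, per-round probability of payoff change.
#' @return An object of class `bandit_environment`: a list with the payoff
#'   matrix `payoffs` (`n_demes` x `n_behaviors`) and `change_prob`.
#' @export
bandit_environment <- function(n_behaviors = 100, n_demes = 1,
                               change_prob = 0.01) {
  stopifnot(n_behaviors >= 1, n_demes >= 1,
            change_prob >= 0, change_prob <= 1)
  payoffs <- matrix(0L, nrow = n_demes, ncol = n_behaviors)
  for (d in seq_len(n_demes)) payoffs[d, ] <- draw_basic_payoffs(n_behaviors)
  structure(list(payoffs = payoffs, change_prob = change_prob),
            class = "bandit_environment")
}

#' @export
print.bandit_environment <- function(x, ...) {
  cat(sprintf("<bandit_environment> %d behaviors x %d deme(s), p_c = %g\n",
              ncol(x$payoffs), nrow(x$payoffs), x$change_prob))
  cat(sprintf("  payoff range %d-%d, mean %.2f\n",
              min(x$payoffs), max(x$payoffs), mean(x$payoffs)))
  invisible(x)
}

#' Stochastically change payoffs between rounds
#'
#' Each behavior, in each deme, is independently replaced with probability
#' `env$change_prob` by a fresh draw from the basic-payoff distribution.
#' Refinement levels held by agents are unaffected: when a refined behavior's
#' base payoff changes, the behavior keeps its refinement level.
#'
#' @param env A [bandit_environment()].
#' @return The updated environment, with attribute `"changed"`: a logical
#'   matrix marking which entries were redrawn.
#' @export
change_payoffs <- function(env) {
  stopifnot(inherits(env, "bandit_environment"))
  p <- env$payoffs
  mask <- matrix(stats::runif(length(p)) < env$change_prob,
                 nrow = nrow(p), ncol = ncol(p))
  n_changed <- sum(mask)
  if (n_changed > 0) p[mask] <- draw_basic_payoffs(n_changed)
  env$payoffs <- p
  attr(env, "changed") <- mask
  env
}

#' Refinement (cumulative-culture) payoff configuration
#'
#' The payoff to a behavior is its basic payoff plus an increment that
#' depends only on the refinement level `r`: a geometric diminishing-returns
#' series with per-step decay 0.95, normalized so the increment reaches
#' `p_max` exactly at `r_max`.
#'
#' The default `p_max = 125` is calibrated against the basic-payoff
#' distribution: over freshly drawn 100-behavior environments, the median
#' number of refinements after which the increment first exceeds the highest
#' basic payoff is about 10 (see the methods vignette).
#'
#' @param r_max Maximum refinement level (positive integer).
#' @param p_max Increment at `r_max` (asymptotic ceiling of the series).
#' @param decay Geometric decay of successive increments (fixed form, 0.95).
#' @param scale Normalizing factor of the series (0.05 = 1 - decay).
#' @return An object of class `refinement_config`.
#' @export
refinement_config <- function(r_max = 100, p_max = 125,
                              decay = 0.95, scale = 0.05) {
  stopifnot(r_max >= 1, r_max == as.integer(r_max), p_max > 0,
            decay > 0, decay < 1, scale > 0)
  structure(list(r_max = as.integer(r_max), p_max = p_max,
                 decay = decay, scale = scale),
            class = "refinement_config")
}

#' Payoff increment for a refinement level
#'
#' Closed form of the geometric series
#' `i(r) = scale / (1 - decay^r_max) * sum_{j=1..r} decay^(r-j) * p_max`,
#' i.e. `p_max * (1 - decay^r) / (1 - decay^r_max)` when `scale = 1 - decay`.
#' Deterministic; `i(0) = 0` and `i(r_max) = p_max`.
#'
#' @param r Refinement level(s), integer in `0..r_max` (vectorized).
#' @param cfg A [refinement_config()].
#' @return Numeric increment(s).
#' @examples
#' cfg <- refinement_config(r_max = 100, p_max = 100)
#' refinement_increment(c(0, 10, 100), cfg)
#' @export
refinement_increment <- function(r, cfg) {
  stopifnot(inherits(cfg, "refinement_config"))
  if (any(r < 0 | r > cfg$r_max)) {
    stop("refinement level out of range 0..r_max", call. = FALSE)
  }
  cfg$scale / (1 - cfg$decay^cfg$r_max) *
    (1 - cfg$decay^r) / (1 - cfg$decay) * cfg$p_max
}

#' Total payoff of a behavior at a refinement level
#'
#' Basic payoff of the behavior in the given deme plus the refinement
#' increment. The increment is a property of the (agent-private) refinement
#' level only; it is unaffected by basic-payoff changes.
#'
#' @param env A [bandit_environment()].
#' @param deme Deme index.
#' @param behavior Behavior index.
#' @param r Refinement level.
#' @param cfg A [refinement_config()].
#' @return Numeric total payoff.
#' @export
total_payoff <- function(env, deme, behavior, r, cfg) {
  stopifnot(inherits(env, "bandit_environment"))
  if (deme < 1 || deme > nrow(env$payoffs) ||
      behavior < 1 || behavior > ncol(env$payoffs)) {
    stop("invalid deme or behavior index", call. = FALSE)
  }
  env$payoffs[deme, behavior] + refinement_increment(r, cfg)
}

#' Refinements needed to beat the best basic payoff
#'
#' For each of `n_envs` freshly drawn environments, finds the minimal
#' refinement level whose increment exceeds that environment's maximum
#' basic payoff. This is the calibration behind the default `p_max`: at
#' `r_max = 100` and `p_max = 125` the median minimal level is about 10
#' refinements, and refined payoffs typically overtake every unrefined
#' payoff beyond level 8.
#'
#' @param n_envs Number of environments to draw.
#' @param n_behaviors Behaviors per environment.
#' @param cfg A [refinement_config()].
#' @return Integer vector of minimal levels, `NA` where even `p_max` does
#'   not exceed the environment's maximum basic payoff.
#' @examples
#' set.seed(1)
#' median(calibrate_refinement(200), na.rm = TRUE)
#' @export
calibrate_refinement <- function(n_envs = 1000, n_behaviors = 100,
                                 cfg = refinement_config()) {
  inc <- refinement_increment(0:cfg$r_max, cfg)
  vapply(seq_len(n_envs), function(k) {
    m <- max(draw_basic_payoffs(n_behaviors))
    r <- which(inc > m)
    if (length(r)) r[1] - 1L else NA_integer_
  }, 0L)
}

#' Snapshot an environment as a tidy data frame
#'
#' @param env A [bandit_environment()].
#' @param round Round number to stamp on the rows.
#' @return A data frame with columns `round`, `deme`, `behavior`,
#'   `basic_payoff`, suitable for writing to CSV.
#' @export
environment_snapshot <- function(env, round = 0L) {
  stopifnot(inherits(env, "bandit_environment"))
  nd <- nrow(env$payoffs); nb <- ncol(env$payoffs)
  data.frame(round = as.integer(round),
             deme = rep(seq_len(nd), each = nb),
             behavior = rep(seq_len(nb), times = nd),
             basic_payoff = as.integer(t(env$payoffs)))
}
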