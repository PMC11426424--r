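# The three-stage contest protocol: pairwise invasions, melees, staged
# promotion, and the smart-refiner vs blind-copier stopping experiment.

derive_seed <- function(root, i) {
  as.integer((as.numeric(root) %% 2147483647) * 48271 %% 2147483647 +
               i * 1009) %% 2147483647L
}

#' Stage-1 pairwise parameter sets
#'
#' The six parameter combinations of the pairwise-invasion stage:
#' `p_c` in {0.001, 0.01, 0.1} crossed with `n_observe` in {1, 5}, with
#' `r_max = 100` and `p_copyFail = 0.05`.
#'
#' @return A data frame with one row per parameter set.
#' @export
stage1_parameter_sets <- function() {
  g <- expand.grid(p_c = c(0.001, 0.01, 0.1), n_observe = c(1L, 5L),
                   KEEP.OUT.ATTRS = FALSE)
  g$p_copyFail <- 0.05
  g$r_max <- 100L
  g$param_set <- seq_len(nrow(g))
  g
}

#' Stage-2/3 systematic melee grid
#'
#' The full cross of the printed melee parameter values:
#' `p_c` (7 values) x `p_copyFail` (7) x `n_observe` (4) x `r_max` (6)
#' = 1176 grid points.
#'
#' @return A data frame with one row per grid point.
#' @export
stage2_grid <- function() {
  g <- expand.grid(p_c = c(0.001, 0.005, 0.01, 0.05, 0.1, 0.2, 0.4),
                   p_copyFail = c(0, 0.01, 0.05, 0.1, 0.15, 0.25, 0.5),
                   n_observe = c(1L, 2L, 5L, 10L),
                   r_max = c(10L, 25L, 50L, 100L, 500L, 1000L),
                   KEEP.OUT.ATTRS = FALSE)
  g$param_set <- seq_len(nrow(g))
  g
}

#' Draw melee parameters from exponential distributions
#'
#' Explores the broader parameter space: each parameter is drawn from an
#' exponential distribution whose mean is the midpoint of its systematic
#' range, truncated (clamped) to that range. `n_observe` and `r_max` are
#' rounded to integers.
#'
#' @param n Number of parameter sets to draw.
#' @return A data frame like [stage2_grid()].
#' @export
draw_melee_parameters <- function(n) {
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  g <- data.frame(
    p_c = clamp(stats::rexp(n, 1 / 0.2), 0.001, 0.4),
    p_copyFail = clamp(stats::rexp(n, 1 / 0.25), 0, 0.5),
    n_observe = as.integer(clamp(round(stats::rexp(n, 1 / 5.5)), 1, 10)),
    r_max = as.integer(clamp(round(stats::rexp(n, 1 / 505)), 10, 1000)))
  g$param_set <- seq_len(n)
  g
}

#' Schedule of Stage-1 pairwise invasion contests
#'
#' Every ordered pair of entries is an invasion contest (defender
#' monoculture invaded by the other entry); each contest runs once per
#' parameter set per replicate. For 51 entries this yields 2550 contests
#' (ordered pairs) and, with 6 parameter sets and 2 replicates per
#' direction, 24 simulations per unordered pair.
#'
#' @param entry_names Character vector of entry names.
#' @param param_sets Parameter-set data frame ([stage1_parameter_sets()]).
#' @param replicates Replicates per contest x parameter set.
#' @return A data frame with one row per scheduled simulation and
#'   attributes `n_contests` (ordered pairs) and `sims_per_pair`
#'   (simulations per unordered pair).
#' @export
stage1_schedule <- function(entry_names, param_sets = stage1_parameter_sets(),
                            replicates = 2) {
  stopifnot(length(entry_names) >= 2)
  pairs <- expand.grid(defender = entry_names, invader = entry_names,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$defender != pairs$invader, ]
  sched <- merge(merge(pairs, param_sets[, "param_set", drop = FALSE]),
                 data.frame(replicate = seq_len(replicates)))
  sched <- sched[order(sched$defender, sched$invader, sched$param_set,
                       sched$replicate), ]
  rownames(sched) <- NULL
  sched$sim <- seq_len(nrow(sched))
  attr(sched, "n_contests") <- nrow(pairs)
  attr(sched, "sims_per_pair") <- 2L * nrow(param_sets) * replicates
  sched
}

#' Run one pairwise invasion contest simulation
#'
#' A monoculture of the defender runs for `burn_in` rounds to establish
#' repertoires; the invader is then introduced through mutation (mutation
#' is enabled with the invader as the only target, so the invader can
#' re-enter after stochastic loss).
#'
#' @param defender,invader [strategy()] objects.
#' @param extensions Extension set (see [simulation_config()]).
#' @param params One-row data frame or list with `p_c`, `n_observe`,
#'   `p_copyFail`, `r_max` overrides.
#' @param rounds,n_agents Scale of the simulation.
#' @param burn_in Rounds before the invader's mutation switches on.
#' @param seed Seed for this simulation.
#' @param ... Further [simulation_config()] overrides.
#' @return A `sim_result`.
#' @export
run_invasion <- function(defender, invader, extensions = "cumulative",
                         params = NULL, rounds = 10000, n_agents = 100,
                         burn_in = 100, seed = 1, ...) {
  over <- list(...)
  base <- list(extensions = extensions, rounds = rounds,
               n_agents = n_agents, mutation_start = burn_in, seed = seed,
               record_diversity = FALSE)
  if (!is.null(params)) {
    base[intersect(names(params), c("p_c", "n_observe", "p_copyFail",
                                    "r_max"))] <-
      as.list(params)[intersect(names(params),
                                c("p_c", "n_observe", "p_copyFail",
                                  "r_max"))]
  }
  cfg <- do.call(simulation_config, utils::modifyList(base, over))
  run_simulation(cfg, list(defender, invader),
                 initial_entry = defender$entry_id,
                 mutation_targets = invader$entry_id)
}

#' Run the Stage-1 pairwise invasion stage
#'
#' Runs the full [stage1_schedule()] and scores every entry as its mean
#' last-quarter frequency, averaged over all simulations it took part in.
#'
#' @param entries Named list of [strategy()] objects.
#' @param extensions Extension set for this contest set.
#' @param param_sets Parameter sets (default [stage1_parameter_sets()]).
#' @param replicates Replicates per direction and parameter set.
#' @param rounds,n_agents,burn_in Scale of each simulation.
#' @param seed Root seed; per-simulation seeds are derived from it.
#' @return A list of class `score_table`: `simulations` (per-simulation
#'   rows with both entries' scores) and `scores` (per-entry means).
#' @export
pairwise_stage <- function(entries, extensions = "cumulative",
                           param_sets = stage1_parameter_sets(),
                           replicates = 2, rounds = 10000, n_agents = 100,
                           burn_in = 100, seed = 1) {
  entry_names <- vapply(entries, `[[`, "", "entry_id")
  names(entries) <- entry_names
  sched <- stage1_schedule(entry_names, param_sets, replicates)
  sims <- vector("list", nrow(sched))
  for (k in seq_len(nrow(sched))) {
    row <- sched[k, ]
    ps <- param_sets[param_sets$param_set == row$param_set, ]
    sim <- run_invasion(entries[[row$defender]], entries[[row$invader]],
                        extensions = extensions, params = ps,
                        rounds = rounds, n_agents = n_agents,
                        burn_in = burn_in, seed = derive_seed(seed, k))
    sims[[k]] <- data.frame(row, entry_id = names(sim$score),
                            score = unname(sim$score), row.names = NULL)
  }
  simulations <- do.call(rbind, sims)
  score_table(simulations, entry_names)
}

#' Run a melee stage
#'
#' All entries simultaneously invade, through mutation, a resident
#' population of the standard defending entry (`innovateOnce` by default),
#' across a grid of parameter sets with replicates.
#'
#' @param entries Named list of invading [strategy()] objects.
#' @param extensions Extension set (Stage 3 uses `"all"`).
#' @param param_sets Parameter-set data frame ([stage2_grid()], a subset of
#'   it, or [draw_melee_parameters()] output).
#' @param replicates Replicates per parameter set.
#' @param rounds,n_agents Scale of each simulation.
#' @param seed Root seed.
#' @param resident Defending [strategy()].
#' @return A `score_table` (resident included in the per-entry means).
#' @export
melee_stage <- function(entries, extensions = "cumulative",
                        param_sets = stage2_grid(), replicates = 10,
                        rounds = 10000, n_agents = 100, seed = 1,
                        resident = innovate_once()) {
  entry_names <- vapply(entries, `[[`, "", "entry_id")
  names(entries) <- entry_names
  if (resident$entry_id %in% entry_names) {
    stop("resident entry must not also be an invader", call. = FALSE)
  }
  sched <- merge(param_sets, data.frame(replicate = seq_len(replicates)))
  sims <- vector("list", nrow(sched))
  for (k in seq_len(nrow(sched))) {
    ps <- sched[k, ]
    cfg <- simulation_config(
      extensions = extensions, rounds = rounds, n_agents = n_agents,
      p_c = ps$p_c, n_observe = ps$n_observe, p_copyFail = ps$p_copyFail,
      r_max = ps$r_max, seed = derive_seed(seed, k),
      record_diversity = FALSE)
    sim <- run_simulation(cfg, c(list(resident), unname(entries)),
                          initial_entry = resident$entry_id,
                          mutation_targets = entry_names)
    sims[[k]] <- data.frame(param_set = ps$param_set,
                            replicate = ps$replicate,
                            entry_id = names(sim$score),
                            score = unname(sim$score), row.names = NULL)
  }
  simulations <- do.call(rbind, sims)
  score_table(simulations, c(resident$entry_id, entry_names))
}

score_table <- function(simulations, entry_names) {
  agg <- stats::aggregate(score ~ entry_id, data = simulations, FUN = mean)
  agg <- agg[match(entry_names, agg$entry_id), ]
  rownames(agg) <- NULL
  structure(list(simulations = simulations, scores = agg),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  n_sims <- nrow(x$simulations) / length(unique(x$simulations$entry_id))
  cat(sprintf("<score_table> %d simulations, %d entries\n",
              as.integer(n_sims), nrow(x$scores)))
  print(x$scores[order(-x$scores$score), ], row.names = FALSE)
  invisible(x)
}

#' Promote top entries between stages
#'
#' Selects the `top_n` entries by mean score; ties are broken by total
#' score across simulations, then lexicographically by entry id.
#'
#' @param scores A `score_table`.
#' @param top_n Number of entries to promote.
#' @param exclude Entry ids never promoted (e.g. the standard resident).
#' @return Character vector of promoted entry ids, best first.
#' @export
promote <- function(scores, top_n, exclude = "innovateOnce") {
  stopifnot(inherits(scores, "score_table"))
  tot <- stats::aggregate(score ~ entry_id, data = scores$simulations,
                          FUN = sum)
  df <- merge(scores$scores, tot, by = "entry_id",
              suffixes = c("_mean", "_total"))
  df <- df[!(df$entry_id %in% exclude), ]
  df <- df[order(-df$score_mean, -df$score_total, df$entry_id), ]
  utils::head(df$entry_id, top_n)
}

#' Classify a simulation's environment as refined or not
#'
#' A simulation is `refined` when some agent attained the maximum
#' refinement level `r_max` at any point.
#'
#' @param sim A `sim_result`.
#' @return `TRUE` (refined) or `FALSE`.
#' @export
classify_environment <- function(sim) {
  sim$max_refinement >= sim$cfg$r_max
}

#' Smart-refiner vs blind-copier stopping-criterion experiment
#'
#' Melee-style runs (resident `innovateOnce`, invaded simultaneously by the
#' smart-refiner entries and the blind copier) under the cumulative
#' extension, halted the first time the mean refinement level of the
#' behaviors performed that round (non-forfeited EXPLOIT moves) exceeds the
#' stopping criterion. At that point each class's fitness is the mean, over
#' its living agents, of mean lifetime payoff; surviving resident agents
#' form a class of their own. Runs that never reach the criterion within
#' the round budget are recorded as censored.
#'
#' @param smart_entries List of "smart" [strategy()] objects (default: the
#'   shipped [smart_refiner()] family member).
#' @param blind_entry The blind-copying [strategy()]
#'   (default [observe_exploit()]).
#' @param stopping_levels Numeric vector of mean-refinement stopping
#'   criteria.
#' @param replicates Replicates per stopping level.
#' @param rounds Round budget (censoring horizon).
#' @param n_agents,p_c,n_observe,p_copyFail,r_max,p_max Simulation
#'   parameters.
#' @param seed Root seed.
#' @param resident Defending [strategy()].
#' @return A data frame with one row per run: `stopping_level`,
#'   `replicate`, `rounds_run`, `censored`, `fitness_smart`,
#'   `fitness_blind`, `fitness_resident` and `fitness_diff`
#'   (smart minus blind).
#' @export
refinement_stopping_experiment <- function(smart_entries =
                                             list(smart_refiner()),
                                           blind_entry = observe_exploit(),
                                           stopping_levels = c(2, 10, 40),
                                           replicates = 50,
                                           rounds = 1000, n_agents = 100,
                                           p_c = 0.01, n_observe = 1,
                                           p_copyFail = 0.05, r_max = 100,
                                           p_max = 125, seed = 1,
                                           resident = innovate_once()) {
  smart_names <- vapply(smart_entries, `[[`, "", "entry_id")
  invaders <- c(smart_entries, list(blind_entry))
  out <- vector("list", length(stopping_levels) * replicates)
  k <- 0L
  for (lev in stopping_levels) {
    for (rep_i in seq_len(replicates)) {
      k <- k + 1L
      cfg <- simulation_config(
        extensions = "cumulative", rounds = rounds, n_agents = n_agents,
        p_c = p_c, n_observe = n_observe, p_copyFail = p_copyFail,
        r_max = r_max, p_max = p_max, seed = derive_seed(seed, k),
        record_diversity = FALSE)
      stop_fn <- function(st) {
        mr <- st$mean_exploit_ref[st$round]
        !is.na(mr) && mr > lev
      }
      sim <- run_simulation(cfg, c(list(resident), invaders),
                            initial_entry = resident$entry_id,
                            mutation_targets = vapply(invaders, `[[`, "",
                                                      "entry_id"),
                            stop_fn = stop_fn)
      cls <- ifelse(sim$agents$entry_id %in% smart_names, "smart",
                    ifelse(sim$agents$entry_id == blind_entry$entry_id,
                           "blind", "resident"))
      fit <- function(cl) {
        v <- sim$agents$mean_lifetime_payoff[cls == cl]
        if (length(v)) mean(v) else NA_real_
      }
      fs <- fit("smart"); fb <- fit("blind")
      out[[k]] <- data.frame(
        stopping_level = lev, replicate = rep_i,
        rounds_run = sim$rounds_completed,
        censored = !sim$stopped_early,
        fitness_smart = fs, fitness_blind = fb,
        fitness_resident = fit("resident"),
        fitness_diff = fs - fb)
    }
  }
  do.call(rbind, out)
}
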