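# Death-birth demography, migration, and the full simulation loop.

# Mutation is active after the invasion burn-in and outside the final
# scoring window (mutation does not occur in the last quarter).
mutation_active <- function(st) {
  st$round > st$cfg$mutation_start &&
    st$round <= st$cfg$rounds - st$score_window
}

# Each agent independently dies with probability death_prob; vacancies are
# filled by naive newborns whose parent is drawn among same-deme survivors
# with probability proportional to mean lifetime payoff P_z =
# total_payoff / rounds_alive. A birth mutates with probability
# mutation_prob to a uniformly chosen *other* entry among the registered
# mutation targets.
death_birth <- function(st) {
  cfg <- st$cfg
  with_stream(st$streams, "demography", {
    dies <- stats::runif(st$n) < cfg$death_prob
    mut_on <- mutation_active(st)
    for (d in unique(st$deme[dies])) {
      vac <- which(dies & st$deme == d)
      surv <- which(!dies & st$deme == d)
      if (length(surv) == 0) surv <- which(st$deme == d) # degenerate deme
      plp <- st$total_payoff[surv] / pmax(st$age[surv], 1L)
      w <- if (sum(plp) > 0) plp / sum(plp) else NULL # uniform fallback
      parents <- surv[sample.int(length(surv), length(vac), replace = TRUE,
                                 prob = w)]
      for (k in seq_along(vac)) {
        i <- vac[k]; p <- parents[k]
        st$n_offspring[p] <- st$n_offspring[p] + 1L
        child_entry <- st$entry[p]
        if (mut_on && stats::runif(1) < cfg$mutation_prob) {
          cand <- setdiff(st$mutation_targets, child_entry)
          if (length(cand)) {
            child_entry <- cand[sample.int(length(cand), 1L)]
            st$n_mutations <- st$n_mutations + 1L
          }
        }
        st$entry[i] <- child_entry
        st$age[i] <- 0L
        st$total_payoff[i] <- 0
        st$times_observed[i] <- 0L
        st$n_offspring[i] <- 0L
        st$rep_pay[i, ] <- NA_real_
        st$rep_ref[i, ] <- 0L
        st$hist[[i]] <- empty_history()
        st$migration_rounds[[i]] <- integer(0)
        st$n_births <- st$n_births + 1L
      }
    }
  })
  invisible(st)
}

# n_migrate agents per deme, chosen uniformly, each reassigned to a
# uniformly chosen different deme. Repertoires (including refinement
# levels) travel unchanged; recorded payoffs are now stale against the new
# deme's payoff table.
migrate <- function(st) {
  cfg <- st$cfg
  if (cfg$n_demes < 2 || cfg$n_migrate < 1) return(invisible(st))
  with_stream(st$streams, "migration", {
    demes <- seq_len(cfg$n_demes)
    movers <- integer(0); dests <- integer(0)
    for (d in demes) {
      idx <- which(st$deme == d)
      k <- min(cfg$n_migrate, length(idx))
      if (k == 0) next
      sel <- idx[sample.int(length(idx), k)]
      other <- demes[demes != d]
      dst <- other[sample.int(length(other), k, replace = TRUE)]
      movers <- c(movers, sel); dests <- c(dests, dst)
    }
    if (length(movers)) {
      st$deme[movers] <- dests
      for (i in movers) {
        st$migration_rounds[[i]] <- c(st$migration_rounds[[i]], st$round)
      }
    }
  })
  invisible(st)
}

# One full simulation round: moves, then reproduction, then environmental
# change, then (spatial case) migration.
step <- function(st) {
  st$round <- st$round + 1L
  resolve_round(st)
  death_birth(st)
  st$env <- with_stream(st$streams, "environment", change_payoffs(st$env))
  if (st$spatial) migrate(st)
  st$freq[st$round, ] <- tabulate(st$entry,
                                  nbins = length(st$entries)) / st$n
  for (d in seq_len(st$cfg$n_demes)) {
    in_d <- st$deme == d
    st$freq_deme[[d]][st$round, ] <-
      tabulate(st$entry[in_d], nbins = length(st$entries)) /
      max(1L, sum(in_d))
  }
  invisible(st)
}

#' Run an evolutionary tournament simulation
#'
#' Runs the configured number of rounds of the move/reproduction/
#' environmental-change/migration loop and scores every registered entry as
#' its mean population frequency over the final quarter of rounds.
#'
#' @param cfg A [simulation_config()].
#' @param entries List of [strategy()] objects (the registered entries).
#' @param initial_entry Entry name (or vector of names, one per agent)
#'   forming the initial population; defaults to the first entry.
#' @param mutation_targets Entry names reachable by mutation (default: all
#'   registered entries). An invasion contest lists only the invader here.
#' @param stop_fn Optional early-stopping predicate, called after each round
#'   with the internal state; return `TRUE` to halt (used by the
#'   refinement stopping-criterion experiment).
#' @return An object of class `sim_result`: entry scores, per-round entry
#'   frequencies, diversity count matrices (behavior usage and knowledge per
#'   deme), per-round mean refinement level of exploited behaviors, maximum
#'   refinement level attained, per-entry move totals, a per-agent summary
#'   of the final population, and a replayable manifest.
#' @examples
#' cfg <- simulation_config(n_agents = 20, rounds = 50, seed = 7)
#' sim <- run_simulation(cfg, list(innovate_once()))
#' sim$score
#' @export
run_simulation <- function(cfg, entries, initial_entry = NULL,
                           mutation_targets = NULL, stop_fn = NULL) {
  st <- new_sim_state(cfg, entries, initial_entry, mutation_targets)
  stopped <- FALSE
  while (st$round < cfg$rounds) {
    step(st)
    if (!is.null(stop_fn) && isTRUE(stop_fn(st))) {
      stopped <- TRUE
      break
    }
  }
  finalize_sim(st, stopped)
}

finalize_sim <- function(st, stopped) {
  cfg <- st$cfg
  rc <- st$round
  freq <- st$freq[seq_len(rc), , drop = FALSE]
  win <- max(1L, as.integer(ceiling(rc * cfg$score_window_fraction)))
  score <- if (rc > 0) {
    colMeans(freq[(rc - win + 1L):rc, , drop = FALSE])
  } else {
    stats::setNames(rep(NA_real_, length(st$entries)), st$entry_names)
  }
  agents <- data.frame(
    agent_id = seq_len(st$n),
    entry_id = st$entry_names[st$entry],
    deme = st$deme,
    rounds_alive = st$age,
    total_exploit_payoff = st$total_payoff,
    mean_lifetime_payoff = st$total_payoff / pmax(st$age, 1L),
    times_observed = st$times_observed,
    n_offspring = st$n_offspring)
  res <- list(
    cfg = cfg,
    entry_names = st$entry_names,
    score = score,
    freq = freq,
    usage = if (cfg$record_diversity) {
      lapply(st$usage, function(m) m[, seq_len(rc), drop = FALSE])
    },
    knowledge = if (cfg$record_diversity) {
      lapply(st$know, function(m) m[, seq_len(rc), drop = FALSE])
    },
    mean_exploit_refinement = st$mean_exploit_ref[seq_len(rc)],
    max_refinement = st$max_refinement,
    move_totals = st$move_totals,
    move_log = if (cfg$record_moves) {
      do.call(rbind, st$move_log[seq_len(rc)])
    },
    agents = agents,
    rounds_completed = rc,
    stopped_early = stopped,
    n_forfeits = st$n_forfeits,
    n_mutations = st$n_mutations,
    n_births = st$n_births)
  res$freq_deme <- lapply(st$freq_deme,
                          function(m) m[seq_len(rc), , drop = FALSE])
  res$initial_entry <- st$initial_entry
  res$mutation_target_names <- st$mutation_target_names
  res$manifest <- run_manifest(res, st$entries)
  class(res) <- "sim_result"
  res
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d rounds%s, %d agents, %d entries\n",
              x$rounds_completed, if (x$stopped_early) " (stopped early)"
              else "", nrow(x$agents), length(x$entry_names)))
  cat("  scores (last-quarter mean frequency):\n")
  for (nm in names(x$score)) cat(sprintf("    %-20s %.4f\n", nm,
                                         x$score[[nm]]))
  if (x$max_refinement > 0) {
    cat(sprintf("  max refinement level attained: %d\n", x$max_refinement))
  }
  invisible(x)
}

#' Simulate agent lifetimes under the per-round death process
#'
#' Applies the same independent per-round death coin used by the
#' death-birth dynamics to `n` agents and reports each lifetime (number of
#' rounds played before death). At the default `death_prob = 0.02`,
#' lifetimes are geometric with mean 50 rounds.
#'
#' @param n Number of agents to simulate.
#' @param death_prob Per-round death probability.
#' @return Integer vector of `n` lifetimes in rounds (each >= 1).
#' @examples
#' mean(sample_lifetimes(1000, 0.02))
#' @export
sample_lifetimes <- function(n, death_prob = 0.02) {
  stopifnot(n >= 1, death_prob > 0, death_prob <= 1)
  life <- integer(n)
  alive <- rep(TRUE, n)
  rounds <- 0L
  while (any(alive)) {
    rounds <- rounds + 1L
    k <- sum(alive)
    dead_now <- stats::runif(k) < death_prob
    life[which(alive)[dead_now]] <- rounds
    alive[alive] <- !dead_now
  }
  life
}
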