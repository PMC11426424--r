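# Agent state and one-round move resolution.
#
# Population state lives in an R environment for in-place updates:
#   entry          integer entry index per agent
#   deme           deme index per agent
#   age            rounds alive
#   total_payoff   summed EXPLOIT payoffs (lifetime)
#   times_observed number of successful copy events with this agent as model
#   n_offspring    offspring parented
#   rep_pay        n_agents x n_behaviors recorded payoffs (NA = unknown)
#   rep_ref        n_agents x n_behaviors refinement levels (agent-private)
#   hist           per-agent aligned histories (move/behavior/payoff/deme/
#                  forfeited), plus migration_rounds
# Refinement levels are engine state, never exposed to strategies.

MOVE_NAMES <- c("EXPLOIT", "INNOVATE", "OBSERVE", "REFINE")
MOVE_COLS <- c(MOVE_NAMES, "FORFEIT")

new_sim_state <- function(cfg, entries, initial_entry = NULL,
                          mutation_targets = NULL) {
  stopifnot(inherits(cfg, "simulation_config"), length(entries) >= 1)
  entries <- lapply(entries, function(e) {
    stopifnot(inherits(e, "strategy")); e
  })
  entry_names <- vapply(entries, `[[`, "", "entry_id")
  if (anyDuplicated(entry_names)) stop("duplicate entry ids", call. = FALSE)
  names(entries) <- entry_names

  n <- cfg$n_agents * cfg$n_demes
  if (is.null(initial_entry)) initial_entry <- entry_names[1]
  init <- match(rep_len(initial_entry, n), entry_names)
  if (anyNA(init)) stop("initial_entry not among entries", call. = FALSE)

  if (is.null(mutation_targets)) {
    mut_idx <- seq_along(entries)
  } else {
    mut_idx <- match(mutation_targets, entry_names)
    if (anyNA(mut_idx)) stop("mutation target not registered", call. = FALSE)
  }

  st <- new.env(parent = emptyenv())
  st$cfg <- cfg
  st$entries <- entries
  st$entry_names <- entry_names
  st$streams <- rng_streams(cfg$seed)
  st$env <- with_stream(st$streams, "environment",
                        bandit_environment(cfg$n_behaviors, cfg$n_demes,
                                           cfg$p_c))
  st$refcfg <- refinement_config(cfg$r_max, cfg$p_max)
  # increment lookup by level (index r + 1), hot path of EXPLOIT/REFINE
  st$inc_table <- refinement_increment(0:cfg$r_max, st$refcfg)
  st$cumulative <- "cumulative" %in% cfg$extensions
  st$model_bias <- "model_bias" %in% cfg$extensions
  st$spatial <- "spatial" %in% cfg$extensions
  st$round <- 0L
  st$n <- n
  st$entry <- init
  st$deme <- rep(seq_len(cfg$n_demes), each = cfg$n_agents)
  st$age <- integer(n)
  st$total_payoff <- numeric(n)
  st$times_observed <- integer(n)
  st$n_offspring <- integer(n)
  st$rep_pay <- matrix(NA_real_, n, cfg$n_behaviors)
  st$rep_ref <- matrix(0L, n, cfg$n_behaviors)
  st$hist <- replicate(n, empty_history(), simplify = FALSE)
  st$migration_rounds <- replicate(n, integer(0), simplify = FALSE)
  st$visible_params <- cfg[c("extensions", "n_agents", "n_behaviors",
                             "n_demes", "rounds", "p_c", "n_observe",
                             "p_copyFail", "r_max", "p_max", "n_migrate",
                             "death_prob", "mutation_prob",
                             "score_window_fraction")]
  st$mutation_targets <- mut_idx
  st$score_window <- max(1L, as.integer(ceiling(cfg$rounds *
                                                cfg$score_window_fraction)))
  ne <- length(entries)
  st$freq <- matrix(NA_real_, cfg$rounds, ne,
                    dimnames = list(NULL, entry_names))
  st$freq_deme <- replicate(cfg$n_demes,
                            matrix(NA_real_, cfg$rounds, ne,
                                   dimnames = list(NULL, entry_names)),
                            simplify = FALSE)
  st$initial_entry <- entry_names[init]
  st$mutation_target_names <- entry_names[mut_idx]
  st$mean_exploit_ref <- rep(NA_real_, cfg$rounds)
  st$max_refinement <- 0L
  st$move_totals <- matrix(0L, ne, length(MOVE_COLS),
                           dimnames = list(entry_names, MOVE_COLS))
  if (cfg$record_diversity) {
    st$usage <- replicate(cfg$n_demes,
                          matrix(0L, cfg$n_behaviors, cfg$rounds),
                          simplify = FALSE)
    st$know <- replicate(cfg$n_demes,
                         matrix(0L, cfg$n_behaviors, cfg$rounds),
                         simplify = FALSE)
  }
  st$move_log <- if (cfg$record_moves) vector("list", cfg$rounds) else NULL
  st$n_forfeits <- 0L
  st$n_mutations <- 0L
  st$n_births <- 0L
  st
}

empty_history <- function() {
  list(move = character(0), behavior = integer(0), payoff = numeric(0),
       deme = integer(0), forfeited = logical(0))
}

# Strategy-facing view: private information only.
make_view <- function(st, i) {
  known <- which(!is.na(st$rep_pay[i, ]))
  list(age = st$age[i],
       deme = st$deme[i],
       repertoire = list(behavior = known,
                         payoff = st$rep_pay[i, known]),
       history = st$hist[[i]],
       migration_rounds = st$migration_rounds[[i]],
       params = st$visible_params)
}

# Validate a raw strategy decision; returns list(move, behavior, forfeit).
check_decision <- function(st, i, dec) {
  forfeit <- function(reason) {
    if (st$cfg$strict) {
      stop(sprintf("agent %d (%s): illegal decision (%s)", i,
                   st$entry_names[st$entry[i]], reason), call. = FALSE)
    }
    list(move = "FORFEIT", behavior = NA_integer_, forfeit = TRUE)
  }
  if (inherits(dec, "error")) return(forfeit(conditionMessage(dec)))
  if (!is.list(dec) || is.null(dec$move) ||
      !(dec$move %in% MOVE_NAMES)) {
    return(forfeit("not a valid move"))
  }
  mv <- dec$move
  beh <- suppressWarnings(as.integer(dec$behavior[1]))
  if (mv == "REFINE" && !st$cumulative) {
    return(forfeit("REFINE outside the cumulative extension"))
  }
  if (mv %in% c("EXPLOIT", "REFINE")) {
    if (is.na(beh) || beh < 1 || beh > st$cfg$n_behaviors ||
        is.na(st$rep_pay[i, beh])) {
      return(forfeit(paste0(mv, " of a behavior not in the repertoire")))
    }
    return(list(move = mv, behavior = beh, forfeit = FALSE))
  }
  list(move = mv, behavior = NA_integer_, forfeit = FALSE)
}

# Noisy model information for observe_who (model-bias extension). All four
# performance indexes are social information, hence Poisson-noised; row
# order is randomized before the ranking function sees it.
build_model_info <- function(st, pool, times_observed = st$times_observed) {
  if (length(pool) == 0) {
    return(data.frame(model_ref = integer(0), age = integer(0),
                      total_payoff = integer(0), times_observed = integer(0),
                      n_offspring = integer(0)))
  }
  info <- data.frame(
    model_ref = pool,
    age = stats::rpois(length(pool), st$age[pool]),
    total_payoff = stats::rpois(length(pool), st$total_payoff[pool]),
    times_observed = stats::rpois(length(pool), times_observed[pool]),
    n_offspring = stats::rpois(length(pool), st$n_offspring[pool]))
  info[sample.int(nrow(info)), , drop = FALSE]
}

# Resolve one round of moves for the whole population, two-phase:
# (1) every strategy is queried against its pre-round view; EXPLOIT,
# INNOVATE and REFINE are applied; (2) OBSERVE moves are processed against
# this round's same-deme exploiters.
resolve_round <- function(st) {
  cfg <- st$cfg
  n <- st$n
  r <- st$round
  entries <- st$entries

  decisions <- with_stream(st$streams, "strategies", {
    lapply(seq_len(n), function(i) {
      tryCatch(entries[[st$entry[i]]]$move(make_view(st, i)),
               error = function(e) e)
    })
  })
  checked <- lapply(seq_len(n), function(i) check_decision(st, i,
                                                           decisions[[i]]))
  mv <- vapply(checked, `[[`, "", "move")
  beh <- vapply(checked, `[[`, 0L, "behavior")

  hist_pay <- rep(NA_real_, n)
  hist_beh <- beh

  # phase 1: EXPLOIT / INNOVATE / REFINE
  ex_idx <- integer(0); ex_beh <- integer(0)
  ex_pay <- numeric(0); ex_ref <- integer(0)
  with_stream(st$streams, "moves", {
    for (i in seq_len(n)) {
      m <- mv[i]
      if (m == "EXPLOIT") {
        lev <- if (st$cumulative) st$rep_ref[i, beh[i]] else 0L
        pay <- st$env$payoffs[st$deme[i], beh[i]] + st$inc_table[lev + 1L]
        st$total_payoff[i] <- st$total_payoff[i] + pay
        st$rep_pay[i, beh[i]] <- pay
        hist_pay[i] <- pay
        ex_idx <- c(ex_idx, i); ex_beh <- c(ex_beh, beh[i])
        ex_pay <- c(ex_pay, pay); ex_ref <- c(ex_ref, lev)
      } else if (m == "INNOVATE") {
        unknown <- which(is.na(st$rep_pay[i, ]))
        if (length(unknown)) {
          b <- unknown[sample.int(length(unknown), 1L)]
          st$rep_pay[i, b] <- st$env$payoffs[st$deme[i], b]
          st$rep_ref[i, b] <- 0L
          hist_beh[i] <- b
          hist_pay[i] <- st$rep_pay[i, b]
        } # full repertoire: no new behavior gained
      } else if (m == "REFINE") {
        lev <- min(st$rep_ref[i, beh[i]] + 1L, cfg$r_max)
        st$rep_ref[i, beh[i]] <- lev
        newpay <- st$env$payoffs[st$deme[i], beh[i]] + st$inc_table[lev + 1L]
        st$rep_pay[i, beh[i]] <- newpay
        hist_pay[i] <- newpay
        if (lev > st$max_refinement) st$max_refinement <- lev
      }
    }
  })

  # phase 2: OBSERVE against this round's exploiters, same deme only
  observers <- which(mv == "OBSERVE")
  if (length(observers)) {
    obs_snapshot <- st$times_observed # pre-phase snapshot for model info
    chosen_list <- vector("list", length(observers))
    biased <- vapply(observers, function(i) {
      st$model_bias && !is.null(entries[[st$entry[i]]]$observe_who)
    }, TRUE)
    if (any(!biased)) {
      # random model choice, without replacement
      with_stream(st$streams, "moves", {
        for (k in which(!biased)) {
          i <- observers[k]
          pool_sel <- ex_idx[st$deme[ex_idx] == st$deme[i]]
          if (length(pool_sel)) {
            ks <- min(cfg$n_observe, length(pool_sel))
            chosen_list[[k]] <- pool_sel[sample.int(length(pool_sel), ks)]
          }
        }
      })
    }
    for (k in which(biased)) {
      i <- observers[k]
      pool_sel <- ex_idx[st$deme[ex_idx] == st$deme[i]]
      if (length(pool_sel) == 0) next # no models, nothing learned
      strat <- entries[[st$entry[i]]]
      info <- with_stream(st$streams, "observation",
                          build_model_info(st, pool_sel, obs_snapshot))
      ranked <- with_stream(st$streams, "strategies",
                            tryCatch(strat$observe_who(info),
                                     error = function(e) info))
      refs <- if (is.data.frame(ranked)) ranked$model_ref
              else info$model_ref[ranked]
      refs <- refs[refs %in% pool_sel]
      if (length(refs) == 0) refs <- info$model_ref
      chosen_list[[k]] <- utils::head(unique(refs), cfg$n_observe)
    }
    with_stream(st$streams, "observation", {
      for (k in seq_along(observers)) {
        i <- observers[k]
        for (m in chosen_list[[k]]) {
          if (stats::runif(1) < cfg$p_copyFail) next # failed copy event
          j <- match(m, ex_idx)
          b <- ex_beh[j]
          est <- stats::rpois(1, ex_pay[j])
          st$rep_pay[i, b] <- est
          if (st$cumulative) st$rep_ref[i, b] <- ex_ref[j]
          st$times_observed[m] <- st$times_observed[m] + 1L
          hist_beh[i] <- b
          hist_pay[i] <- est
        }
      }
    })
  }

  # bookkeeping
  forf <- mv == "FORFEIT"
  st$n_forfeits <- st$n_forfeits + sum(forf)
  for (i in seq_len(n)) {
    h <- st$hist[[i]]
    k <- length(h$move) + 1L
    h$move[k] <- mv[i]
    h$behavior[k] <- hist_beh[i]
    h$payoff[k] <- hist_pay[i]
    h$deme[k] <- st$deme[i]
    h$forfeited[k] <- forf[i]
    st$hist[[i]] <- h
  }
  st$age <- st$age + 1L

  tab <- table(factor(st$entry_names[st$entry], levels = st$entry_names),
               factor(mv, levels = MOVE_COLS))
  st$move_totals <- st$move_totals + unclass(tab)

  st$mean_exploit_ref[r] <- if (length(ex_ref)) mean(ex_ref) else NA_real_
  if (cfg$record_diversity) {
    for (d in seq_len(cfg$n_demes)) {
      st$usage[[d]][, r] <- tabulate(ex_beh[st$deme[ex_idx] == d],
                                     nbins = cfg$n_behaviors)
      rows <- which(st$deme == d)
      st$know[[d]][, r] <- colSums(!is.na(st$rep_pay[rows, , drop = FALSE]))
    }
  }
  if (cfg$record_moves) {
    st$move_log[[r]] <- data.frame(
      round = r, agent_id = seq_len(n),
      entry_id = st$entry_names[st$entry], deme = st$deme,
      move = mv, behavior = hist_beh, payoff_or_estimate = hist_pay,
      forfeited = forf)
  }
  invisible(st)
}
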