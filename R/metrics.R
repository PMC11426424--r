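# Cultural-diversity metrics: amount, Pielou evenness, persistence, and
# learning-composition statistics.

#' Amount of cultural diversity
#'
#' The proportion of possible behaviors used (or known) by at least one
#' agent: `|{behaviors with count > 0}| / n_behaviors`.
#'
#' @param counts Non-negative vector of per-behavior counts (users or
#'   knowers) for one round.
#' @param n_behaviors Number of possible behaviors (defaults to
#'   `length(counts)`).
#' @return A proportion in `[0, 1]`.
#' @export
amount <- function(counts, n_behaviors = length(counts)) {
  stopifnot(all(counts >= 0), n_behaviors >= 1)
  sum(counts > 0) / n_behaviors
}

#' Pielou's evenness index
#'
#' `J = -sum(p_i log p_i) / log S` with `p_i` the proportion of agents
#' using behavior `i` and `S` the number of *possible* behaviors, so that
#' J = 1 when all possible behaviors are performed with equal frequency and
#' J = 0 when all agents perform the same single behavior. Zero counts
#' contribute nothing (`0 log 0 := 0`). All-zero counts give `NA`.
#'
#' @param counts Non-negative per-behavior counts for one round.
#' @param S Number of possible behaviors (defaults to `length(counts)`).
#' @return `J` in `[0, 1]`, or `NA` when no behavior is in use.
#' @examples
#' pielou_evenness(rep(1, 100))          # 1
#' pielou_evenness(c(100, rep(0, 99)))   # 0
#' @export
pielou_evenness <- function(counts, S = length(counts)) {
  stopifnot(all(counts >= 0), S >= 2)
  tot <- sum(counts)
  if (tot == 0) return(NA_real_)
  p <- counts[counts > 0] / tot
  -sum(p * log(p)) / log(S)
}

#' Persistence of behaviors (run lengths of presence)
#'
#' The number of consecutive rounds a behavior was exploited by (or known
#' to) at least one agent, without a break. Maximal runs are pooled over
#' behaviors; refinement level is not differentiated (a behavior is the
#' same behavior after refinement).
#'
#' @param presence Logical (or count) matrix, behaviors x rounds.
#' @return A list with the pooled run lengths (`runs`) and their `mean`,
#'   `median` and `max` (all `NA` when nothing was ever present).
#' @export
persistence <- function(presence) {
  presence <- presence > 0
  runs <- unlist(lapply(seq_len(nrow(presence)), function(b) {
    r <- rle(presence[b, ])
    r$lengths[r$values]
  }), use.names = FALSE)
  if (length(runs) == 0) {
    return(list(runs = integer(0), mean = NA_real_, median = NA_real_,
                max = NA_real_))
  }
  list(runs = runs, mean = mean(runs), median = stats::median(runs),
       max = max(runs))
}

#' Per-timepoint diversity records from a simulation
#'
#' Computes amount and Pielou evenness of both the behavior repertoire
#' (what the population exploits) and the knowledge repertoire (what at
#' least one agent knows) for each recorded round, per deme and then
#' averaged over demes. Time-series output can be thinned to a cadence
#' (e.g. every 1000 rounds, averaging within each block).
#'
#' @param sim A `sim_result` run with `record_diversity = TRUE`.
#' @param every Block size in rounds for time-series averaging (1 = keep
#'   every round).
#' @return A data frame with columns `round`, `amount_behavior`,
#'   `amount_knowledge`, `evenness_behavior`, `evenness_knowledge`.
#' @export
diversity_records <- function(sim, every = 1L) {
  if (is.null(sim$usage)) {
    stop("run was made without record_diversity = TRUE", call. = FALSE)
  }
  nb <- sim$cfg$n_behaviors
  rc <- sim$rounds_completed
  per_deme <- lapply(seq_along(sim$usage), function(d) {
    u <- sim$usage[[d]]; k <- sim$knowledge[[d]]
    data.frame(
      amount_behavior = colSums(u > 0) / nb,
      amount_knowledge = colSums(k > 0) / nb,
      evenness_behavior = apply(u, 2, pielou_evenness, S = nb),
      evenness_knowledge = apply(k, 2, pielou_evenness, S = nb))
  })
  avg <- Reduce(`+`, lapply(per_deme, as.matrix)) / length(per_deme)
  out <- data.frame(round = seq_len(rc), avg)
  if (every > 1) {
    block <- (out$round - 1L) %/% as.integer(every)
    out <- do.call(rbind, lapply(split(out, block), function(b) {
      data.frame(round = max(b$round), lapply(b[-1], mean, na.rm = TRUE))
    }))
    rownames(out) <- NULL
  }
  out
}

#' Persistence summaries for a simulation
#'
#' Run-length persistence of behavior (exploited by at least one agent) and
#' knowledge (known to at least one agent), per deme then averaged over
#' demes.
#'
#' @param sim A `sim_result` run with `record_diversity = TRUE`.
#' @param window `"all"` (whole run, default) or `"last_quarter"`.
#' @return A data frame with one row per repertoire type (`behavior`,
#'   `knowledge`) and columns `mean`, `median`, `max` (deme averages).
#' @export
persistence_summary <- function(sim, window = c("all", "last_quarter")) {
  window <- match.arg(window)
  if (is.null(sim$usage)) {
    stop("run was made without record_diversity = TRUE", call. = FALSE)
  }
  rc <- sim$rounds_completed
  cols <- if (window == "last_quarter") {
    win <- max(1L, as.integer(ceiling(rc * sim$cfg$score_window_fraction)))
    (rc - win + 1L):rc
  } else {
    seq_len(rc)
  }
  one <- function(mats) {
    per <- lapply(mats, function(m) {
      persistence(m[, cols, drop = FALSE])
    })
    c(mean = mean(vapply(per, `[[`, 0, "mean")),
      median = mean(vapply(per, `[[`, 0, "median")),
      max = mean(vapply(per, `[[`, 0, "max")))
  }
  out <- rbind(behavior = one(sim$usage), knowledge = one(sim$knowledge))
  data.frame(repertoire = rownames(out), out, row.names = NULL)
}

#' Learning composition per entry
#'
#' Learning is any executed move but EXPLOIT (INNOVATE + OBSERVE + REFINE).
#' Reports, per entry, the proportion of executed moves that were learning
#' moves, the proportion of learning that was social (OBSERVE), and the
#' proportion of all executed moves that were REFINE. Forfeited rounds are
#' excluded from the move base and reported separately.
#'
#' @param sim A `sim_result` (uses the per-entry move totals).
#' @return A data frame with one row per entry.
#' @export
learning_composition <- function(sim) {
  mt <- sim$move_totals
  executed <- rowSums(mt[, MOVE_NAMES, drop = FALSE])
  learning <- rowSums(mt[, c("INNOVATE", "OBSERVE", "REFINE"), drop = FALSE])
  data.frame(
    entry_id = rownames(mt),
    moves = executed,
    prop_learning = ifelse(executed > 0, learning / executed, NA_real_),
    prop_learning_social = ifelse(learning > 0,
                                  mt[, "OBSERVE"] / learning, NA_real_),
    prop_refine = ifelse(executed > 0, mt[, "REFINE"] / executed, NA_real_),
    forfeits = mt[, "FORFEIT"],
    row.names = NULL)
}
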