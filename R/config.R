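#' Simulation configuration
#'
#' Collects every tournament parameter. Defaults are the Stage-1
#' cumulative-culture profile: 100 agents per deme, 100 behaviors, 10,000
#' rounds, environmental change probability `p_c = 0.01`, one model observed
#' per OBSERVE (`n_observe = 1`), copy-failure probability 0.05,
#' `r_max = 100` with the calibrated increment ceiling `p_max = 125`, death
#' probability 0.02 per round, mutation probability 1/50, and scoring (and
#' mutation shut-off) over the final quarter of rounds.
#'
#' @param extensions Character vector: any subset of `"cumulative"`,
#'   `"model_bias"`, `"spatial"`. `"none"` or `character(0)` disables all;
#'   `"all"` enables all three (the Stage-3 setting). REFINE is only a legal
#'   move when `"cumulative"` is enabled.
#' @param n_agents Agents per deme.
#' @param n_behaviors Number of bandit arms.
#' @param n_demes Demes; defaults to 3 under the spatial extension, else 1.
#' @param rounds Number of simulation rounds.
#' @param p_c Per-behavior, per-round payoff change probability.
#' @param n_observe Models sampled per OBSERVE move.
#' @param p_copyFail Per-event probability that a social-learning event fails.
#' @param r_max Maximum refinement level.
#' @param p_max Refinement increment at `r_max` (see [refinement_config()]).
#' @param n_migrate Migrants chosen per deme per round (spatial only).
#' @param death_prob Per-agent, per-round death probability.
#' @param mutation_prob Per-birth probability that the offspring's entry
#'   mutates to another registered entry.
#' @param score_window_fraction Fraction of final rounds used for scoring;
#'   mutation is disabled over the same window.
#' @param mutation_start Mutation is inactive during rounds
#'   `1..mutation_start` (the invasion burn-in; 0 = active from the start).
#' @param seed Integer root seed for all named RNG substreams.
#' @param record_diversity Record per-round behavior-usage and knowledge
#'   counts (needed by the diversity metrics).
#' @param record_moves Keep a full per-agent move log (memory-heavy; off by
#'   default).
#' @param strict If `TRUE`, an illegal strategy decision aborts the run
#'   instead of forfeiting the agent's round.
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(extensions = "cumulative",
                              n_agents = 100,
                              n_behaviors = 100,
                              n_demes = NULL,
                              rounds = 10000,
                              p_c = 0.01,
                              n_observe = 1,
                              p_copyFail = 0.05,
                              r_max = 100,
                              p_max = 125,
                              n_migrate = 10,
                              death_prob = 0.02,
                              mutation_prob = 1 / 50,
                              score_window_fraction = 0.25,
                              mutation_start = 0,
                              seed = 1,
                              record_diversity = TRUE,
                              record_moves = FALSE,
                              strict = FALSE) {
  extensions <- normalize_extensions(extensions)
  if (is.null(n_demes)) n_demes <- if ("spatial" %in% extensions) 3L else 1L
  cfg <- list(extensions = extensions,
              n_agents = as.integer(n_agents),
              n_behaviors = as.integer(n_behaviors),
              n_demes = as.integer(n_demes),
              rounds = as.integer(rounds),
              p_c = p_c,
              n_observe = as.integer(n_observe),
              p_copyFail = p_copyFail,
              r_max = as.integer(r_max),
              p_max = p_max,
              n_migrate = as.integer(n_migrate),
              death_prob = death_prob,
              mutation_prob = mutation_prob,
              score_window_fraction = score_window_fraction,
              mutation_start = as.integer(mutation_start),
              seed = as.integer(seed),
              record_diversity = isTRUE(record_diversity),
              record_moves = isTRUE(record_moves),
              strict = isTRUE(strict))
  class(cfg) <- "simulation_config"
  validate_config(cfg)
}

normalize_extensions <- function(extensions) {
  if (length(extensions) == 0) return(character(0))
  extensions <- tolower(as.character(extensions))
  if (identical(extensions, "none")) return(character(0))
  if (identical(extensions, "all")) {
    return(c("cumulative", "model_bias", "spatial"))
  }
  bad <- setdiff(extensions, c("cumulative", "model_bias", "spatial"))
  if (length(bad)) {
    stop("unknown extension(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unique(extensions)
}

validate_config <- function(cfg) {
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  for (p in c("p_c", "p_copyFail", "death_prob", "mutation_prob",
              "score_window_fraction")) {
    chk(is.numeric(cfg[[p]]) && length(cfg[[p]]) == 1 &&
          cfg[[p]] >= 0 && cfg[[p]] <= 1,
        sprintf("%s must be a probability in [0, 1]", p))
  }
  chk(cfg$n_agents >= 1, "n_agents must be >= 1")
  chk(cfg$n_behaviors >= 1, "n_behaviors must be >= 1")
  chk(cfg$n_demes >= 1, "n_demes must be >= 1")
  chk(cfg$rounds >= 0, "rounds must be >= 0")
  chk(cfg$n_observe >= 1, "n_observe must be >= 1")
  chk(cfg$r_max >= 1, "r_max must be >= 1")
  chk(cfg$p_max > 0, "p_max must be > 0")
  chk(cfg$n_migrate >= 0, "n_migrate must be >= 0")
  chk(cfg$mutation_start >= 0, "mutation_start must be >= 0")
  if (!("spatial" %in% cfg$extensions)) {
    chk(cfg$n_demes == 1, "n_demes must be 1 without the spatial extension")
  }
  if (length(problems)) {
    stop("invalid simulation_config:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  ext <- if (length(x$extensions)) paste(x$extensions, collapse = "+")
         else "none"
  cat(sprintf(paste0("<simulation_config> extensions: %s\n",
                     "  %d agents/deme x %d deme(s), %d behaviors, %d rounds\n",
                     "  p_c=%g n_observe=%d p_copyFail=%g r_max=%d p_max=%g",
                     " n_migrate=%d\n",
                     "  death=%g mutation=%g score window=%g seed=%d\n"),
              ext, x$n_agents, x$n_demes, x$n_behaviors, x$rounds,
              x$p_c, x$n_observe, x$p_copyFail, x$r_max, x$p_max,
              x$n_migrate, x$death_prob, x$mutation_prob,
              x$score_window_fraction, x$seed))
  invisible(x)
}

#' Load a simulation configuration from JSON or YAML
#'
#' Unknown keys and out-of-range values raise an error naming the offending
#' fields. Missing keys are filled from a named profile of defaults. An
#' empty file yields the full Stage-1 cumulative profile.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @param profile Default profile to fill unspecified fields:
#'   `"stage1"` (pairwise defaults), `"stage2"` or `"stage3"` (melee
#'   defaults: mutation active from round 1, all extensions for stage 3).
#' @return A validated [simulation_config()].
#' @export
load_config <- function(path, profile = c("stage1", "stage2", "stage3")) {
  profile <- match.arg(profile)
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(raw)) raw <- list()
  config_from_list(raw, profile = profile)
}

config_from_list <- function(raw, profile = "stage1") {
  defaults <- config_profile(profile)
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  args <- utils::modifyList(defaults, raw[intersect(names(raw), known)])
  do.call(simulation_config, args)
}

config_profile <- function(profile) {
  switch(profile,
    stage1 = list(extensions = "cumulative", mutation_start = 100L),
    stage2 = list(extensions = "cumulative", mutation_start = 0L),
    stage3 = list(extensions = "all", mutation_start = 0L),
    stop("unknown profile: ", profile, call. = FALSE))
}

#' Write a configuration to JSON
#'
#' @param cfg A [simulation_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "simulation_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
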