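#' Construct a move decision
#'
#' Helper for strategy authors: one of the four moves, with the behavior
#' argument required for EXPLOIT and REFINE and ignored otherwise.
#'
#' @param move One of `"EXPLOIT"`, `"INNOVATE"`, `"OBSERVE"`, `"REFINE"`.
#' @param behavior Behavior index (for EXPLOIT/REFINE).
#' @return A list with elements `move` and `behavior`.
#' @export
move_decision <- function(move, behavior = NA_integer_) {
  list(move = move, behavior = behavior)
}

#' Define a tournament strategy (entry)
#'
#' A strategy is a decision rule bound to every agent playing that entry.
#' Its `move` function receives a strategy view -- the agent's private
#' information only: age, aligned per-round histories (move, behavior,
#' payoff received or learned, deme, forfeit flag), current repertoire as
#' behavior/recorded-payoff pairs, migration history, and all simulation
#' parameters -- and returns a [move_decision()]. It never sees refinement
#' levels, the true payoff tables, or other agents' private state, and it
#' cannot persist information between rounds outside the view.
#'
#' The optional `observe_who` function implements model-biased copying:
#' it receives a data frame of noisy model information (columns `model_ref`,
#' `age`, `total_payoff`, `times_observed`, `n_offspring`, each estimate
#' Poisson-distributed around the true value, rows in randomized order) and
#' returns the same rows ranked by preference; the first `n_observe` become
#' the learning models. Strategies without `observe_who` get random models.
#'
#' @param entry_id Name of the entry.
#' @param move `function(view)` returning a [move_decision()].
#' @param observe_who Optional `function(model_info)` returning the ranked
#'   data frame (or a row-index permutation).
#' @return An object of class `strategy`.
#' @export
strategy <- function(entry_id, move, observe_who = NULL) {
  stopifnot(is.character(entry_id), length(entry_id) == 1,
            is.function(move),
            is.null(observe_who) || is.function(observe_who))
  structure(list(entry_id = entry_id, move = move, observe_who = observe_who),
            class = "strategy")
}

#' @export
print.strategy <- function(x, ...) {
  cat(sprintf("<strategy> %s%s\n", x$entry_id,
              if (is.null(x$observe_who)) "" else " (with observe_who)"))
  invisible(x)
}

best_known <- function(view) {
  # highest recorded payoff; first index on ties
  view$repertoire$behavior[which.max(view$repertoire$payoff)]
}

#' Reference strategy: innovate once, then exploit
#'
#' Learns a single behavior asocially in its first round, then exploits
#' that behavior for the rest of its life. The standard defending entry of
#' the melee stages.
#'
#' @return A [strategy()].
#' @export
innovate_once <- function() {
  strategy("innovateOnce", function(view) {
    if (length(view$repertoire$behavior) == 0) {
      move_decision("INNOVATE")
    } else {
      move_decision("EXPLOIT", view$repertoire$behavior[1])
    }
  })
}

#' Reference strategy: observe once, then exploit (blind copier)
#'
#' Plays OBSERVE until its repertoire is non-empty (repeating after failed
#' or model-less observations, since an empty-repertoire agent has no legal
#' EXPLOIT), then exploits its highest-recorded-payoff behavior forever.
#' The minimal-learning "blind copying" heuristic.
#'
#' @return A [strategy()].
#' @export
observe_exploit <- function() {
  strategy("observeExploit", function(view) {
    if (length(view$repertoire$behavior) == 0) {
      move_decision("OBSERVE")
    } else {
      move_decision("EXPLOIT", best_known(view))
    }
  })
}

#' Reference strategy family: selective ("smart") refiner
#'
#' A parametric heuristic family standing in for the tournament's flexible
#' refining entries: observe while naive; then refine the best-known
#' behavior only while (a) the best recorded payoff is below
#' `payoff_threshold` (a proxy for living in an unrefined world), (b) the
#' agent's age lies within `age_window`, and (c) fewer than `refine_budget`
#' REFINE moves have been spent; otherwise exploit the best-known behavior.
#' REFINE is only emitted when the cumulative extension is active.
#'
#' @param refine_budget Maximum lifetime REFINE moves.
#' @param age_window Two-element numeric: ages (rounds alive) during which
#'   refining is allowed.
#' @param payoff_threshold Recorded-payoff level above which the world is
#'   treated as already refined and the strategy stops refining.
#' @param entry_id Entry name.
#' @return A [strategy()].
#' @export
smart_refiner <- function(refine_budget = 30, age_window = c(0, 40),
                          payoff_threshold = 120,
                          entry_id = "smartRefiner") {
  force(refine_budget); force(age_window); force(payoff_threshold)
  strategy(entry_id, function(view) {
    if (length(view$repertoire$behavior) == 0) {
      return(move_decision("OBSERVE"))
    }
    best <- which.max(view$repertoire$payoff)
    best_beh <- view$repertoire$behavior[best]
    best_pay <- view$repertoire$payoff[best]
    if ("cumulative" %in% view$params$extensions &&
        best_pay < payoff_threshold &&
        view$age >= age_window[1] && view$age <= age_window[2] &&
        sum(view$history$move == "REFINE") < refine_budget) {
      move_decision("REFINE", best_beh)
    } else {
      move_decision("EXPLOIT", best_beh)
    }
  })
}

#' Reference model-ranking rule: payoff-rate bias
#'
#' Ranks available models by estimated total payoff per round of life
#' (`total_payoff / age`, with age 0 treated as rate `total_payoff`),
#' highest first, ties broken randomly.
#'
#' @return A function suitable as a [strategy()]'s `observe_who`.
#' @export
payoff_bias_observe_who <- function() {
  function(model_info) {
    if (nrow(model_info) == 0) return(model_info)
    rate <- ifelse(model_info$age > 0,
                   model_info$total_payoff / model_info$age,
                   model_info$total_payoff)
    ord <- order(rate, stats::runif(length(rate)), decreasing = TRUE)
    model_info[ord, , drop = FALSE]
  }
}

#' Built-in reference strategies
#'
#' @return A named list of constructors, keyed by entry name, each of which
#'   returns a fresh [strategy()] when called without arguments.
#' @export
builtin_strategies <- function() {
  list(
    innovateOnce = innovate_once,
    observeExploit = observe_exploit,
    smartRefiner = smart_refiner,
    observeExploitBias = function() {
      s <- observe_exploit()
      strategy("observeExploitBias", s$move, payoff_bias_observe_who())
    }
  )
}

#' Load strategies by name or from a plugin manifest
#'
#' Names matching [builtin_strategies()] are instantiated directly. A JSON
#' manifest may map additional entry names to R source files; each file must
#' define (or return) a function that, called without arguments, yields a
#' [strategy()] with the matching `entry_id`.
#'
#' @param names Character vector of entry names to load.
#' @param manifest Optional path to a JSON manifest
#'   (`{"entryName": "path/to/file.R", ...}`; relative paths are resolved
#'   against the manifest's directory).
#' @return Named list of [strategy()] objects.
#' @export
load_strategies <- function(names, manifest = NULL) {
  registry <- builtin_strategies()
  paths <- list()
  if (!is.null(manifest)) {
    paths <- jsonlite::read_json(manifest, simplifyVector = TRUE)
    paths <- lapply(paths, function(p) {
      if (!grepl("^(/|[A-Za-z]:)", p)) file.path(dirname(manifest), p) else p
    })
  }
  out <- list()
  for (nm in names) {
    if (nm %in% names(registry)) {
      out[[nm]] <- registry[[nm]]()
    } else if (nm %in% names(paths)) {
      env <- new.env(parent = globalenv())
      val <- source(paths[[nm]], local = env)$value
      ctor <- if (is.function(val)) val else get(nm, envir = env)
      out[[nm]] <- ctor()
    } else {
      stop("unknown strategy: ", nm, call. = FALSE)
    }
    if (!inherits(out[[nm]], "strategy")) {
      stop("loader for '", nm, "' did not return a strategy", call. = FALSE)
    }
  }
  out
}
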