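# Shared fixtures: scripted strategies and small configurations.

# Always claims to exploit a behavior it never learned: forfeits every round.
never_learn <- function(entry_id = "neverLearn") {
  strategy(entry_id, function(view) move_decision("EXPLOIT", 1L))
}

# Plays a fixed move script (recycled), taking behavior arguments from a
# parallel script; NA behavior means "best known".
scripted <- function(moves, behaviors = NULL, entry_id = "scripted") {
  strategy(entry_id, function(view) {
    k <- (view$age %% length(moves)) + 1L
    b <- if (!is.null(behaviors)) behaviors[k] else NA_integer_
    if (is.na(b) && moves[k] %in% c("EXPLOIT", "REFINE") &&
        length(view$repertoire$behavior)) {
      b <- view$repertoire$behavior[which.max(view$repertoire$payoff)]
    }
    move_decision(moves[k], b)
  })
}

# A strategy whose move function throws.
crasher <- function(entry_id = "crasher") {
  strategy(entry_id, function(view) stop("boom"))
}

tiny_cfg <- function(...) {
  defaults <- list(n_agents = 10, rounds = 20, seed = 42, p_c = 0,
                   death_prob = 0, mutation_start = 0)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# Fresh internal state for direct unit tests of move application.
tiny_state <- function(cfg = tiny_cfg(), entries = list(innovate_once()),
                       ...) {
  refinebandit:::new_sim_state(cfg, entries, ...)
}

# Direct summation of the refinement-increment series: the printed
# geometric sum, used as the brute-force oracle for the closed form.
increment_oracle <- function(r, r_max, p_max, decay = 0.95, scale = 0.05) {
  if (r == 0) return(0)
  scale / (1 - decay^r_max) * sum(decay^(r - seq_len(r))) * p_max
}
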