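resolve_once <- function(st) {
  st$round <- st$round + 1L
  refinebandit:::resolve_round(st)
  st
}

test_that("INNOVATE learns a uniformly random unknown behavior exactly", {
  cfg <- tiny_cfg(n_agents = 1, n_behaviors = 10)
  st <- tiny_state(cfg, list(scripted(rep("INNOVATE", 5))))
  # seed all but behavior 7
  st$rep_pay[1, -7] <- 1
  st <- resolve_once(st)
  expect_equal(st$hist[[1]]$behavior[1], 7L)
  expect_equal(st$rep_pay[1, 7], st$env$payoffs[1, 7])
  expect_equal(st$rep_ref[1, 7], 0L)
  # full repertoire: no-op, not a forfeit
  st <- resolve_once(st)
  expect_false(st$hist[[1]]$forfeited[2])
  expect_true(is.na(st$hist[[1]]$payoff[2]))

  # uniformity over the unknown set
  counts <- integer(10)
  for (k in 1:4000) {
    st2 <- tiny_state(tiny_cfg(n_agents = 1, n_behaviors = 10, seed = k),
                      list(scripted("INNOVATE")))
    st2 <- resolve_once(st2)
    b <- st2$hist[[1]]$behavior[1]
    counts[b] <- counts[b] + 1L
  }
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
})

test_that("EXPLOIT pays the current total payoff and corrects stale records", {
  cfg <- tiny_cfg(n_agents = 1, n_behaviors = 5)
  st <- tiny_state(cfg, list(scripted("EXPLOIT", 2L)))
  st$rep_pay[1, 2] <- 40 # stale record
  st$env$payoffs[1, 2] <- 3L
  st <- resolve_once(st)
  expect_equal(st$hist[[1]]$payoff[1], 3)
  expect_equal(st$rep_pay[1, 2], 3)
  expect_equal(st$total_payoff[1], 3)
  # unchanged environment: consecutive exploits pay identically
  st <- resolve_once(st)
  expect_equal(st$hist[[1]]$payoff[2], 3)
})

test_that("REFINE raises the hidden level, saturates at r_max, pays exactly", {
  cfg <- tiny_cfg(n_agents = 1, n_behaviors = 5, r_max = 3, p_max = 100,
                  extensions = "cumulative")
  st <- tiny_state(cfg, list(scripted("REFINE", 2L)))
  st$rep_pay[1, 2] <- st$env$payoffs[1, 2]
  rc <- refinement_config(3, 100)
  for (k in 1:5) st <- resolve_once(st)
  expect_equal(st$rep_ref[1, 2], 3L) # capped at r_max
  expect_equal(st$rep_pay[1, 2], st$env$payoffs[1, 2] + 100)
  expect_equal(st$hist[[1]]$payoff[1],
               st$env$payoffs[1, 2] + refinement_increment(1, rc))
})

test_that("REFINE outside the cumulative extension forfeits the round", {
  cfg <- tiny_cfg(n_agents = 1, n_behaviors = 5, extensions = "none")
  st <- tiny_state(cfg, list(scripted("REFINE", 2L)))
  st$rep_pay[1, 2] <- 1
  st <- resolve_once(st)
  expect_true(st$hist[[1]]$forfeited[1])
  expect_equal(st$rep_ref[1, 2], 0L)
})

test_that("illegal decisions forfeit (or abort in strict mode)", {
  cfg <- tiny_cfg(n_agents = 2, n_behaviors = 5)
  st <- tiny_state(cfg, list(never_learn(), crasher()),
                   initial_entry = c("neverLearn", "crasher"))
  st <- resolve_once(st)
  expect_true(all(st$hist[[1]]$forfeited, st$hist[[2]]$forfeited))
  expect_equal(st$total_payoff, c(0, 0))
  expect_equal(st$n_forfeits, 2L)
  expect_equal(st$age, c(1L, 1L)) # forfeited rounds still count as lived

  strict <- tiny_state(tiny_cfg(n_agents = 1, strict = TRUE),
                       list(crasher()))
  strict$round <- 1L
  expect_error(refinebandit:::resolve_round(strict), "illegal decision")
})

test_that("the model pool is exactly this round's same-deme exploiters", {
  # agent 1 exploits, agent 2 innovates, agent 3 forfeits, agent 4 observes;
  # agent 5 exploits in the other deme and must be invisible to agent 4
  cfg <- simulation_config(extensions = "spatial", n_agents = 2, n_demes = 3,
                           rounds = 5, p_c = 0, death_prob = 0,
                           n_migrate = 0, p_copyFail = 0, seed = 9)
  entries <- list(scripted("EXPLOIT", 1L, entry_id = "ex"),
                  scripted("INNOVATE", entry_id = "in"),
                  never_learn(),
                  scripted("OBSERVE", entry_id = "ob"))
  # demes are filled in blocks of n_agents: (1,2), (3,4), (5,6)
  st <- tiny_state(cfg, entries,
                   initial_entry = c("ex", "ob", "in", "neverLearn",
                                     "ex", "in"))
  st$rep_pay[1, 1] <- 5
  st$rep_pay[5, 1] <- 5
  st$env$payoffs[1, 1] <- 17L
  st$env$payoffs[3, 1] <- 99L
  st <- resolve_once(st)
  # the deme-1 observer copied the deme-1 exploiter, not the deme-3 one
  expect_equal(st$hist[[2]]$behavior[1], 1L)
  expect_false(is.na(st$rep_pay[2, 1]))
  expect_equal(st$times_observed, c(1L, 0L, 0L, 0L, 0L, 0L))
})

test_that("an observer with no exploiting models learns nothing", {
  cfg <- tiny_cfg(n_agents = 2, n_behaviors = 5)
  st <- tiny_state(cfg, list(scripted("OBSERVE", entry_id = "ob"),
                             scripted("INNOVATE", entry_id = "in")),
                   initial_entry = c("ob", "in"))
  st <- resolve_once(st)
  expect_true(all(is.na(st$rep_pay[1, ])))
  expect_false(st$hist[[1]]$forfeited[1])
})

test_that("n_observe models are sampled without replacement; failures consume events", {
  mk <- function(p_fail, n_obs, seed) {
    cfg <- tiny_cfg(n_agents = 11, n_behaviors = 20, p_copyFail = p_fail,
                    n_observe = n_obs, seed = seed)
    entries <- list(scripted("EXPLOIT", entry_id = "ex"),
                    scripted("OBSERVE", entry_id = "ob"))
    st <- tiny_state(cfg, entries, initial_entry = c(rep("ex", 10), "ob"))
    for (i in 1:10) st$rep_pay[i, i] <- 1 # each exploits its own behavior
    resolve_once(st)
  }
  st <- mk(0, 5, 3)
  expect_equal(sum(st$times_observed), 5L)
  expect_equal(sum(!is.na(st$rep_pay[11, ])), 5L) # 5 distinct behaviors
  st <- mk(1, 5, 3)
  expect_equal(sum(st$times_observed), 0L)
  expect_true(all(is.na(st$rep_pay[11, ])))
})

test_that("payoff estimates are Poisson around the model's received payoff", {
  ests <- vapply(1:3000, function(k) {
    cfg <- tiny_cfg(n_agents = 2, n_behaviors = 3, p_copyFail = 0, seed = k)
    st <- tiny_state(cfg, list(scripted("EXPLOIT", 1L, entry_id = "ex"),
                               scripted("OBSERVE", entry_id = "ob")),
                     initial_entry = c("ex", "ob"))
    st$rep_pay[1, 1] <- 1
    st$env$payoffs[1, 1] <- 40L
    st <- resolve_once(st)
    st$rep_pay[2, 1]
  }, 0)
  expect_lt(abs(mean(ests) - 40), 3 * sqrt(40 / length(ests)))
  expect_lt(abs(stats::var(ests) - 40), 0.1 * 40)
  # a zero true payoff is estimated as zero with certainty
  cfg <- tiny_cfg(n_agents = 2, n_behaviors = 3, p_copyFail = 0, seed = 1)
  st <- tiny_state(cfg, list(scripted("EXPLOIT", 1L, entry_id = "ex"),
                             scripted("OBSERVE", entry_id = "ob")),
                   initial_entry = c("ex", "ob"))
  st$rep_pay[1, 1] <- 1
  st$env$payoffs[1, 1] <- 0L
  st <- resolve_once(st)
  expect_equal(st$rep_pay[2, 1], 0)
})

test_that("copied behaviors carry the model's refinement level", {
  cfg <- tiny_cfg(n_agents = 2, n_behaviors = 3, p_copyFail = 0,
                  extensions = "cumulative", r_max = 50, seed = 4)
  st <- tiny_state(cfg, list(scripted("EXPLOIT", 1L, entry_id = "ex"),
                             scripted("OBSERVE", entry_id = "ob")),
                   initial_entry = c("ex", "ob"))
  st$rep_pay[1, 1] <- 1
  st$rep_ref[1, 1] <- 12L
  st <- resolve_once(st)
  expect_equal(st$rep_ref[2, 1], 12L)
})

test_that("model info is Poisson-noised on all four performance indexes", {
  cfg <- tiny_cfg(n_agents = 3, seed = 1)
  st <- tiny_state(cfg, list(innovate_once()))
  st$age <- c(0L, 10L, 10L)
  st$total_payoff <- c(0, 400, 0)
  st$n_offspring <- c(0L, 4L, 0L)
  st$times_observed <- c(0L, 7L, 0L)
  set.seed(99)
  reps <- replicate(4000, {
    info <- refinebandit:::build_model_info(st, c(1L, 2L))
    unlist(info[info$model_ref == 2, c("age", "total_payoff",
                                       "times_observed", "n_offspring")])
  })
  means <- rowMeans(reps)
  expect_lt(abs(means["age"] - 10), 3 * sqrt(10 / 4000))
  expect_lt(abs(means["total_payoff"] - 400), 3 * sqrt(400 / 4000))
  expect_lt(abs(means["times_observed"] - 7), 3 * sqrt(7 / 4000))
  expect_lt(abs(means["n_offspring"] - 4), 3 * sqrt(4 / 4000))
  # true zeros are reported as exact zeros
  info <- refinebandit:::build_model_info(st, 1L)
  expect_equal(unlist(info[1, -1]), c(age = 0, total_payoff = 0,
                                      times_observed = 0, n_offspring = 0))
  empty <- refinebandit:::build_model_info(st, integer(0))
  expect_identical(nrow(empty), 0L)
})

test_that("the strategy view hides refinement levels and global state", {
  cfg <- tiny_cfg(n_agents = 2, extensions = "cumulative")
  st <- tiny_state(cfg, list(innovate_once()))
  st$rep_pay[1, 1] <- 5
  st$rep_ref[1, 1] <- 3L
  v <- refinebandit:::make_view(st, 1)
  expect_named(v, c("age", "deme", "repertoire", "history",
                    "migration_rounds", "params"))
  expect_named(v$repertoire, c("behavior", "payoff"))
  flat <- unlist(lapply(v, names))
  expect_false(any(grepl("ref", flat, ignore.case = TRUE)))
  expect_false(any(grepl("payoffs|env", flat)))
})

test_that("a living agent's repertoire never shrinks", {
  cfg <- simulation_config(n_agents = 12, rounds = 40, death_prob = 0,
                           p_c = 0.2, p_copyFail = 0.2, seed = 31,
                           extensions = "cumulative", mutation_start = 0)
  st <- tiny_state(cfg, list(innovate_once(), observe_exploit(),
                             smart_refiner()),
                   initial_entry = rep(c("innovateOnce", "observeExploit",
                                         "smartRefiner"), 4))
  known_prev <- rowSums(!is.na(st$rep_pay))
  for (r in 1:40) {
    st <- resolve_once(st)
    known <- rowSums(!is.na(st$rep_pay))
    expect_true(all(known >= known_prev))
    known_prev <- known
  }
})
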