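test_that("innovateOnce learns once asocially then exploits for life", {
  cfg <- tiny_cfg(n_agents = 3, rounds = 50, record_moves = TRUE)
  sim <- run_simulation(cfg, list(innovate_once()))
  log <- sim$move_log
  for (a in 1:3) {
    mine <- log[log$agent_id == a, ]
    expect_equal(mine$move[1], "INNOVATE")
    expect_true(all(mine$move[-1] == "EXPLOIT"))
    expect_equal(length(unique(mine$behavior[-1])), 1L)
    expect_equal(sum(mine$move != "EXPLOIT"), 1L)
  }
})

test_that("observeExploit keeps observing until it learns, then exploits", {
  # certain copy failure: observes every round, never exploits
  cfg <- tiny_cfg(n_agents = 4, rounds = 30, p_copyFail = 1,
                  record_moves = TRUE)
  sim <- run_simulation(cfg, list(observe_exploit(), innovate_once()),
                        initial_entry = c("observeExploit", "innovateOnce",
                                          "innovateOnce", "innovateOnce"))
  expect_equal(unname(sim$move_totals["observeExploit", "OBSERVE"]), 30L)
  expect_equal(unname(sim$move_totals["observeExploit", "EXPLOIT"]), 0L)

  # models first exist in round 2 (residents innovate in round 1); the
  # first successful observation switches it to exploiting thereafter
  cfg2 <- tiny_cfg(n_agents = 4, rounds = 30, p_copyFail = 0,
                   record_moves = TRUE)
  sim2 <- run_simulation(cfg2, list(observe_exploit(), innovate_once()),
                         initial_entry = c("observeExploit", "innovateOnce",
                                           "innovateOnce", "innovateOnce"))
  mine <- sim2$move_log[sim2$move_log$agent_id == 1, ]
  expect_equal(mine$move, c("OBSERVE", "OBSERVE", rep("EXPLOIT", 28)))
})

test_that("observeExploit exploits the higher of two observed estimates", {
  cfg <- tiny_cfg(n_agents = 3, n_behaviors = 10, n_observe = 2,
                  p_copyFail = 0, rounds = 2, record_moves = TRUE, seed = 12)
  st <- tiny_state(cfg, list(scripted("EXPLOIT", entry_id = "ex"),
                             observe_exploit()),
                   initial_entry = c("ex", "ex", "observeExploit"))
  st$rep_pay[1, 1] <- 1; st$env$payoffs[1, 1] <- 60L
  st$rep_pay[2, 2] <- 1; st$env$payoffs[1, 2] <- 2L
  st$round <- 1L
  refinebandit:::resolve_round(st)
  st$round <- 2L
  refinebandit:::resolve_round(st)
  h <- st$hist[[3]]
  expect_equal(h$move, c("OBSERVE", "EXPLOIT"))
  best <- which.max(st$rep_pay[3, ])
  expect_equal(h$behavior[2], best)
})

test_that("smartRefiner honours budget, window and threshold", {
  # budget 0: never refines, trace-equivalent to observeExploit
  cfg <- tiny_cfg(n_agents = 4, rounds = 40, extensions = "cumulative",
                  p_copyFail = 0, record_moves = TRUE, seed = 14)
  entries <- list(innovate_once(),
                  smart_refiner(refine_budget = 0, entry_id = "noBudget"))
  sim <- run_simulation(cfg, entries,
                        initial_entry = c("innovateOnce", "innovateOnce",
                                          "innovateOnce", "noBudget"))
  expect_equal(unname(sim$move_totals["noBudget", "REFINE"]), 0L)

  # fresh unrefined world: refines within its age window
  entries2 <- list(innovate_once(), smart_refiner())
  sim2 <- run_simulation(cfg, entries2,
                         initial_entry = c("innovateOnce", "innovateOnce",
                                           "innovateOnce", "smartRefiner"))
  mine <- sim2$move_log[sim2$move_log$agent_id == 4, ]
  expect_gt(sum(mine$move == "REFINE"), 0)
  first_refine <- min(which(mine$move == "REFINE"))
  expect_lte(first_refine, 41)

  # recorded payoff above threshold: reduces to observe-then-exploit
  st <- tiny_state(tiny_cfg(n_agents = 1, extensions = "cumulative",
                            rounds = 10),
                   list(smart_refiner(payoff_threshold = 50)))
  st$rep_pay[1, 2] <- 60
  st$round <- 1L
  refinebandit:::resolve_round(st)
  expect_equal(st$hist[[1]]$move[1], "EXPLOIT")
})

test_that("smartRefiner never refines outside the cumulative extension", {
  cfg <- tiny_cfg(n_agents = 4, rounds = 30, extensions = "none",
                  p_copyFail = 0)
  sim <- run_simulation(cfg, list(innovate_once(), smart_refiner()),
                        initial_entry = c("innovateOnce", "innovateOnce",
                                          "innovateOnce", "smartRefiner"))
  expect_equal(unname(sim$move_totals["smartRefiner", "REFINE"]), 0L)
  expect_equal(unname(sim$move_totals["smartRefiner", "FORFEIT"]), 0L)
})

test_that("payoff-rate ranking prefers higher payoff per round of life", {
  rank_fn <- payoff_bias_observe_who()
  one <- data.frame(model_ref = 1L, age = 3L, total_payoff = 30L,
                    times_observed = 0L, n_offspring = 0L)
  expect_equal(rank_fn(one)$model_ref, 1L)

  two <- data.frame(model_ref = c(1L, 2L), age = c(10L, 2L),
                    total_payoff = c(100L, 50L), times_observed = 0L,
                    n_offspring = 0L)
  set.seed(1)
  expect_equal(rank_fn(two)$model_ref[1], 2L) # 25/round beats 10/round

  zero_age <- data.frame(model_ref = c(1L, 2L), age = c(0L, 1L),
                         total_payoff = c(5L, 100L), times_observed = 0L,
                         n_offspring = 0L)
  expect_equal(rank_fn(zero_age)$model_ref[1], 2L)
})

test_that("payoff-biased copying beats random copying on copied payoff", {
  # strong payoff spread among exploiters; compare the payoff actually
  # copied by a biased observer against a random-choice observer
  run_one <- function(biased, seed) {
    cfg <- simulation_config(extensions = "model_bias", n_agents = 12,
                             rounds = 12, p_c = 0, p_copyFail = 0,
                             n_observe = 1, death_prob = 0, seed = seed,
                             mutation_start = 0)
    obs <- if (biased) {
      strategy("obs", observe_exploit()$move, payoff_bias_observe_who())
    } else {
      strategy("obs", observe_exploit()$move)
    }
    sim <- run_simulation(cfg, list(innovate_once(), obs),
                          initial_entry = c(rep("innovateOnce", 11), "obs"))
    # the observer's first exploit reveals what it copied
    sum(sim$agents$total_exploit_payoff[12]) / max(1, 11)
  }
  seeds <- 1:60
  gain_biased <- vapply(seeds, function(s) run_one(TRUE, s), 0)
  gain_random <- vapply(seeds + 500, function(s) run_one(FALSE, s), 0)
  expect_gt(mean(gain_biased), mean(gain_random))
})

test_that("strategy decisions replay bit-for-bit from the same seed", {
  cfg <- simulation_config(n_agents = 20, rounds = 60, seed = 77,
                           p_c = 0.05, p_copyFail = 0.1,
                           extensions = "cumulative", record_moves = TRUE,
                           mutation_start = 0)
  mk <- function() list(innovate_once(), observe_exploit(), smart_refiner())
  sim1 <- run_simulation(cfg, mk(), initial_entry = "innovateOnce")
  sim2 <- run_simulation(cfg, mk(), initial_entry = "innovateOnce")
  expect_identical(sim1$move_log, sim2$move_log)
  expect_identical(sim1$score, sim2$score)
})

test_that("strategy loading resolves builtins and plugin manifests", {
  got <- load_strategies(c("innovateOnce", "observeExploit"))
  expect_named(got, c("innovateOnce", "observeExploit"))
  expect_s3_class(got$innovateOnce, "strategy")
  expect_error(load_strategies("noSuchEntry"), "unknown strategy")

  dir <- withr::local_tempdir()
  writeLines(c(
    "function() {",
    "  refinebandit::strategy('pluginEntry', function(view) {",
    "    refinebandit::move_decision('INNOVATE')",
    "  })",
    "}"), file.path(dir, "plugin.R"))
  jsonlite::write_json(list(pluginEntry = "plugin.R"),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  got2 <- load_strategies("pluginEntry",
                          manifest = file.path(dir, "manifest.json"))
  expect_equal(got2$pluginEntry$entry_id, "pluginEntry")
})
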