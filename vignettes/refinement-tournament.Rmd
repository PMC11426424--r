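---
title: "The refinement tournament: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The refinement tournament: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refinebandit)
```

## The model

`refinebandit` simulates the evolution of learning strategies on a
restless multi-armed bandit. A population of agents (100 per deme by
default) shares an environment of `n_behaviors = 100` behaviors, each with
a basic integer payoff drawn as `round(2 * X^2)`, `X ~ Exponential(1)`:
most payoffs are small, a few are large, and the bulk of the mass lies in
0–50. Each round, each behavior's payoff is independently redrawn with
probability `p_c` — the "restless" dynamic that makes recorded knowledge
go stale.

Agents act through four moves. Only EXPLOIT earns payoff; INNOVATE,
OBSERVE and REFINE all cost the round's exploitation opportunity, which is
the only learning cost in the model. INNOVATE returns a uniformly random
unknown behavior with its exact current payoff; OBSERVE copies the
behaviors of randomly chosen same-round, same-deme exploiters, with
per-event failure probability `p_copyFail` and Poisson-distributed payoff
estimates (so larger payoffs carry larger absolute errors); REFINE raises
a known behavior's refinement level by one. The payoff of a behavior at
refinement level `r` is its basic payoff plus

```
increment(r) = p_max * (1 - 0.95^r) / (1 - 0.95^r_max),
```

the closed form of a geometric diminishing-returns series: successive
increments shrink by the factor 0.95, `increment(0) = 0`, and
`increment(r_max) = p_max`. Refinement levels are deliberately hidden from
strategies (and from observers, who inherit the demonstrated level
without knowing it): agents see payoffs, not refinement counters.

Selection is a death–birth process. Each agent independently dies with
probability `death_prob = 0.02` per round (expected lifespan 50 rounds);
each vacancy is filled by a naive newborn whose parent is drawn among
same-deme survivors with probability proportional to mean lifetime payoff
`P_z`. Births mutate with probability `1/50` to a uniformly chosen other
registered entry; mutation is silent during the final quarter of the run,
which is also the scoring window (an entry's score is its mean population
frequency over that window).

A round is: (i) all moves are chosen against pre-round views and resolved
in two phases (OBSERVE is processed after the other moves, so every
exploiter of the round is a potential model regardless of agent order);
(ii) death–birth; (iii) environmental change; (iv) migration in the
spatial case.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `p_c` | 0.01 | per-behavior, per-round payoff change probability (plausible range explored: 0.001–0.4) |
| `n_observe` | 1 | models sampled per OBSERVE (1–10 in melee grids) |
| `p_copyFail` | 0.05 | per-event social-learning failure probability (0–0.5) |
| `r_max` | 100 | maximum refinement level (10–1000 in melee grids) |
| `p_max` | 125 | increment at `r_max`; see calibration below |
| `n_migrate` | 10 | migrants per deme per round (spatial; melee range 1–20) |
| `death_prob` | 0.02 | per-round death probability |
| `mutation_prob` | 1/50 | per-birth entry mutation probability |
| `rounds` | 10000 | simulation length; scoring window = final quarter |

### Calibrating `p_max`

The increment ceiling has no canonical value; what is pinned down is the
*relationship* between refinement and the basic-payoff distribution:
refining should overtake the best unrefined payoff after roughly ten
refine moves at `r_max = 100`, and refined payoffs should typically
exceed every basic payoff beyond level 8. The default was therefore
calibrated against the generator itself: the maximum of 100 basic-payoff
draws has median ≈ 49, and `p_max = 125` puts the median minimal level
whose increment beats that maximum at 10 (interquartile range roughly
7–16). A ceiling of 100 would shift that median to 14, weakening the
intended "refinement wins if you persist" structure.
`calibrate_refinement()` recomputes this curve, and
`scripts/acceptance.R` reports it.

## What the generator emulates — and what it does not

All inputs are synthetic by design: the environment *is* the model. The
generator reproduces the study conditions — heavy-tailed payoffs,
independent per-arm change, independent deme tables, Poisson social
noise — but nothing about real cultural systems beyond them: no payoff
correlations, no behavior-specific change rates, no recombination of
variants, no cooperative payoff structure. Passing tests therefore shows
that the engine implements this model faithfully, not that real cumulative
culture behaves like the model.

The 51 originally submitted tournament entries are not available; the
package ships the two protocol-defined reference entries (`innovate_once`,
`observe_exploit`), a payoff-rate `observe_who` ranking, and a *documented
stand-in*: the `smart_refiner()` parametric family (observe while naive;
refine the best-known behavior while its recorded payoff is below
`payoff_threshold`, the agent is within `age_window`, and a lifetime
`refine_budget` remains). The family's defaults (budget 30, window 0–40
rounds, threshold 120) were chosen so that refining continues while
recorded payoffs are below roughly the level reachable by ~45
refinements and stops in heavily refined worlds — the behavior reported
for successful flexible entries. The threshold is an explicit proxy for
"estimating that the world is unrefined"; the original entries'
estimators are unknown.

## Contest protocol

Pairwise invasion contests run a defender monoculture for a 100-round
burn-in, then enable mutation with the invader as the only target — an
invader lost to drift can re-enter, matching a mutation-driven process
rather than one-shot seeding. Six parameter sets (`p_c` in {0.001, 0.01,
0.1} × `n_observe` in {1, 5}, `p_copyFail = 0.05`, `r_max = 100`), two
directions and two replicates give 24 simulations per unordered pair;
`stage1_schedule()` reports ordered-pair contest counts so either reading
of the headline contest total is checkable. Melees seed all entries by
mutation into an `innovateOnce` resident over the printed 7 × 7 × 4 × 6
systematic grid, or over exponentially drawn parameter sets. The draw
rates are not canonical; the package uses exponentials with means at the
midpoints of the systematic ranges, clamped to those ranges, and records
the drawn values with the run.

The stopping-criterion experiment halts a melee-style cumulative run the
first time the *mean refinement level of the behaviors performed that
round* (mean over non-forfeited EXPLOIT moves of the exploited behavior's
level) exceeds a criterion, then compares mean lifetime payoff between
the smart-refiner class and the blind copier (surviving residents form a
class of their own). Censored runs (criterion never reached within the
round budget) are flagged, not discarded silently.

## Numerical and design choices

* **Rounding.** Basic payoffs round half away from zero
  (`floor(2x^2 + 0.5)`), chosen once so results are bit-stable.
* **RNG.** One root seed derives named L'Ecuyer-CMRG substreams
  (environment, moves, demography, migration, observation, strategies) in
  a fixed order, so components are independently replayable and adding
  draws to one never perturbs another. Manifests capture the
  configuration, entry source hashes and seed; `replay()` reproduces a
  run bit-for-bit and refuses version or hash mismatches.
* **Model sampling** is without replacement, and an observer is never in
  its own pool (it is not exploiting that round). Failed copy events
  consume the event.
* **Observing a known behavior** overwrites the record and adopts the
  demonstrated refinement level — including a lower one. The alternative
  (keep the higher level) is defensible; overwriting was chosen because
  observation is defined as acquiring the demonstrated variant.
* **Illegal or erroring strategy decisions** forfeit the round: no
  payoff, no learning, but the round counts toward age. `strict = TRUE`
  aborts instead, for debugging.
* **Degenerate weights.** If every candidate parent has zero mean
  lifetime payoff, parents are drawn uniformly; if a deme's death draw
  kills everyone, the pre-death deme serves as the parent pool.
* **Migration** reassigns each selected migrant to a uniformly chosen
  *different* deme, so deme sizes may drift while total population is
  conserved; reproduction is within-deme.
* **Evenness** uses `S = n_behaviors` (the possible behaviors, not the
  observed ones): this is the only normalization under which both
  boundary statements hold — J = 1 exactly when *all possible* behaviors
  are used equally, J = 0 when a single behavior is used. The knowledge
  analogue substitutes "knowing" for "using" and is labelled as an
  extension. All-zero counts return `NA` rather than a value.
* **Persistence** treats a behavior as the same behavior across
  refinement levels, and is computed per deme then averaged; both
  whole-run and last-quarter windows are available (whole-run default).
* **Ties** in promotion between stages break by total score, then entry
  id, and are logged in the returned table.

## Problem sizes

Full-scale runs (100 agents, 10,000 rounds) are supported but slow in
pure R (~1 minute per simulation with simple strategies). The package's
test suite exercises the same code paths at reduced scale, chosen as the
smallest sizes at which the checked contrasts are statistically stable:
invasion contests at 30–40 agents and 200–500 rounds, the
stopping-criterion experiment at 50 agents with a 2,000-round censoring
horizon and 50 replicates per level, and the diversity contrast at 50
agents, 1,200 rounds and `p_c = 0.1` (fast environmental turnover keeps
baseline persistence off the run-length ceiling).

## Limitations

Payoff dynamics are uncorrelated and memoryless; refinement is strictly
payoff-improving with a fixed diminishing-returns form; strategies are
stateless between rounds by contract; and conclusions about the original
tournament's specific entries cannot be reproduced, only the protocol and
the qualitative contrasts the reference family was designed to exhibit.
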