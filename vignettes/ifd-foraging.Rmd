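---
title: "Personality-dependent foraging and the ideal free distribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personality-dependent foraging and the ideal free distribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(ifdsim)
```

## The model

A population of `N` foraging consumers distributes itself over `P`
habitat patches (by default a 7×7 grid, 49 patches). Patch `p` supplies
resources at a constant input rate `Q_p > 0`; a consumer on a patch
holding `n_p` foragers realises a per-capita intake that depends on the
patch only through the resource-per-capita ratio `Q_p / n_p`:

* **type I** (linear): intake `= Q_p / n_p`;
* **type II** (saturating, Arditi–Ginzburg ratio-dependent form): intake
  `= a (Q_p/n_p) / (1 + a h (Q_p/n_p))` with attack rate `a > 0` and
  handling time `h ≥ 0`.

Consumers are omniscient and mobile without cost: whenever a consumer
*assesses* its situation, it compares its current intake
`f(Q_p, n_p)` with the prospective intake `f(Q_q, n_q + 1)` on every
other patch — counting itself at the destination, and not double-counting
itself at the origin. If the best alternative is *strictly* better it
moves there instantly (ties among equally good destinations are broken
uniformly at random from the run's seeded RNG stream); if its current
patch is already maximal it stays. Consistency of the two formulas is
essential: comparing a current intake computed one way with a
prospective intake computed another lets consumers "believe" they are
optimally placed when they are not, and inverts the predicted relation
between activity composition and equilibration time.

What distinguishes individuals is a single stable trait, **activity**
`∈ [0, 1]`: how often a consumer assesses. It is a per-opportunity
assessment probability in discrete time and an assessment *rate* per
unit time in continuous time. Activity never affects *where* a consumer
moves, only *when* it gets the chance.

The **ideal free distribution (IFD)** is the absorbing set of this
process: a state in which no consumer has a strictly improving move,
```
for every occupied patch p:  f(Q_p, n_p) ≥ f(Q_q, n_q + 1)  for all q ≠ p.
```
`is_ifd()` implements this predicate exactly; empty patches are valid
move targets but are not tested as sources.

### Why type I and type II give identical dynamics

Both responses are strictly increasing functions of the single quantity
`Q/n`. A strictly monotone transform preserves every comparison the
movement rule makes — current vs. best prospective intake, and the
identity of the argmax set — so the accepted-move sequence, the final
distribution, and the time to the IFD coincide *exactly* for
seed-matched runs, for any `a > 0, h ≥ 0`. The test suite verifies this
on hundreds of seed-matched run pairs under both schedulers. A practical
corollary: the numerical values of the type II parameters are
behaviourally irrelevant here, which is why the defaults (`a = 1`,
`h = 1`) need no tuning.

### Termination: the congestion potential

The process is a congestion game with potential
`Φ = Σ_p Σ_{k=1..n_p} f(Q_p, k)`. Any accepted move changes `Φ` by
exactly the mover's intake gain, which is strictly positive by the
strict-improvement rule; `Φ` is bounded above on a fixed landscape, so
sequential best-response dynamics on a static landscape always reach a
true IFD in finitely many moves. `potential()` exposes `Φ`, and the
suite replays recorded move logs to confirm the strict increase at every
single accepted move. This is also why requiring *strict* improvement
(ties with the current patch mean "stay") is not a cosmetic choice: it
is what guarantees termination.

On a static landscape with continuous qualities the dynamics have a
stronger empirical property: **no consumer needs to move more than
once**. Whether this holds with probability 1 for every tie structure is
open; with qualities drawn from a continuous distribution (the package
default, uniform on [1, 10]), exact intake ties between distinct patches
have measure zero and the bound holds in every run we test. This is the
reason the default quality distribution is continuous rather than a
small set of round numbers.

## The two schedulers

**Discrete time** (`run_discrete()`): each time step, *one* consumer is
chosen uniformly at random, and with probability equal to its activity
it assesses (and moves if profitable). One decision opportunity per
step is the documented design: it reproduces the mechanical property
that in a larger population, more individuals must take turns, so time
to any target distribution inflates with `N` — an artefact of the clock,
not of the ecology. (Whether the original formulation selected consumers
uniformly or in shuffled sweeps is not recoverable; uniform selection is
this package's documented choice.)

**Continuous time** (`run_gillespie()`): consumers assess independently
at exponential rates equal to their activities, simulated exactly with
the Gillespie algorithm — waiting times `Exp(Λ)` with `Λ = Σ_i a_i`,
the assessor drawn with probability `a_i / Λ`, and no second Bernoulli
trial (the rate *is* the activity). The movement rule and predicate are
shared verbatim with the discrete scheduler; only the clock differs, so
any difference between the schedulers' conclusions is attributable to
the time scale. On this natural scale the population-size story
reverses: at `N = 1000` on 49 patches, crowded patches mean that every
departure raises the intake of everyone left behind ("alleviated
within-patch competition"), and the IFD is reached *faster* than at
`N = 40` or `N = 100`. Rescaling all activities by a common factor `c`
rescales event times by `1/c` and changes nothing else — a seed-matched
invariance the tests check exactly.

## Stopping rules, and why the choice matters

* `true_ifd` — stop when the exact predicate first holds. It is checked
  at time 0 and after every accepted move (and after every quality
  change); between such events the state cannot change, so no check is
  missed. `time_to_stop` is the time of the last accepted move.
* `quiescence` — stop after `quiescence_K = 50` consecutive steps
  without a patch change (a consumer that assessed and stayed counts as
  quiescent: the criterion watches movement, not assessment).

The quiescence rule is a *biased estimator of equilibrium*: in
populations dominated by low-activity individuals, 50 still steps
usually reflect reluctance to move, not optimality. Every run result
therefore carries `reached_true_ifd`, the exact predicate evaluated at
stop regardless of stopping rule. In the bundled `stopping_bias`
scenario (activities 0.9/0.1, at most 30% active, N = 40), nearly all
quiescence-stopped runs are *not* at the IFD, while under `true_ifd`
stopping the false-stop fraction is exactly zero by construction.

`max_steps` (default 10^6) and `max_time` (default 10^5) are safeguards
far beyond observed stopping times at these scales; hitting them yields
`stop_reason = "max_bound"`, recorded rather than thrown.

## Changing environments and robust deviation measures

With `env_change_period = T > 0` (discrete scheduler), the quality
vector changes every `T` steps — `permute` shuffles the existing
qualities (conserving the total input), `redraw` re-samples them. The
change is applied at the start of the step, before that step's movement
decision; any fixed ordering would do, this one is documented and
tested. When the environment keeps moving, a "time to reach the IFD" is
not well defined — movement can never settle if qualities reshuffle
every 10–20 steps — so the harness reports state metrics instead:

* `intake_variance()` — the population variance of realised per-capita
  intakes, by default over occupied patches, unweighted. Empty patches
  have no realised intake; both the patch set (`occupied`/`all`) and the
  weighting (`patch`/`individual`) are configurable because the phrase
  "across patches" is genuinely ambiguous. Zero variance characterises
  type-I input matching.
* `matching_slope()` — the OLS slope of `log n_p` on `log Q_p` over
  occupied patches (natural logs; empty patches are excluded because
  `log 0` is undefined). Slope 1 is input matching, slope < 1 is
  undermatching. No canonical undermatching statistic exists for this
  model; the log-log slope is the conventional matching-law stand-in
  and is labelled as such. At small `N`, integer granularity alone
  produces slopes below 1 (undermatching-by-discreteness), which is
  reported, not asserted, by the tooling.

## What the generator emulates — and what it does not

`generate_landscape()` draws qualities i.i.d. uniform on [1, 10] on a
7×7 grid; `place_population()` supports uniform-random placement
(default), one-per-patch (the very-low-density regime), and
single-patch starts. The activity mixture is deterministic:
`round(proportion_active * N)` consumers get `activity_high`, the rest
`activity_low`, so "proportion" means exactly what it says rather than
a binomial draw. The standard scenarios use activities 0.8/0.2
(mixture and population-size experiments) and 0.9/0.1 (stopping-bias
experiment), `N = 40` unless the experiment varies it, and 49 patches.

These synthetic worlds deliberately omit much of real foraging:
resources do not deplete between scheduled changes, consumers are
identical apart from activity (no size, competitive-ability, or
energetic differences), information is perfect and free, movement is
instantaneous and costless, and there is no mortality, interference
beyond sharing, or space. Passing tests therefore certify the *model's*
internal logic — consistency of the intake comparison, exactness of the
stopping rule, the time-scale artefact — not that any of these patterns
will hold quantitatively in field data.

## Reproducibility and numerical choices

Every run is driven by a single integer seed; sweeps derive one child
seed per (cell, replicate) with `child_seed()`, a counter-based Lehmer
hash modulo 2^31 − 1, so replicates are independent streams and any run
can be replayed in isolation. No code path ever seeds from the clock.
Floating-point intake comparisons use exact `>` / `>=`; with continuous
qualities ties occur only through genuinely equal ratios, which both
response types preserve, so seed-matched equivalence holds bit-for-bit.

Problem sizes in the shipped tests are the package's own desk-scale
choices: 100 seed-matched instance pairs for the equivalence check,
exhaustive enumeration up to 3 patches × 6 consumers against the
brute-force oracle, 1000 replayed runs for potential monotonicity,
200 replicates per mixture level (100 in the acceptance script) for the
slowdown and stopping-bias scenarios, and 100 replicates per population
size for the large-`N` comparison — versus 1000 replicates per setting
for publication-scale figures, which `run_sweep(replicates = 1000)`
reproduces unchanged.

## A worked sweep

```{r}
preset <- sweep_preset("activity_mixture", replicates = 20)
batch <- do.call(run_sweep, c(preset, list(master_seed = 41)))
batch$summary[, c("proportion_active", "scheduler", "mean_time_to_ifd",
                  "proportion_true_ifd", "max_max_moves")]
```

The mean time to the IFD falls as the share of active consumers rises,
under both clocks; every run ends at a certified IFD and no consumer
moves twice.

## Known limitations

* Quiescence stopping and environmental change are defined for the
  discrete scheduler only; in continuous time "50 steps of stillness"
  has no natural analogue, and the exact predicate makes it unnecessary.
* `enumerate_equilibria()` is guarded to `P ≤ 6`, `N ≤ 12`; it is a
  testing oracle, not a production equilibrium solver.
* The event-based scheduler keeps `Λ` constant (activities are fixed
  traits); time-varying activities or birth–death events would require
  rate recomputation that is out of scope.
* No claim of bit-compatibility with any other implementation's tie
  handling or consumer-selection order is made; this package documents
  its own conventions and tests against independent oracles.
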