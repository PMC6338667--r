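---
title: "How a traffic rule evolves before the communication system it regulates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How a traffic rule evolves before the communication system it regulates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(swarmevol)
```

## The system

`swarmevol` models a clonal swarm of disk-shaped robots foraging between a
nest and a food source in a walled rectangular arena, and the evolution of
two kinds of traits on top of that behavior:

* a **core component** — trail-pheromone communication.  A robot that finds
  food carries it home while secreting a chemical on the ground; if the
  swarm can detect that chemical (locus $p = 1$), other robots are recruited
  onto the trail and guided to the food.
* a **regulatory component** — a traffic rule.  When two robots collide,
  each reacts by either *Stay* (halt for a fixed time) or *Leave* (back up a
  fixed distance).  Which reaction a robot takes is set by the locus
  matching its current behavioral state: $b_1$ while searching ($S_1$),
  $b_2$ while carrying food inbound ($S_2$), $b_3$ while following the trail
  outbound ($S_3$).  With $b_2 = 0$ and $b_3 = 1$, outbound robots yield to
  inbound ones — a priority rule that prevents the trail from jamming.

A genome is the 4-bit vector $\{b_1, b_2, b_3; p\}$, written
`"{1,0,1;1}"`.  Swarm fitness is the number of completed foraging bouts
(food deliveries) in one trial.  The package asks, and answers, the
question: when a population of swarms evolves from `{0,0,0;0}` to the best
genotype `{1,0,1;1}`, does the regulatory allele $b_3 = 1$ (useless without
communication) arise before or after the core allele $p = 1$?

Because $S_3$ is unreachable when $p = 0$, the allele at $b_3$ is exactly
neutral on a $p = 0$ background — the simulator guarantees this bit-exactly,
and the test suite asserts it.  That neutrality is what makes stochastic
tunneling through `{1,0,1;0}` possible.

## The embodied layer

One trial (`simulate_trial()`) advances all robots synchronously in 0.1 s
ticks.  Per tick: motion (a correlated random walk for searchers with
reflective walls, beacon homing for carriers, two-sensor trail taxis for
followers), pairwise collision detection with Stay/Leave reactions and
iterated symmetric separation of overlapping bodies, a pheromone-field
update (deposits into 30 mm cells, multiplicative evaporation, conservative
4-neighbour diffusion), and the state transitions.  All randomness comes
from per-robot counter-seeded xoshiro256++ streams derived from the trial
seed, so a trial is bit-reproducible from `(genotype, config, seed)` and
prefix-stable in the number of steps.

Parameters the original description leaves open are explicit configuration
with the following defaults, chosen once:

* **Pheromone numerics** (cell 30 mm, deposit 3 per step, retention 0.997
  per step, diffusion 0.05, detection threshold 0.05): an unreinforced
  passage decays below the detection threshold in roughly 1–2 simulated
  minutes, so trails are usable but transient.
* **Follow hysteresis** (`follow_threshold = 0.01`): a robot is recruited
  only at the detection threshold, but once committed keeps tracking the
  trail down to a five-times-weaker signal.  Without hysteresis, followers
  reliably lose the aging food-end of the trail (which was laid earliest)
  and recruitment never pays its cost.
* **Controller noise** (searching 0.4 rad/step, steering 0.1 rad/step,
  applied also while reversing): embodied controllers are noisy, and the
  noise is functionally important — with exact deterministic steering both
  traffic streams collapse onto the same one-dimensional lane and head-on
  encounters deadlock.
* **Outbound orientation of followers**: a recruited robot is outbound by
  definition, so the $S_3$ controller uses the globally visible nest beacon
  to keep its heading pointed away from the nest while the two trail
  sensors handle lateral tracking.
* **Stay 1.5 s, Leave 150 mm (one body length)**: the halt and the detour
  cost comparable time at cruise speed, which reproduces the reported
  fitness ordering of the collision alleles.

The desk-scale study condition (`reduced_arena_config()`) shortens the
arena to 900 × 6000 mm and trials to 6000 steps (10 simulated minutes) with
the same 30 robots.  The swarm then covers 9.8% of the arena area versus
6.5% at full scale, keeping the collision regime comparable while an
individual trial runs in well under a second.  Shorter arenas were rejected:
at 900 × 3000 mm the density triples, collisions dominate all behavior, and
random search becomes so efficient relative to the food-light radius that
recruitment cannot beat it.

What desk-scale trials do *not* show: absolute bout counts and collision
counts are not comparable with the full-scale system, and the fitness
valley of `{1,0,0;1}` as well as the advantage of `{1,0,1;1}` are milder
than at full scale.  All downstream conclusions are therefore about
orderings and mechanisms, not about absolute fitness values.

## Mapping the landscape

```{r}
land <- fitness_landscape(200, reduced_arena_config(), seed = 1)
land$summary[order(-land$summary$mean_bouts), ][1:5, ]
```

Four features of the summary carry the whole story: `{1,0,1;1}` attains the
highest mean fitness of the 16 genotypes; `{1,0,0;0}` (Leave while
searching, no communication) beats the ancestor `{0,0,0;0}`; the
pheromone-without-rule genotype `{1,0,0;1}` sits *below* `{1,0,0;0}` — the
fitness valley caused by overcrowding on the trail — and its mean collision
count is roughly double that of `{1,0,1;1}`.  Every genotype pair differing
only at $b_3$ with $p = 0$ has bit-identical samples because the landscape
shares one per-trial seed stream across genotypes.

## The evolutionary layer

`run_evolution()` iterates a Wright–Fisher population of $N = 200$
non-interacting clonal swarms: every offspring swarm picks a parent with
probability proportional to the parent's *realized* fitness, then each of
its four loci flips with probability $\mu = 0.001$.  Fitness is redrawn for
every swarm every generation — one foraging trial's worth of noise — via a
fitness provider; the surrogate provider resamples the stored per-genotype
landscape samples, which keeps a 50-replicate experiment in seconds while
preserving exactly the fitness noise the embodied layer produces.  The full
parent map is retained, so the genealogy of the fixed genotype can be
traced back to generation 0 and classified (`classify_genealogy()`):
`b3_first` if, after the lineage first carries `{1,0,0;0}`, the first
$0 \to 1$ mutation at $b_3$ strictly precedes the one at $p$ and the
lineage only visits shortest-path genotypes; `p_first` symmetrically;
anything else `irregular`.

Under the study conditions, all 50 replicates fix `{1,0,1;1}` within a few
hundred generations; about 43 of 50 classify `b3_first` and $b_3$ precedes
$p$ on 45–50 of the focal genealogies — the regulatory allele almost always
arrives first, riding neutrally until $p = 1$ turns it into a traffic rule.

One reported feature does **not** reproduce at desk scale.  In the original
full-scale system, every run had the resident `{1,0,0;0}` at frequency
$\ge 0.985$ before the focal lineage's $b_3/p$ mutations arose.  In the
desk-scale landscape the genotype `{0,0,1;1}` (traffic rule without
searcher-Leave) is nearly as fit as the resident, so in roughly a third of
the replicates the winning lineage acquires $b_3$ *before* $b_1$ and
crosses the valley via `{0,0,1;0}` → `{0,0,1;1}` while the resident is
still sweeping; the minimum resident peak across 50 runs is then near 0
rather than 0.985.  This is a genuine consequence of the desk-scale
landscape (the $b_1$ advantage is compressed more than the recruitment
advantage), not of the evolutionary machinery; configurations that restored
a large $b_1$ advantage destroyed either the global maximum or the mildness
of the valley and were rejected.  The corresponding acceptance check is
expected to fail at desk scale and is left failing.

## The analytical layer

The waiting time for the two-step transition resident → intermediate →
final is computed from the standard stochastic-tunneling description: with
$T$ the tunneling rate, $S_1, S_2$ the sequential fixation rates,

$$E[t] = \frac{T}{(T+S_1)^2} + \frac{S_1\,(S_1+S_2+T)}{S_2\,(T+S_1)^2},$$

whose $T \to 0$ limit is the pure sequential time $1/S_1 + 1/S_2$.  The
components are deliberately *exact* finite-$N$ quantities rather than the
usual infinite-population approximations:

* `fixation_probability(r, N)` solves the absorbing Wright–Fisher chain of
  the mutant count (binomial updates with success probability
  $ir/(ir+N-i)$) by a dense linear solve; the neutral value is $1/N$
  exactly.  The Moran closed form $(1-1/r)/(1-1/r^N)$ was rejected: the
  evolutionary layer is Wright–Fisher, and the Moran form understates
  fixation of beneficial mutants by about a factor of two.
* the tunnel itself is an absorbing chain over the intermediate copy
  number $k$, in which each offspring launches an ultimately-fixing final
  lineage with hazard $p_k\,\mu\,U(a)$.  Solving it yields $\sigma_1$ (a
  successful launch before loss or fixation) and $u_1$ (fixation with no
  launch), from which $T = N\mu\sigma_1$, $S_1 = N\mu u_1$ and
  $v_1 = 1 - \sigma_1/(1-u_1)$, so the printed factorization
  $T = N\mu(1-U)(1-v_1)$ holds identically.  A branching-process fixed
  point was implemented first and rejected: at $N = 10$–$50$ a
  conditionally surviving neutral lineage grows to a size comparable with
  $N$, and the infinite-population approximation is 15–40% off.
* $S_2 = N\mu\,U(a/r_x)$ uses fitness relative to the new resident.

The binding correctness check is `simulate_two_step()`, a brute-force
Wright–Fisher simulation of the same three-type process.  It reports both
the *fixation* generation and the *seeding* generation of the winning
intermediate clan (mid-generation convention for the mutation event).  The
analytic rates clock ultimately-successful seedings, so $E[t]$ is compared
against the seeding time; across the grid
$N \in \{10, 50\} \times \mu \in \{0.005, 0.01\} \times r_x \in \{0.5, 1\}
\times a \in \{2, 5\}$ the agreement is within 10% (worst point ≈ 9%).
The gap between seeding and fixation — maturation of the tunneling lineage
plus the final sweep — is excluded from the rate description by
construction and reaches half the total time at $N = 50,\ \mu = 0.01$; no
choice of components can make the printed formula match *fixation* times
there.

`predict_outcome_sets()` is the hybrid analysis: triples
$(r_0, r_-, a)$ of relative fitness are drawn from bootstrap distributions
of resampled mean ratios (`relative_fitness()`, resampling with
replacement, ratio of resampled means — the simplest scheme consistent
with a resampled relative-mean-fitness distribution), $E[t]$ is evaluated
for the neutral-intermediate and inferior-intermediate paths, and the
shorter-time path is recorded (exact ties, a measure-zero event, go to the
neutral path and are counted).  Per-set counts and mean waiting times are
summarized by 2.5th/97.5th percentiles across sets.  With desk-scale
inputs the neutral-intermediate path dominates essentially every outcome,
because the desk-scale valley ($r_- \approx 0.6$) is far deeper relative
to the bootstrap noise than the full-scale one.

## Numerical and degenerate-input policy

* All probabilities are clamped to $[0,1]$ after linear solves;
  $E[t]$ evaluation errors out at $\mu = 0$ instead of returning NaN.
* Non-positive bootstrap draws in the hybrid analysis are rejected and
  redrawn, with a count reported.
* Zero-fitness generations in the Wright–Fisher layer fall back to uniform
  parent choice and are flagged on the run.
* A world state is fully serializable; editing it directly (placing robots
  by hand) and stepping it is the supported way to construct scenarios,
  and `n_steps = 0` trials are legal.
* In `expected_time_vec` (the vectorized hybrid-analysis path) the exact
  tunnel chain is solved per distinct parameter pair when there are few,
  and interpolated bilinearly on a $(\log r, \rho)$ grid otherwise.

## Problem sizes

The shipped analyses use: 200 trials per genotype for the desk-scale
landscape, 50 evolutionary replicates at $N = 200$, $\mu = 0.001$, 20,000
replicates per point for the two-step oracle grid, and 1000 sets × 50
outcomes with 4000–10,000 bootstrap draws for the hybrid analysis.  These
sizes keep the full reproduction on one CPU core in the tens of minutes;
they are package choices, and all of them scale up by changing one
argument.

## Known limitations

* Desk-scale fitness values are not the full-scale ones; only orderings
  and mechanisms transfer (see above for the one reported quantity that
  does not).
* The collision model is rigid-disk contact with iterated positional
  separation; there is no rotational dynamics, friction or sensor
  occlusion.
* The pheromone field is a coarse grid, not a continuous plume; trail
  width is set by the cell size and diffusion.
* The analytic layer assumes one-directional mutation and at most one
  intermediate class per path; back mutation and the other twelve
  genotypes exist only in the simulation layers.
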