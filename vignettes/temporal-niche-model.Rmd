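---
title: "An agent-based model of temporal niche competition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of temporal niche competition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chrononiche)
```

## The model

`chrononiche` simulates a community of one or two species of organisms
competing for limited resources in an environment of 60 spaces. Time is
circular: one simulated day is 360 degrees (1 h = 15 degrees) and is
advanced in 10 equal steps. Each day, 600 resources are added to uniformly
random spaces at a constant rate (60 per step).

Each organism carries two heritable rhythm traits: an **amplitude**
$A \in [0, 1]$ and a **phase angle** $\varphi \in [0^\circ, 360^\circ)$. Its
movement follows the cosine activity profile

$$m(t_0, t_1) = \int_{t_0}^{t_1} \frac{M_{total}}{360^\circ}
  \bigl(1 + A\cos(t - \varphi)\bigr)\,dt,$$

with the total fixed at $M_{total} = 20$ moves per day regardless of the
rhythm parameters, so the *timing* of activity is the only variable under
selection. A move jumps to one of the 59 other spaces uniformly at random;
landing on a space with a resource consumes one resource. Metabolism costs a
flat 2 energy per day; a consumed resource yields a baseline 0.5 energy.
Organisms die when their energy reaches zero or at 12 days of age.

Reproduction is sexual and energy-proportional: parents are drawn with
probability proportional to stored energy, each donates one third of its
energy to the single offspring, and matings occur at a rate that would grow
the population 10% per day if nothing died. With **stabilization** on, the
per-species rate is adjusted by $r_{adj} = r\,k\,P_{total}/p$ toward a
target community fraction $k$. When traits evolve, the offspring amplitude
is the parents' mean $\pm$ Normal(0, `amp_sd`) (clamped to $[0,1]$) and the
offspring phase is the parents' circular mean $\pm$ Normal(0,
`phase_sd_frac` $\times 360^\circ$).

Two optional layers complete the model:

* **Specialization** $S$: energy per resource becomes
  $E_{orig}(1 + S\cos(t-\varphi))$, i.e. foraging is more efficient at the
  circadian peak and less at the trough (at $S = 0.2$, 20% more and 20%
  less). The specialization wave shares the activity phase.
* **Assortative mating**: mating requires overlapping 135-degree (9-h)
  mating windows fixed relative to each phase angle; the pairing weight is
  energy times window overlap, which falls linearly to zero at a
  135-degree phase difference.

Reproductive segregation is summarized by the **cross-group mating (CGM)**
statistic: 2-means clustering of the rows of the pairwise mating-window
overlap matrix splits the population in two; CGM is the mean overlap across
the split (0 = complete reproductive isolation, 1 = one panmictic clump).

## What the scenarios show

```{r, eval = FALSE}
rec <- run_trial(build_scenario("character_displacement"), seed = 1)
mean(tail(phase_difference_series(rec), 200))
```

* `exclusion_arrhythmic` / `exclusion_inphase`: two species in an identical
  temporal niche; one is always competitively excluded.
* `coexist_antiphase`: antiphase rhythms partition the day and the pair
  coexists indefinitely.
* `character_displacement`: phases free to evolve from a shared starting
  value diverge to an antiphase equilibrium (about 180 degrees apart) and
  stay there.
* `single_species`: intraspecific competition flattens amplitude unless
  specialization is strong; around $S = 0.75$ (a sevenfold peak-to-trough
  efficiency ratio) high amplitude is maintained.
* `two_species`: with a competitor and a small specialization, amplitudes
  rise; the minority species (mostly facing interspecific competition)
  becomes more rhythmic than the majority (mostly facing itself).
* `speciation`: under assortative mating a single population can split into
  two reproductively isolated groups; whether it splits or instead goes
  arrhythmic depends on the relative flexibility (mutation SD) of phase
  versus amplitude.

## Design choices

**Event order within a step.** Resources are added, organisms move and
forage in freshly shuffled order, flat metabolism is charged, energy-dead
organisms are removed, matings occur, and at the day boundary everyone ages
and age-dead organisms are removed before the daily record. Feeding before
charging is conservative; newborns join after the mating phase and cannot
forage or be selected until the next step. All moves of a step forage at the
step's midpoint time (the model integrates movement over the step but
defines no within-step event times).

**Stochastic mating stream.** Matings are described as pairs chosen at a
constant rate throughout the day, so the engine draws the per-step mating
count as Poisson with the expected-progeny mean $p\,r_{adj}\,\Delta t /
360^\circ$. This demographic birth noise matters: with a deterministic
birth ledger (available as `poisson_births = FALSE`), two identical
arrhythmic species are a nearly noise-free martingale in relative abundance
and coexist long past 2000 days, while the Poisson stream reproduces the
reliable competitive exclusion the model is built to show. The
deterministic ledger remains useful for exact bookkeeping demonstrations.

**Fractional moves and births.** Expected moves per step are generally
non-integer; each organism carries a fractional move credit and realizes
`floor(credit + expected)` moves (floor-with-carry). A `1e-9` snap inside
the floor keeps exact-integer daily totals (20 moves from zero starting
credit) from losing a move to the last ulp of float accumulation; away from
integer boundaries the carry is conserved exactly.

**Circular arithmetic.** Angles are degrees everywhere, converted to
radians only inside trig calls; `sinpi`/`cospi` keep quarter-cycle values
exact. The circular mean of an antipodal parent pair (resultant length
below $10^{-9}$) picks one parent's phase at random — any deterministic
tie-break would bias phase evolution. The circular SD
$\sqrt{-2\ln\bar R}$ is capped at the value for $\bar R = 10^{-12}$
(about 425.9 degrees). Amplitude mutations clamp at the $[0,1]$ boundary
rather than redraw, accepting a slight boundary bias in exchange for an
unchanged mutation kernel.

**CGM details.** Lloyd's algorithm runs on the $n$-dimensional rows of the
overlap matrix with Euclidean distance, 10 seeded restarts, a 300-iteration
cap, and a $10^{-6}$ centroid-shift tolerance; the best within-cluster sum
of squares wins. If a cluster empties, the point farthest from the
surviving centroid is moved into it, which keeps the statistic defined for
a single identical-phase clump (every split of an all-ones overlap matrix
gives CGM 1). CGM is computed once per day on the full living population;
with fewer than two organisms it is a missing value, never an error. The
suite cross-checks this implementation against `stats::kmeans` and, for
$n \le 12$, against exhaustive enumeration of all bipartitions.

**Initial conditions.** Two-species scenarios start with 75 organisms each
(150 for one species), energy 2.0 (one day's cost), ages uniform on 0–11
days, zero move credit, uniform random positions, and traits at the
scenario's exact initial values (optionally Normal-spread phases via
`init_phase_sd`). Scenarios with evolving amplitude start at the neutral
midpoint 0.5 unless the design fixes amplitude at 1. One RNG stream drives
every stochastic draw of a trial, so a `(config, seed)` pair reproduces a
trial bit-for-bit.

## Problem sizes and convergence

Trials default to the 2000-day horizon used by the preset experiments; the
package's own test suite runs 10-trial batches for the exclusion /
coexistence split, one 2000-day trial for character displacement, 5 trials
per corner of the speciation trait-flexibility grid, 5 seeds per
population-ratio treatment, and 10 trials per specialization level. The
rise of amplitude under $S = 0.75$ from the 0.5 midpoint is slow; that
check runs to its equilibrium at 4000 days (runs started at amplitude 1
settle onto the same ~0.85 equilibrium from above). The batch runner seeds
trial $i$ with `base_seed + i - 1`, so results are independent of
scheduling and recomputable per trial.

## What the model does not capture

Movement is spatially unstructured (uniform jumps, no territories or
adjacency), competition is purely exploitative (no interference costs),
activity profiles are strictly sinusoidal with a fixed daily total, and
inheritance is phenotypic — a polygenic stand-in with a constant mutation
kernel, not an allele-level model. Activity timing is purely genetic:
organisms cannot behaviorally shift their day. Synthetic fixture
populations built by `generate_fixture_population()` exercise the metrics
layer with known mixtures; passing those tests validates the statistics,
not the realism of any particular field system. Quantitative equilibria
(e.g. the exact majority-species amplitude under asymmetric ratios) depend
on the unreported specialization strength behind the asymmetric-ratio
experiments; the package adopts $S = 0.2$ and treats the ordinal ordering —
minority amplitude above majority, and the more dominant the majority the
flatter its rhythm — as the robust prediction.
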