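# chrononiche

An individual-based simulation of how competition for resources shapes
biological rhythms. One or two species of organisms forage on a 60-space
grid that receives 600 resources per day; each organism moves according to
a cosine circadian activity profile with two heritable traits, an amplitude
*A* ∈ [0, 1] and a phase angle φ (360° = 24 h), while its daily total of 20
moves stays fixed. Energy from consumed resources drives survival and
energy-proportional sexual reproduction, so natural selection acts on
*when* organisms are active. The package is for ecological and evolutionary
modellers studying temporal niches: competitive exclusion and coexistence,
character displacement of circadian phase, niche expansion through
arrhythmicity, the evolution of rhythm amplitude under time-of-day
specialization, and allochronic (breeding-time) population splitting under
phase-assortative mating.

## Model core

Movement between times *t₀* and *t₁* follows

```
m = ∫ (M_total / 360°) (1 + A cos(t − φ)) dt,   M_total = 20 moves/day
```

advanced in 10 steps per day. Organisms spend 2 energy/day, gain 0.5 energy
per resource — scaled by a specialization factor (1 + S cos(t − φ)) when
*S* > 0 — and die at zero energy or 12 days of age. Matings arrive as a
constant-rate stream; with stabilization the per-species growth rate is
`r_adj = r · k · P_total / p` around a target community fraction *k*.
Offspring traits are the parents' (circular) means plus Normal mutation
noise. Under assortative mating, pairs form in proportion to the overlap of
their 135° (9-h) mating windows, and reproductive segregation is tracked by
the cross-group mating statistic (CGM): 2-means clustering of the
mating-window overlap matrix, with CGM the mean overlap across the split
(0 = complete reproductive isolation).

## Worked example

Two species start fully rhythmic at the *same* phase; phases evolve
(mutation SD 0.04 × 360°) while amplitude stays at 1:

```r
library(chrononiche)
cfg <- build_scenario("character_displacement", horizon_days = 600)
rec <- run_trial(cfg, seed = 42)
rec
#> <trial_record> seed 42, 600 days, 2 species
#>   final populations: 64, 59
#>   final mean amplitudes: 1, 1

pd <- phase_difference_series(rec)
round(pd[c(1, 101, 301, 601)], 1)   # days 0, 100, 300, 600
#> [1]   0.0  19.9 165.7 179.4
```

The mean phase difference climbs from 0° to ~180°: the two species displace
each other to opposite times of day and hold the antiphase arrangement.
With identical niches instead, one species is always excluded:

```r
b <- run_batch(build_scenario("exclusion_arrhythmic"), n_trials = 5,
               base_seed = 1)
b
#> <batch_summary> 5 trials (base seed 1)
#>   all species survived: 0%; excluded: 100%; speciated: 0%
b$aggregates$median_exclusion_day
#> [1] 359
```

And the CGM statistic recognizes a phase-split population:

```r
cgm(c(rep(20, 8), rep(200, 7)), seed = 1)   # two clumps 180 deg apart
#> [1] 0
```

`write_outputs(rec, "out/")` exports tidy CSV time series (one row per day
× species) plus a JSON sidecar with events, the seed, and a config hash;
`inst/scripts/simulate.R` wraps the same presets for shell use.

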