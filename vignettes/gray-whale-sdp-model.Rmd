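---
title: "A state-dependent life-history model of pregnant gray whales under acoustic disturbance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A state-dependent life-history model of pregnant gray whales under acoustic disturbance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(graywhaleSDP)
```

## The problem

Western gray whales are capital breeders: a pregnant female must acquire,
during a single summer-fall foraging season off northeast Sakhalin, the
energy that will carry her through migration, gestation and most of
lactation. The foraging grounds are two small areas — a nearshore strip
(model cells 1-7, of which the coastal cells 1, 3, 5 and 7 are monitored by
shore stations) and a richer offshore area (cells 8-11) — that in 2015
overlapped active seismic surveys. The package implements a stochastic
dynamic programming (SDP) model of one pregnant female's season, a forward
Monte-Carlo simulation of populations with and without acoustic
disturbance, and the statistical machinery used to compare such model
output with shore-based field data, in the tradition of the population
consequences of disturbance (PCoD) framework.

## Female and fetus state

A female is described by her body length $L$ (m, fixed for the season), fat
mass $F$ (kg), fetal length $G$ (m), and location (a feeding cell, or
outside the study area). Total body mass is a configured power law
$M(L) = a L^b$ (default $15.1\,L^3$ kg, about 31 t at the 12.7 m mean
length). Two length-specific quantities anchor the state space:

* **starvation floor** — a female dies if fat falls below 5% of $M(L)$;
* **storage capacity** — fat is capped at 45% of $M(L)$; surplus beyond the
  cap is discarded (free disposal).

Each 6-h bin a female pays a metabolic cost (default
$0.586\,M^{0.75}$ MJ/day, twice the Kleiber basal coefficient, spread over
four bins), a travel cost when she moves (16 MJ/km at the 4.5 km/h
reference speed, path length inflated by the inverse of a drawn linearity),
and the cost of scheduled fetal growth. The fetus grows 8 mm/day; fetal
mass is $9.45\,G^3$ kg and new tissue costs 20 MJ/kg (tissue energy plus
the heat of gestation). Allocation is prioritized: intake covers current
metabolism, travel and fetal growth first; a surplus is stored as fat at
90% efficiency and 39.3 MJ/kg; under a deficit, fetal growth drops to half
its scheduled rate and the shortfall is catabolised from fat at 39.3 MJ/kg.
The per-bin budget identity (intake − costs − fat flux = 0 away from the
storage cap) is asserted to $10^{-9}$ MJ in the test suite.

These cost schedules are configuration (`bioenergetics_params()`), chosen
to be of plausible magnitude for an adult gray whale; all structural tests
(conservation, monotonicity, orderings) are parameterization-robust.

## Terminal fitness

Reproductive success — carrying the fetus to term and weaning the calf back
on the foraging grounds — is evaluated at departure as the product of three
scaled logistic components in the departure state: overwinter maternal
survival in the fat fraction $F/M$ (midpoint 0.12, steepness 40; also
exposed as `survival_to_next_season()`), calf survival by maternal
condition (midpoint 0.20, steepness 25; asymptote 0.60 / 0.75 / 0.90 for
the low / medium / high variants), and calf survival by fetal length
(steepness 6 per m; midpoint 1.5 / 1.3 / 1.1 m). Holding the steepness of
the fetal component common across variants makes the three variants ordered
pointwise (low ≤ medium ≤ high), which the tests assert on a dense grid. A
female with no fetus has fitness zero, and departure time influences
fitness only through the state reached at departure — there is no separate
time penalty.

One design note: the survival component appears exactly once. The leave
action, the terminal values and the reproduction Bernoulli all use
`reproductive_fitness()`, which already contains overwinter survival;
multiplying by `survival_to_next_season()` again would square it.

## Backward iteration

Decisions are daily; within a day, a female's behavior probability
distribution governs each of the four 6-h bins. The four actions are leave
(absorbing; locks in the fitness of the current state), feed here, travel
within the cell (half a foraging bout plus a short travel cost), and travel
to any other cell (no foraging that day, distance-based cost). Prey energy
per 6-h bout is lognormal per cell and season period (early/mid/late thirds
of the 25-week season), discretized into $K$ equally spaced categories; the
category is redrawn independently each day, so the stored value surface
$\bar V(t, \mathrm{cell}, F, G)$ is the expectation over categories. Future
values are discounted by daily background survival (2%/yr annual mortality
converted per bin). Backward iteration runs from the terminal day (every
remaining female departs) to the season start over a uniform fat × fetal
grid, solved separately on a small grid of body lengths spanning
$[L_{\min}, 14]$ m; simulation uses the nearest solved length.

### From values to behavior probabilities

How optimal values become behavior *probabilities* is genuinely open; two
rules are implemented:

* `rule = "argmax"` — deterministic optimum, ties shared uniformly within
  `epsilon`. Under this rule the value recursion is the classical Bellman
  maximum, and the package's backward iteration is checked to $10^{-10}$
  against brute-force enumeration of all action sequences and prey-category
  outcomes on randomized toy instances whose energy ledger moves in exact
  grid units (no interpolation error by construction).
* `rule = "softmax"` (scenario default) — action probabilities proportional
  to $\exp(Q_a/\tau)$ and $\bar V = \sum_a \pi_a Q_a$, i.e. the value the
  stochastic agent actually achieves. The default temperature
  $\tau = 3\times10^{-4}$ sits well below the ~$3\times10^{-3}$ per-day
  fitness increment of a good foraging day, so clearly different actions
  are separated sharply while near-equivalent cells share probability. (A
  much hotter temperature makes the recursion model a near-random agent
  whose value collapses; a colder one degenerates to argmax and the
  population piles onto single cells.)

A noteworthy emergent property of the softmax recursion: a cell whose
alternatives are all clearly inferior keeps a slightly higher value than an
equally rich cell surrounded by near-equivalent options, because the
stochastic agent wastes fewer bouts there. Under the default prey gradient
this only adds a small extra pull toward the richest cell.

### Numerical choices

The default grid is 36 fat × 12 fetal nodes, bilinear interpolation, with
policies solved at 4 lengths. The absolute level of $\bar V$ converges
slowly along the fetal axis (piecewise-linear interpolation of the logistic
fetal component is re-applied along the 8 mm/day characteristic for 175
days, giving a smooth common downward shift at coarse resolution), but the
shift is nearly independent of the action and therefore leaves behavior and
simulated outcomes unchanged: the test suite doubles the grid and requires
seasonal reproduction to move by less than 1% (it moves by far less).
States below the starvation floor carry value zero; dead and departed are
absorbing. Behavior probabilities for a continuous state are computed at
the four surrounding grid nodes and blended bilinearly, renormalized;
states outside the hull are clamped with a warning.

## Forward simulation

`simulate_population()` propagates `n_rep` population replicates of `n_pop`
pregnant females. Per female: length from the truncated normal
(12.7 ± 0.6 m on $[L_{\min}, 14]$), starting fat fraction
(0.25 ± 0.03 of $M$), starting fetal length (0.35 ± 0.05 m), arrival day
(June 15 ± 5 d), and a coastal entry cell. Each 6-h bin while in-area she
may first be disturbed (below); otherwise she draws an action from the
governing day's probabilities at her current state and prey category, with
per-bin draws of dive fraction (0.70 ± 0.05), travel speed (4.5 ± 1 km/h)
and path linearity (0.8 ± 0.1) modulating intake and travel cost; energy is
updated through the allocation rule; background mortality is applied.
Occupancy is recorded after the bin's action; weekly pooling averages the
28 bins of each week within a replicate. Dead females count as outside
from their death bin, keeping nearshore/offshore/outside an exact partition.

Every random stream is indexed by (replicate, day, bin, female) rather than
consumed sequentially, so disturbed and undisturbed runs under one seed are
*coupled*: with zero exposure they are bit-identical, which makes Cohen's d
comparisons a paired design and is asserted exactly in the tests.

## Acoustic disturbance

`exposure_probability()` reduces a block-level SPL grid (1 km² blocks
nearshore, 100 km² offshore; windows of 5 min or coarser) to the
per-cell, per-6-h-bin probability of exposure at or above 163 dB re 1 µPa²
SPL: a block is disturbed in a bin if *any* of its windows reaches the
threshold (inclusive at exactly 163.0), and the cell probability is the
disturbed fraction of blocks with data. A responding whale (response
probability 1 by default; 0.1 mirrors the originating behavioral-response
study) relocates to the first cell in her cell's neighbor order with zero
exposure — cells 8 and 9 are each other's first neighbor — pays the travel
cost, and loses the bin's foraging. Relocation happens at most once per bin.

## Synthetic study conditions

The generators in `scenario_truth()` stand in for the unavailable 2015
field and acoustic data and define the default study conditions:

* **Prey** (MJ per 6-h bout, early/mid/late): coastal nearshore 500/340/240
  (cell 3, the Piltun mouth, 560/380/270), seaward nearshore 430/300/220,
  offshore rising from 1450/1550/1600 (cell 8) to 1650/1750/1850 (cell 11,
  the richest); $\sigma_{\log}$ 0.35 nearshore, 0.30 offshore. Nearshore
  thus starts near energetic break-even and declines; offshore exceeds the
  nearshore mean roughly sevenfold late in the season.
* **Seismic survey**: a source at 240 dB re 1 µPa² at 1 m with
  $20\log_{10}(r)$ spreading (163 dB footprint ≈ 7 km) tracks the
  nearshore strip in weeks 5-8 and loiters near cells 8-9 in weeks 9-14,
  emitting windows during two bins per day.
* **Regressions**: true coefficient vectors for the zero-inflated beta
  photo-ID model, the per-cell hurdle-gamma density model (coverage raises
  the hurdle probability), and the logistic pregnant-fraction model (a
  U-shaped week² term), on a fixed standardized-week scale.
* **Roster**: 27 reproductive females calving with probability 0.35 in any
  year not following a calf year, enforcing the two-year inter-birth
  interval.

What the generators do *not* emulate: within-cell spatial structure and
seasonal prey patches (the real data show, e.g., a transient sand-lance
patch in cell 7 that a cell × period lognormal cannot carry), sighting
geometry and detection (detection probability is fixed at 1), identity
resolution in photo-ID, vessel and pile-driving sound, and any multi-year
carryover. Passing tests therefore certify the pipeline's internal
consistency and statistical calibration under the assumed structure, not
fidelity to the 2015 field season.

## Field-comparison statistics

The daily proportion of a pregnant-female group seen nearshore is modeled
with a zero-inflated beta likelihood (support $[0,1)$; mean-precision
parameterization, logit links for the nonzero probability and the beta
mean, constant precision). Scan-survey block densities aggregate to cell
densities by count over covered area and feed per-cell hurdle-gamma fits
(mean-shape parameterization; week polynomial and coverage in the hurdle;
sparse cells drop to a single week term). The pregnant fraction among
identified whales is a binomial-logit regression. All three are fitted by
an adaptive random-walk Metropolis sampler initialised at the posterior
mode with a Hessian-based proposal, flat priors inside a wide box (a
warning reports any posterior mass near the box), and split-$\hat R$
diagnostics. Simulation-based calibration in the acceptance suite requires
the 90% credible intervals to cover every generating coefficient in at
least 80% of 50 repetitions per family. Predictions at "ideal conditions"
use Beaufort 0 and visibility 1, with survey coverage held at its seasonal
mean.

Cohen's d uses the pooled-sd convention with categories none / small /
intermediate / large at |d| cutoffs 0.2 / 0.5 / 0.8. Reproductive-rate
bookkeeping under the two-year inter-birth rule is
`calves_year2 / (n_females - calves_year1)`, reported to two decimals, and
mother-match fractions are integer percents.

## Problem sizes

The shipped tests and the acceptance script run the full 25-week season
with populations of 50 females and 20 replicates, policies at 30 × 10
state nodes and 3 lengths with 6 prey categories, 50-repetition regression
calibration at 150-250 records per fit, and 25 randomized toy instances
for the enumeration oracle; these sizes were chosen so a complete run
finishes in minutes on one core while leaving every qualitative contrast
(seasonal nearshore-offshore shift, $L_{\min}$ sensitivity of cell-11 use,
little-to-no disturbance effect on reproduction under a prey-equivalent
refuge) comfortably resolved against across-replicate variability.
Production-scale settings (100 replicates, 36 × 12 nodes, 4 lengths,
`K = 7-10`) are the documented defaults of the corresponding functions.

## Known limitations

* The softmax temperature is a behavioral parameter with no field
  calibration; both it and the ε-argmax alternative are exposed, and
  conclusions that depend on fine spatial spread (cell-level occupancy)
  are more rule-sensitive than energetic outcomes (reproduction).
* Backward iteration is disturbance-blind — exposure enters only the
  forward simulation — so simulated whales do not anticipate or avoid
  future disturbance.
* The policy treats a day as one pooled decision while the simulation
  redraws prey categories per bin; the two agree in expectation but not in
  within-day variance.
* A single breeding event is modeled: no abortion decision, no multi-year
  state carryover, no calf tracking after birth.
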