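# graywhaleSDP

State-dependent life-history modeling of pregnant western gray whales
(*Eschrichtius robustus*) on the Sakhalin feeding grounds, for quantitative
population ecologists working in the population-consequences-of-disturbance
(PCoD) tradition.

Pregnant gray whales are capital breeders: one summer–fall season of benthic
foraging in two small areas — a nearshore strip (cells 1–7) and a richer
offshore area (cells 8–11) — must fund migration, gestation and most of
lactation. Seismic surveys near these areas raise the question of whether
lost foraging opportunities translate into lost calves. The package answers
it with a stochastic dynamic programming (SDP) model paired with forward
Monte-Carlo simulation, plus the statistics used to confront such models
with shore-based field data.

## The model in brief

A female's state is $(F, G, \text{cell})$ — fat mass, fetal length,
location — with body length $L$ fixed per individual. Backward iteration
solves, daily over a 25-week season,

$$V_t(F, G, c) = \mathbb{E}_{k}\!\left[\,\Pi_a\!\left\{Q_t^{(a)}\right\}\,\right],\qquad
Q_t^{(a)} = s_{\text{day}}\, V_{t+1}\!\big(F', G', c'\big),$$

over four actions $a$: leave the grounds (locking in the terminal fitness
$R(L, F, G)$, a product of logistic components for overwinter maternal
survival and calf survival by maternal condition and by fetal length), feed
in the current cell (prey energy lognormal per cell × season period,
discretized into $K$ categories $k$), travel within the cell, or travel to
another cell. $\Pi_a$ is either the Bellman maximum with tie-sharing or a
softmax over action values (the scenario default); energy dynamics follow a
prioritized allocation rule with a 5%-of-body-mass starvation floor.
Forward simulation then propagates populations through 6-h bins, optionally
applying the behavioral response to measured or synthetic acoustic exposure:
any whale in a cell-bin exposed at ≥ 163 dB re 1 µPa² SPL moves to the
nearest undisturbed cell (cells 8 and 9 are each other's nearest) and loses
the bin's foraging.

The field-comparison layer provides zero-inflated beta, hurdle-gamma and
binomial-logistic regressions (adaptive Metropolis, flat priors, split-R̂
diagnostics), block→cell density aggregation, pregnant-female density
scaling, Cohen's *d* with the 0.2/0.5/0.8 category cutoffs, and
reproductive-rate bookkeeping under a two-year inter-birth interval. Seeded
synthetic-data generators stand in for the field and acoustic data streams
and are the measurable inverses of the fitting stages.

## Worked example

```r
library(graywhaleSDP)

cells  <- build_study_area()                       # the 11-cell map
season <- season_grid()                            # May 15 + 25 weeks
truth  <- scenario_truth(seed = 1)                 # synthetic study conditions
survey <- gen_prey_survey(truth, n_samples = 40, seed = 2)
prey   <- prey_field(fit_prey_lognormal(survey), K = 6)

policy <- sdp_policy(cells, prey, season, fitness_function("low"),
                     bioenergetics_params(length_min = 11),
                     n_fat = 30, n_fetal = 10, n_lengths = 3)
policy
#> State-dependent policy (low fitness, L_min 11 m)
#>   grid: 30 fat x 10 fetal nodes; 3 solved lengths ( 11, 12.5, 14 m )
#>   behavior rule: softmax (temperature 3e-04 )

sim <- simulate(policy, nsim = 20, seed = 101, n_pop = 50)
sim
#> Forward simulation: 20 replicates x 50 females (no disturbance)
#>   reproduction: mean 0.286 (sd 0.069 across replicates)
#>   fates: dead 6, departed 994
```

A mean of 0.286 says that under the low reproductive-fitness variant with
minimum maternal length 11 m, about 29% of pregnant females carry the fetus
to term and return with a calf; 6 of 1000 simulated females starved or died
of background mortality. Occupancy shifts offshore as nearshore prey
declines through the season:

```r
occ <- occupancy_series(sim)
subset(occ$weekly, area == "offshore" & week %in% c(5, 10, 15, 20, 25))
#>  week     area  mean    sd
#>     5 offshore 0.514 0.055
#>    10 offshore 0.999 0.004
#>    15 offshore 0.996 0.008
#>    20 offshore 0.995 0.011
#>    25 offshore 0.994 0.011

cohens_d(0.62, 0.11, 20, 0.51, 0.11, 20)
#> Cohen's d = 1.000 (large effect)

reproductive_rate(27, 11, 14)   # 14 calves from 27 - 11 eligible females
#> [1] 0.88
```

Disturbance enters through an exposure series —
`exposure_probability(acoustic_grid, cells, season)` from block-level SPL
records, or `gen_acoustic_field(truth, ...)` for the synthetic seismic
survey — passed to `simulate_population(policy, exposure = ...)`;
`compare_scenarios()` then reports weekly per-cell and reproduction effect
sizes between coupled disturbed and undisturbed runs.

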