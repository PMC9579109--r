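# Shared fixtures: exact-on-grid toy dynamic programs with an independent
# brute-force oracle, and small synthetic scenario pieces.

default_cells <- function() build_study_area()
default_season <- function(n_weeks = 25L) season_grid(n_weeks = n_weeks)

# Prey field with hand-chosen categories (bypasses the lognormal
# discretization; structure matches prey_field()).
manual_prey_field <- function(values_by_cell, probs_by_cell) {
  field <- lapply(1:11, function(cl) {
    per <- list(values = values_by_cell[[cl]], prob = probs_by_cell[[cl]])
    list(early = per, mid = per, late = per)
  })
  structure(list(cells = field, K = length(values_by_cell[[1]]),
                 coverage = NA, params = NULL),
            class = "prey_field")
}

# Cell map whose only traversable pair is cells 8 and 9 (1 km apart); travel
# anywhere else costs more fat than a whale can carry, so those branches die
# immediately in both the package DP and the oracle.
toy_cells <- function(pair_dist_km = 1) {
  tab <- utils::read.csv(system.file("extdata", "cells_default.csv",
                                     package = "graywhaleSDP"),
                         stringsAsFactors = FALSE)
  tab$x_km <- c(-200, -400, -600, -800, -1000, -1200, -1400,
                0, pair_dist_km, 1600, 1800)
  tab$y_km <- 0
  build_study_area(tab)
}

# Parameter set whose energy ledger moves in exact grid-spacing units:
# mass 1000 kg, fat capacity 450 kg on a 5-node grid (step 112.5 kg),
# 1 MJ per kg of fat, full deposition efficiency, no fetal growth.
toy_params <- function(met_units = 1) {
  bioenergetics_params(
    mass_a = 1000 / 12^3, mass_b = 3,
    fat_floor_frac = 0.05, fat_max_frac = 0.45,
    fmr_coef = met_units * 112.5 / 1000^0.75,
    fat_energy_MJ_kg = 1, deposition_eff = 1,
    fetal_growth_m_day = 0, travel_MJ_km = 112.5,
    within_cell_km = 1, ref_speed_kmh = 4.5,
    dive_frac = c(0.25, 0, 0.25, 0.25),
    speed_kmh = c(4.5, 0, 4.5, 4.5),
    linearity = c(1, 0, 1, 1),
    annual_mortality = 0)
}

# Independent expectimax oracle for the toy instances: plain recursion over
# days, exact states (no grids, no interpolation). Mirrors the model
# semantics: daily step, intake = 4 * E * dive_frac, prioritized allocation,
# starvation floor, leave locks in the terminal fitness, terminal departure
# at season end.
oracle_value <- function(day, cell, fat, G, T_end, prey, fitness, params,
                         cells, L = 12) {
  mass <- params$mass_a * L^params$mass_b
  floor_kg <- params$fat_floor_frac * mass
  fmax <- params$fat_max_frac * mass
  met <- params$fmr_coef * mass^0.75
  tc <- cells$dist_km / params$linearity[1] * params$travel_MJ_km
  twc <- params$within_cell_km / params$linearity[1] * params$travel_MJ_km
  rfit <- function(f, g) reproductive_fitness(fitness, L, f, g, params)
  step_fat <- function(fat, intake, travel) {
    if (intake >= met + travel) {
      f2 <- fat + (intake - met - travel) * params$deposition_eff /
        params$fat_energy_MJ_kg
    } else {
      f2 <- fat - (met + travel - intake) / params$fat_energy_MJ_kg
    }
    min(f2, fmax)
  }
  rec <- function(day, cell, fat) {
    if (fat < floor_kg) return(0)
    if (day > T_end) return(rfit(fat, G))
    pd <- prey$cells[[cell]][["early"]]
    vals_k <- numeric(length(pd$values))
    trav <- vapply(setdiff(1:11, cell), function(d) {
      f2 <- step_fat(fat, 0, tc[cell, d])
      if (f2 < floor_kg) 0 else rec(day + 1, d, f2)
    }, numeric(1))
    for (k in seq_along(pd$values)) {
      I <- 4 * pd$values[k] * params$dive_frac[1]
      ffeed <- step_fat(fat, I, 0)
      feed <- if (ffeed < floor_kg) 0 else rec(day + 1, cell, ffeed)
      ftw <- step_fat(fat, 0.5 * I, twc)
      tw <- if (ftw < floor_kg) 0 else rec(day + 1, cell, ftw)
      vals_k[k] <- max(rfit(fat, G), feed, tw, max(trav))
    }
    sum(pd$prob * vals_k)
  }
  rec(day, cell, fat)
}

# Small prey-field scenario used across simulation tests.
quick_prey <- function(K = 5, seed = 2) {
  truth <- scenario_truth(1)
  prey_field(fit_prey_lognormal(gen_prey_survey(truth, 30, seed = seed)), K = K)
}

.policy_cache <- new.env(parent = emptyenv())

quick_policy <- function(variant = "low", L_min = 11, K = 5, seed = 2,
                         n_fat = 24, n_fetal = 8, n_lengths = 2, ...) {
  key <- paste(variant, L_min, K, seed, n_fat, n_fetal, n_lengths,
               paste(deparse(list(...)), collapse = ""), sep = "|")
  if (is.null(.policy_cache[[key]])) {
    .policy_cache[[key]] <- sdp_policy(
      default_cells(), quick_prey(K = K, seed = seed),
      default_season(), fitness_function(variant),
      bioenergetics_params(length_min = L_min),
      n_fat = n_fat, n_fetal = n_fetal, n_lengths = n_lengths, ...)
  }
  .policy_cache[[key]]
}
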