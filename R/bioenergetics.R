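# Female/fetus bioenergetics: mass scaling, prioritized energy allocation,
# starvation, background mortality, and the terminal reproductive-fitness
# functions of a capital breeder.

#' Bioenergetic parameter set
#'
#' All quantitative cost schedules are configuration with documented defaults
#' of plausible magnitude for an adult gray whale female; every downstream
#' test is written against structural properties (conservation, monotonicity,
#' ordering) rather than the specific default values. Units: length m, mass
#' kg, energy MJ, time days unless noted.
#'
#' @param mass_a,mass_b Length-mass power law `mass = mass_a * L^mass_b`
#'   (kg; default gives ~30.9 t at 12.7 m).
#' @param fat_floor_frac Starvation floor: death below this fraction of
#'   length-specific total body mass (0.05).
#' @param fat_max_frac Maximum fat store as fraction of total mass.
#' @param fmr_coef Field metabolic rate coefficient, MJ/day per kg^0.75
#'   (default twice the Kleiber basal coefficient).
#' @param fat_energy_MJ_kg Energy released per kg of fat catabolised, and
#'   stored per kg deposited before efficiency (39.3).
#' @param deposition_eff Fraction of surplus energy retained when deposited
#'   as fat.
#' @param reduced_growth Fetal growth multiplier applied when intake cannot
#'   cover full costs.
#' @param fetal_growth_m_day Scheduled fetal length growth (m/day).
#' @param fetal_mass_a Fetal mass = `fetal_mass_a * G^3` kg.
#' @param fetal_tissue_MJ_kg Energetic cost per kg of fetal tissue laid down
#'   (tissue energy plus heat of gestation).
#' @param travel_MJ_km Locomotion cost above maintenance per km traveled at
#'   the reference speed.
#' @param ref_speed_kmh Reference travel speed.
#' @param within_cell_km Path length charged for within-cell travel.
#' @param dive_frac Mean, sd and bounds of the fraction of a 6-h bout spent
#'   foraging (percentage of time diving).
#' @param speed_kmh,linearity Travel parameter distributions (mean, sd,
#'   lower, upper): speed scales cost linearly with `speed/ref_speed`;
#'   path length is straight-line distance divided by linearity.
#' @param annual_mortality Background annual mortality rate of non-calves.
#' @param start_fat_frac,start_fetal_m Starting fat (fraction of total mass)
#'   and fetal length distributions at arrival (mean, sd, lower, upper).
#' @param length_mean,length_sd,length_min,length_max Reproductive-female
#'   body-length distribution: normal(12.7, 0.6) truncated to
#'   `[length_min, length_max]`.
#' @return A `bioenergetics_params` list.
#' @export
bioenergetics_params <- function(mass_a = 15.1, mass_b = 3.0,
                                 fat_floor_frac = 0.05, fat_max_frac = 0.45,
                                 fmr_coef = 0.586,
                                 fat_energy_MJ_kg = 39.3,
                                 deposition_eff = 0.9,
                                 reduced_growth = 0.5,
                                 fetal_growth_m_day = 0.008,
                                 fetal_mass_a = 9.45,
                                 fetal_tissue_MJ_kg = 20,
                                 travel_MJ_km = 16,
                                 ref_speed_kmh = 4.5,
                                 within_cell_km = 3,
                                 dive_frac = c(0.7, 0.05, 0.5, 0.9),
                                 speed_kmh = c(4.5, 1.0, 2.0, 7.0),
                                 linearity = c(0.8, 0.1, 0.5, 1.0),
                                 annual_mortality = 0.02,
                                 start_fat_frac = c(0.25, 0.03, 0.10, 0.35),
                                 start_fetal_m = c(0.35, 0.05, 0.20, 0.50),
                                 length_mean = 12.7, length_sd = 0.6,
                                 length_min = 11.0, length_max = 14.0) {
  p <- as.list(environment())
  stopifnot(p$mass_a > 0, p$mass_b > 0, p$fat_floor_frac > 0,
            p$fat_max_frac > p$fat_floor_frac, p$deposition_eff > 0,
            p$deposition_eff <= 1, p$fat_energy_MJ_kg > 0,
            p$reduced_growth >= 0, p$reduced_growth <= 1)
  structure(p, class = "bioenergetics_params")
}

#' Length-specific total body mass and starvation floor
#'
#' @param L Body length (m), within the configured `[length_min, length_max]`
#'   range (11-14 m by default).
#' @param params A [bioenergetics_params()] set.
#' @return `total_mass`: kg. `fat_floor`: the fat mass (kg) below which a
#'   female dies (5% of total mass by default). `fat_max`: storage capacity.
#' @export
total_mass <- function(L, params = bioenergetics_params()) {
  if (any(L < params$length_min - 1e-9) || any(L > params$length_max + 1e-9)) {
    stop("length outside [", params$length_min, ", ", params$length_max, "] m")
  }
  params$mass_a * L^params$mass_b
}

#' @rdname total_mass
#' @export
fat_floor <- function(L, params = bioenergetics_params()) {
  params$fat_floor_frac * total_mass(L, params)
}

#' @rdname total_mass
#' @export
fat_max <- function(L, params = bioenergetics_params()) {
  params$fat_max_frac * total_mass(L, params)
}

# Daily field metabolic rate (MJ/day).
metabolic_day <- function(L, params) params$fmr_coef * total_mass(L, params)^0.75

# Energetic cost (MJ) of growing the fetus from length G by dG.
fetal_cost <- function(G, dG, params) {
  3 * params$fetal_mass_a * G^2 * dG * params$fetal_tissue_MJ_kg
}

#' Per-bin background survival probability
#'
#' Converts an annual background mortality rate into the survival probability
#' of one bin: `(1 - annual_rate)^(bin_hours / 8760)`, so that compounding
#' over a year recovers the annual rate exactly.
#'
#' @param annual_rate Annual mortality in `[0, 1)`.
#' @param bin_hours Bin width in hours.
#' @export
bin_survival <- function(annual_rate, bin_hours = 6) {
  if (annual_rate < 0 || annual_rate >= 1) stop("annual_rate must be in [0, 1)")
  (1 - annual_rate)^(bin_hours / 8760)
}

#' Prioritized energy allocation over one time step
#'
#' Intake first covers current metabolic needs, travel, and scheduled fetal
#' growth; any surplus is deposited as fat at the configured efficiency. When
#' intake falls short, fetal growth is slowed to `reduced_growth_factor`
#' times the scheduled rate and the remaining deficit is catabolised from fat
#' (39.3 MJ/kg by default). Fat is capped at the storage capacity and never
#' goes below zero; a female whose fat falls below the starvation floor (5%
#' of total mass) dies.
#'
#' @param state List with `L` (m), `fat` (kg), `G` (fetal length m), and
#'   optionally `status` ("alive"/"dead"/"departed").
#' @param budget List with `intake`, `metabolic_need`, `fetal_growth_cost`
#'   and `travel_cost` in MJ per step; `fetal_growth_cost` is the cost of the
#'   fully scheduled fetal increment `dG`.
#' @param dG Scheduled fetal length increment for the step (m).
#' @param params A [bioenergetics_params()] set.
#' @param reduced_growth_factor Fetal growth multiplier under deficit.
#' @return The updated state (fat, G, status).
#' @export
allocate_energy <- function(state, budget, dG,
                            params = bioenergetics_params(),
                            reduced_growth_factor = params$reduced_growth) {
  if (!is.null(state$status) && state$status != "alive") {
    stop("allocate_energy requires a living female")
  }
  b <- budget
  for (nm in c("intake", "metabolic_need", "fetal_growth_cost", "travel_cost")) {
    if (is.null(b[[nm]]) || !is.finite(b[[nm]])) stop("budget$", nm, " must be finite")
    if (b[[nm]] < 0) stop("budget$", nm, " must be non-negative")
  }
  r <- alloc_core(state$fat, state$G, b$intake, b$metabolic_need,
                  b$fetal_growth_cost, b$travel_cost, dG, state$L, params,
                  reduced_growth_factor)
  state$fat <- r$fat
  state$G <- r$G
  state$status <- if (r$dead) "dead" else "alive"
  state
}

# Vectorised allocation core shared by the public wrapper, the backward
# iteration and the forward simulation. All arguments recycle.
alloc_core <- function(fat, G, intake, met, fetal, travel, dG, L, params,
                       rgf = params$reduced_growth) {
  full <- intake >= met + fetal + travel
  cost_r <- met + travel + rgf * fetal
  surplus <- ifelse(full, intake - (met + fetal + travel),
                    pmax(intake - cost_r, 0))
  deficit <- ifelse(full, 0, pmax(cost_r - intake, 0))
  fat2 <- fat + surplus * params$deposition_eff / params$fat_energy_MJ_kg -
    deficit / params$fat_energy_MJ_kg
  fat2 <- pmin(fat2, params$fat_max_frac * params$mass_a * L^params$mass_b)
  dead <- fat2 < params$fat_floor_frac * params$mass_a * L^params$mass_b
  fat2 <- pmax(fat2, 0)
  list(fat = fat2, G = G + ifelse(full, dG, rgf * dG), dead = dead)
}

#' Reproductive fitness functions (low / medium / high)
#'
#' Terminal probability that a female departing the foraging grounds carries
#' her fetus to term and weans the calf on return. It is the product of three
#' scaled logistic components: overwinter maternal survival in the departure
#' fat fraction (shared across variants, identical to
#' [survival_to_next_season()]), calf survival in the departure fat fraction
#' (variants differ in asymptote), and calf survival in fetal length at
#' departure (variants differ in midpoint; a common steepness keeps the three
#' variants ordered pointwise low <= medium <= high). A female with no fetus
#' has fitness zero.
#'
#' @param variant "low", "medium" or "high".
#' @param surv_mid,surv_steep Overwinter maternal-survival logistic, on the
#'   fat/mass fraction scale.
#' @param mass_asym Calf-survival-by-maternal-mass asymptote for the variant.
#' @param mass_mid,mass_steep Midpoint/steepness of that component (fat
#'   fraction scale).
#' @param fetal_mid Midpoint (m of fetal length) of the calf-survival-by-
#'   fetal-length component for the variant.
#' @param fetal_steep Common steepness (per m).
#' @return A `fitness_function` object.
#' @export
fitness_function <- function(variant = c("low", "medium", "high"),
                             surv_mid = 0.12, surv_steep = 40,
                             mass_asym = NULL, mass_mid = 0.20, mass_steep = 25,
                             fetal_mid = NULL, fetal_steep = 6) {
  variant <- match.arg(variant)
  if (is.null(mass_asym)) {
    mass_asym <- c(low = 0.60, medium = 0.75, high = 0.90)[[variant]]
  }
  if (is.null(fetal_mid)) {
    fetal_mid <- c(low = 1.5, medium = 1.3, high = 1.1)[[variant]]
  }
  structure(list(variant = variant, surv_mid = surv_mid,
                 surv_steep = surv_steep, mass_asym = mass_asym,
                 mass_mid = mass_mid, mass_steep = mass_steep,
                 fetal_mid = fetal_mid, fetal_steep = fetal_steep),
            class = "fitness_function")
}

#' @export
print.fitness_function <- function(x, ...) {
  cat(sprintf(
    "Reproductive fitness (%s): calf-mass asymptote %.2f @ midpoint %.2f, fetal midpoint %.2f m\n",
    x$variant, x$mass_asym, x$mass_mid, x$fetal_mid))
  invisible(x)
}

#' Probability of successful reproduction at departure
#'
#' Departure time enters through the state reached at departure (fat and
#' fetal length); there is no separate explicit time penalty.
#'
#' @param fn A [fitness_function()].
#' @param L Maternal length (m).
#' @param fat_dep Fat mass at departure (kg). Vectorised with `G_dep`.
#' @param G_dep Fetal length at departure (m).
#' @param params A [bioenergetics_params()] set.
#' @param t_dep Departure day (accepted for interface completeness; see
#'   Details).
#' @return Probability in `[0, 1]`.
#' @export
reproductive_fitness <- function(fn, L, fat_dep, G_dep,
                                 params = bioenergetics_params(),
                                 t_dep = NULL) {
  stopifnot(inherits(fn, "fitness_function"))
  frac <- pmax(fat_dep, 0) / total_mass(L, params)
  surv <- stats::plogis(fn$surv_steep * (frac - fn$surv_mid))
  cmass <- fn$mass_asym * stats::plogis(fn$mass_steep * (frac - fn$mass_mid))
  cfetal <- stats::plogis(fn$fetal_steep * (G_dep - fn$fetal_mid))
  out <- surv * cmass * cfetal
  out[G_dep <= 0] <- 0
  pmin(pmax(out, 0), 1)
}

#' Overwinter maternal survival
#'
#' Logistic in the departure fat fraction `fat_dep / total_mass(L)` with
#' configured midpoint and steepness; non-decreasing in `fat_dep`.
#' @inheritParams reproductive_fitness
#' @param mid,steep Logistic midpoint (fat fraction) and steepness.
#' @export
survival_to_next_season <- function(L, fat_dep, params = bioenergetics_params(),
                                    mid = 0.12, steep = 40) {
  if (any(fat_dep < 0)) stop("fat_dep must be >= 0")
  stats::plogis(steep * (fat_dep / total_mass(L, params) - mid))
}

#' Draw a pregnant female's starting state
#'
#' Length comes from the truncated normal reproductive-female distribution
#' (mean 12.7 m, sd 0.6 m, bounds `[L_min, 14]`); starting fat and fetal
#' length are drawn from configured truncated normals, fat scaled by
#' length-specific total mass.
#'
#' @param n Number of females.
#' @param params A [bioenergetics_params()] set (length bounds carry
#'   `L_min`).
#' @param seed Optional seed (local to the call).
#' @return Data frame with `L`, `fat`, `G`.
#' @export
sample_female <- function(n, params = bioenergetics_params(), seed = NULL) {
  if (params$length_min > params$length_max) {
    stop("length_min exceeds length_max")
  }
  with_local_seed(seed, {
    L <- rtruncnorm(n, params$length_mean, params$length_sd,
                    params$length_min, params$length_max)
    ff <- rtruncnorm(n, params$start_fat_frac[1], params$start_fat_frac[2],
                     params$start_fat_frac[3], params$start_fat_frac[4])
    G <- rtruncnorm(n, params$start_fetal_m[1], params$start_fetal_m[2],
                    params$start_fetal_m[3], params$start_fetal_m[4])
    data.frame(L = L, fat = ff * total_mass(L, params), G = G)
  })
}
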