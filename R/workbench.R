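# Scenario orchestration: the factorial experimental design (three fitness
# variants x four minimum lengths, with and without disturbance), end-to-end
# runs with provenance, and scenario comparison by Cohen's d.

#' Define a model scenario
#'
#' @param fitness Fitness-function variant: "low", "medium" or "high".
#' @param L_min Minimum reproductive female length; one of 11.0, 12.1, 12.7,
#'   13.0 m unless `allow_custom`.
#' @param disturbance Include the synthetic seismic-survey exposure?
#' @param n_rep Population replicates.
#' @param n_pop Females per replicate.
#' @param seed Master seed.
#' @param allow_custom Permit L_min values outside the studied set.
#' @return An `sdp_scenario` object.
#' @export
scenario <- function(fitness = c("low", "medium", "high"), L_min = 11.0,
                     disturbance = FALSE, n_rep = 100L, n_pop = 50L,
                     seed = 1L, allow_custom = FALSE) {
  fitness <- match.arg(fitness)
  allowed <- c(11.0, 12.1, 12.7, 13.0)
  if (!allow_custom && !any(abs(L_min - allowed) < 1e-9)) {
    stop("L_min must be one of ", paste(allowed, collapse = ", "),
         " (use allow_custom = TRUE to override)")
  }
  structure(list(fitness = fitness, L_min = L_min, disturbance = disturbance,
                 n_rep = as.integer(n_rep), n_pop = as.integer(n_pop),
                 seed = as.integer(seed)),
            class = "sdp_scenario")
}

#' @export
print.sdp_scenario <- function(x, ...) {
  cat(sprintf("Scenario: %s fitness, L_min %.1f m, %s, %d x %d females, seed %d\n",
              x$fitness, x$L_min,
              if (x$disturbance) "disturbed" else "undisturbed",
              x$n_rep, x$n_pop, x$seed))
  invisible(x)
}

#' The factorial scenario grid
#'
#' Three reproductive-fitness variants crossed with four minimum lengths
#' give the twelve model permutations of the experimental design.
#'
#' @inheritParams scenario
#' @return List of 12 `sdp_scenario` objects.
#' @export
scenario_grid <- function(disturbance = FALSE, n_rep = 100L, n_pop = 50L,
                          seed = 1L) {
  out <- list()
  for (fv in c("low", "medium", "high")) {
    for (lm in c(11.0, 12.1, 12.7, 13.0)) {
      out[[length(out) + 1L]] <- scenario(fv, lm, disturbance, n_rep, n_pop, seed)
    }
  }
  out
}

#' Run a scenario end to end
#'
#' Generates (or accepts) the synthetic inputs, fits the prey field, solves
#' the policy, runs the forward simulation, and returns a results bundle
#' with summaries and a provenance hash of the fully resolved configuration.
#' The same scenario and seed reproduce the bundle exactly.
#'
#' @param sc An [scenario()] object.
#' @param truth A [scenario_truth()]; default derives its seed from the
#'   scenario's.
#' @param cells,season Study area and calendar (defaults).
#' @param K Prey categories.
#' @param n_fat,n_fetal,n_lengths Policy grid resolution.
#' @param rule,temperature Behavior-probability rule.
#' @param exposure Optional pre-built [exposure_series()]; by default a
#'   disturbance scenario generates the synthetic acoustic field.
#' @param params_args Named list of overrides for [bioenergetics_params()].
#' @return A `scenario_bundle` list.
#' @export
run_scenario <- function(sc, truth = scenario_truth(child_seed(sc$seed, 99L)),
                         cells = build_study_area(),
                         season = season_grid(), K = 7L,
                         n_fat = 36L, n_fetal = 12L, n_lengths = 4L,
                         rule = "softmax", temperature = 3e-4,
                         exposure = NULL, params_args = list()) {
  stopifnot(inherits(sc, "sdp_scenario"))
  params <- do.call(bioenergetics_params,
                    c(list(length_min = sc$L_min), params_args))
  samples <- gen_prey_survey(truth, seed = child_seed(sc$seed, 1L))
  prey_par <- fit_prey_lognormal(samples)
  prey <- prey_field(prey_par, K = K)
  fitness <- fitness_function(sc$fitness)
  policy <- sdp_policy(cells, prey, season, fitness, params,
                       n_fat = n_fat, n_fetal = n_fetal,
                       n_lengths = n_lengths, rule = rule,
                       temperature = temperature)
  if (sc$disturbance && is.null(exposure)) {
    grid <- gen_acoustic_field(truth, cells, season,
                               seed = child_seed(sc$seed, 2L))
    exposure <- exposure_probability(grid, cells, season)
  }
  sim <- simulate_population(policy, exposure = if (sc$disturbance) exposure,
                             n_pop = sc$n_pop, n_rep = sc$n_rep,
                             seed = sc$seed)
  occ <- occupancy_series(sim)
  rep_sum <- reproduction_summary(sim)
  config <- list(scenario = unclass(sc), params = unclass(params),
                 prey = prey_par, K = K, n_fat = n_fat, n_fetal = n_fetal,
                 n_lengths = n_lengths, rule = rule, temperature = temperature)
  structure(list(scenario = sc, truth_seed = truth$seed, policy = policy,
                 exposure = exposure, sim = sim, occupancy = occ,
                 reproduction = rep_sum, config = config,
                 config_hash = config_hash(config)),
            class = "scenario_bundle")
}

#' @export
print.scenario_bundle <- function(x, ...) {
  print(x$scenario)
  cat(sprintf("  reproduction %.3f (sd %.3f); config %s\n",
              x$reproduction$mean, x$reproduction$sd,
              substr(x$config_hash, 1, 8)))
  invisible(x)
}

#' Run a list of scenarios
#'
#' @param scenarios List of [scenario()] objects (e.g. [scenario_grid()]).
#' @param ... Passed to [run_scenario()].
#' @export
run_scenario_grid <- function(scenarios, ...) {
  lapply(scenarios, run_scenario, ...)
}

#' Compare two scenario bundles by Cohen's d
#'
#' Weekly effect sizes per cell and per area from the across-replicate
#' means and standard deviations of occupancy proportions, plus the
#' reproduction effect size across replicates. Positive d means the first
#' bundle is higher.
#'
#' @param a,b `scenario_bundle` results sharing a season grid and replicate
#'   count (or `sdp_sim` objects).
#' @return List with data frames `cell`, `area`, and the reproduction
#'   `effect_size`.
#' @export
compare_scenarios <- function(a, b) {
  sim_a <- if (inherits(a, "scenario_bundle")) a$sim else a
  sim_b <- if (inherits(b, "scenario_bundle")) b$sim else b
  stopifnot(inherits(sim_a, "sdp_sim"), inherits(sim_b, "sdp_sim"))
  if (sim_a$season$n_bins != sim_b$season$n_bins ||
      sim_a$n_rep != sim_b$n_rep) {
    stop("bundles must share the season grid and replicate count")
  }
  oa <- if (inherits(a, "scenario_bundle")) a$occupancy else occupancy_series(a)
  ob <- if (inherits(b, "scenario_bundle")) b$occupancy else occupancy_series(b)
  n <- sim_a$n_rep
  n_weeks <- sim_a$season$n_weeks
  cell <- do.call(rbind, lapply(1:11, function(cl) {
    do.call(rbind, lapply(seq_len(n_weeks), function(w) {
      xa <- oa$cell_week[, w, cl]; xb <- ob$cell_week[, w, cl]
      es <- cohens_d(mean(xa), stats::sd(xa), n, mean(xb), stats::sd(xb), n)
      data.frame(cell = cl, week = w, d = es$d, category = es$category)
    }))
  }))
  area <- do.call(rbind, lapply(1:3, function(ai) {
    nm <- c("nearshore", "offshore", "outside")[ai]
    do.call(rbind, lapply(seq_len(n_weeks), function(w) {
      xa <- oa$area_week[, w, ai]; xb <- ob$area_week[, w, ai]
      es <- cohens_d(mean(xa), stats::sd(xa), n, mean(xb), stats::sd(xb), n)
      data.frame(area = nm, week = w, d = es$d, category = es$category)
    }))
  }))
  ra <- reproduction_summary(sim_a); rb <- reproduction_summary(sim_b)
  repro <- cohens_d(ra$mean, ra$sd, n, rb$mean, rb$sd, n)
  list(cell = cell, area = area, reproduction = repro)
}
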