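# Mass scaling, energy allocation, starvation, mortality, and the three
# reproductive-fitness variants.

test_that("total mass follows the configured power law and the floor is 5% of it", {
  p <- bioenergetics_params()
  expect_equal(total_mass(12.7, p), 15.1 * 12.7^3)
  expect_equal(fat_floor(12.7, p), 0.05 * 15.1 * 12.7^3)
  p2 <- bioenergetics_params(mass_a = 20000 / 12^3, mass_b = 3)
  expect_equal(fat_floor(12, p2), 1000)
  L <- seq(11, 14, by = 0.25)
  expect_true(all(diff(fat_floor(L, p)) > 0))
  expect_error(total_mass(10.5, p), "outside")
})

test_that("energy allocation conserves energy in surplus and deficit regimes", {
  p <- bioenergetics_params()
  set.seed(7)
  for (i in 1:50) {
    L <- runif(1, 11, 14)
    st <- list(L = L, fat = runif(1, 0.1, 0.3) * total_mass(L, p),
               G = runif(1, 0.2, 1.5), status = "alive")
    dG <- p$fetal_growth_m_day / 4
    b <- list(intake = runif(1, 0, 800), metabolic_need = runif(1, 200, 400),
              fetal_growth_cost = 3 * p$fetal_mass_a * st$G^2 * dG * p$fetal_tissue_MJ_kg,
              travel_cost = sample(c(0, runif(1, 0, 300)), 1))
    new <- allocate_energy(st, b, dG, p)
    dfat <- new$fat - st$fat
    fetal_spent <- 3 * p$fetal_mass_a * st$G^2 * (new$G - st$G) * p$fetal_tissue_MJ_kg
    fat_energy <- if (dfat >= 0) dfat * p$fat_energy_MJ_kg / p$deposition_eff else
      dfat * p$fat_energy_MJ_kg
    resid <- b$intake - b$metabolic_need - b$travel_cost - fetal_spent - fat_energy
    expect_lt(abs(resid), 1e-9)
    # fetal growth is full when intake covers everything, reduced otherwise
    full <- b$intake >= b$metabolic_need + b$fetal_growth_cost + b$travel_cost
    expect_equal(new$G - st$G, if (full) dG else p$reduced_growth * dG)
  }
})

test_that("a 39.3 MJ deficit catabolises exactly one kg of fat", {
  p <- bioenergetics_params()
  st <- list(L = 12.7, fat = 5000, G = 0, status = "alive")
  new <- allocate_energy(st, list(intake = 0, metabolic_need = 39.3,
                                  fetal_growth_cost = 0, travel_cost = 0),
                         dG = 0, p)
  expect_equal(new$fat, 4999)
  expect_equal(new$status, "alive")
})

test_that("balance-point intake leaves fat unchanged with full fetal growth", {
  p <- bioenergetics_params()
  st <- list(L = 12, fat = 6000, G = 1, status = "alive")
  dG <- 0.002
  fc <- 3 * p$fetal_mass_a * 1^2 * dG * p$fetal_tissue_MJ_kg
  new <- allocate_energy(st, list(intake = 300 + fc, metabolic_need = 300,
                                  fetal_growth_cost = fc, travel_cost = 0),
                         dG = dG, p)
  expect_equal(new$fat, 6000)
  expect_equal(new$G, 1 + dG)
})

test_that("females die when fat falls below the starvation floor", {
  p <- bioenergetics_params()
  st <- list(L = 12.7, fat = fat_floor(12.7, p) + 0.5, G = 0.5, status = "alive")
  new <- allocate_energy(st, list(intake = 0, metabolic_need = 400,
                                  fetal_growth_cost = 5, travel_cost = 0),
                         dG = 0.002, p)
  expect_equal(new$status, "dead")
  expect_error(allocate_energy(list(L = 12, fat = 100, G = 0, status = "dead"),
                               list(intake = 0, metabolic_need = 1,
                                    fetal_growth_cost = 0, travel_cost = 0),
                               0, p), "living")
  expect_error(allocate_energy(st, list(intake = -1, metabolic_need = 1,
                                        fetal_growth_cost = 0, travel_cost = 0),
                               0, p), "non-negative")
})

test_that("fitness variants are ordered low <= medium <= high on a state grid", {
  p <- bioenergetics_params()
  fl <- fitness_function("low"); fm <- fitness_function("medium")
  fh <- fitness_function("high")
  grid <- expand.grid(L = c(11, 12.7, 14), fat_frac = seq(0.06, 0.45, by = 0.03),
                      G = seq(0, 2, by = 0.2))
  vl <- reproductive_fitness(fl, grid$L, grid$fat_frac * total_mass(grid$L, p), grid$G, p)
  vm <- reproductive_fitness(fm, grid$L, grid$fat_frac * total_mass(grid$L, p), grid$G, p)
  vh <- reproductive_fitness(fh, grid$L, grid$fat_frac * total_mass(grid$L, p), grid$G, p)
  expect_true(all(vl >= 0 & vh <= 1))
  expect_true(all(vm >= vl - 1e-12))
  expect_true(all(vh >= vm - 1e-12))
})

test_that("fitness is zero with no fetus, ~0 at the starvation floor, monotone in state", {
  p <- bioenergetics_params()
  for (v in c("low", "medium", "high")) {
    fn <- fitness_function(v)
    expect_equal(reproductive_fitness(fn, 12.7, 9000, 0, p), 0)
    expect_lt(reproductive_fitness(fn, 12.7, fat_floor(12.7, p), 1.8, p), 0.01)
    fat <- seq(0, fat_max(12.7, p), length.out = 40)
    expect_true(all(diff(reproductive_fitness(fn, 12.7, fat, 1.4, p)) >= 0))
    G <- seq(0, 2, length.out = 40)
    expect_true(all(diff(reproductive_fitness(fn, 12.7, 9000, G, p)) >= -1e-12))
  }
})

test_that("overwinter survival is a logistic in the departure fat fraction", {
  p <- bioenergetics_params()
  mass <- total_mass(12.7, p)
  expect_equal(survival_to_next_season(12.7, 0.12 * mass, p), 0.5)
  expect_lt(survival_to_next_season(12.7, 0, p), 0.01)
  fat <- seq(0, 0.45 * mass, length.out = 30)
  expect_true(all(diff(survival_to_next_season(12.7, fat, p)) >= 0))
  expect_error(survival_to_next_season(12.7, -1, p), ">= 0")
})

test_that("female starting states follow the truncated length distribution", {
  p <- bioenergetics_params()
  d <- sample_female(1e5, p, seed = 3)
  # closed-form moments of normal(12.7, 0.6) truncated to [11, 14]
  a <- (11 - 12.7) / 0.6; b <- (14 - 12.7) / 0.6
  Z <- pnorm(b) - pnorm(a)
  m_true <- 12.7 + 0.6 * (dnorm(a) - dnorm(b)) / Z
  v_true <- 0.6^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                       ((dnorm(a) - dnorm(b)) / Z)^2)
  expect_equal(mean(d$L), m_true, tolerance = 0.01)
  expect_equal(sd(d$L), sqrt(v_true), tolerance = 0.01)
  expect_true(all(d$L >= 11 & d$L <= 14))

  p13 <- bioenergetics_params(length_min = 13)
  d13 <- sample_female(2000, p13, seed = 4)
  expect_gte(min(d13$L), 13)
  expect_identical(sample_female(50, p, seed = 9), sample_female(50, p, seed = 9))
  expect_error(sample_female(5, bioenergetics_params(length_min = 14.5)))
})

test_that("background mortality compounds exactly to the annual rate", {
  expect_equal(bin_survival(0), 1)
  expect_equal(bin_survival(0.02), 0.98^(6 / 8760))
  expect_equal(bin_survival(0.02)^(8760 / 6), 0.98)
  expect_error(bin_survival(1), "annual_rate")
})
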