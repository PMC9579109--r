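# Backward iteration: terminal values, brute-force oracle equivalence on
# exact-on-grid toys, value monotonicity, and behavior-probability semantics.

toy_policy <- function(prey, params = toy_params(), pair_dist = 1,
                       fitness = fitness_function("low"), n_weeks = 1) {
  sdp_policy(toy_cells(pair_dist), prey, season_grid(n_weeks = n_weeks),
             fitness, params, n_fat = 5, n_fetal = 2, fetal_max = 1.75,
             lengths = 12, rule = "argmax")
}

toy_prey <- function(v8, p8, v9, p9) {
  vals <- c(list(), rep(list(0), 7), list(v8, v9), rep(list(0), 2))
  prb <- c(rep(list(1), 7), list(p8, p9), rep(list(1), 2))
  manual_prey_field(vals, prb)
}

test_that("terminal values equal departure fitness and inherit its structure", {
  p <- bioenergetics_params()
  fn <- fitness_function("medium")
  Fg <- seq(0, fat_max(12.7, p), length.out = 12)
  Gg <- seq(0, 2, length.out = 6)
  V <- terminal_values(fn, 12.7, Fg, Gg, p)
  expect_equal(V[, 1], rep(0, 12))                      # no fetus
  expect_true(all(apply(V, 2, function(col) all(diff(col) >= 0))))
  expect_equal(V[12, 6], reproductive_fitness(fn, 12.7, Fg[12], Gg[6], p))
  expect_equal(max(V), V[12, 6])
  expect_equal(as.vector(V[Fg < fat_floor(12.7, p), ]),
               rep(0, sum(Fg < fat_floor(12.7, p)) * 6))
})

test_that("backward iteration matches the brute-force expectimax oracle", {
  prey <- toy_prey(c(0, 225, 450), c(0.3, 0.4, 0.3), c(0, 225), c(0.5, 0.5))
  params <- toy_params(met_units = 1)
  pol <- toy_policy(prey, params)
  e <- pol$per_length[[1]]
  t0 <- pol$season$n_days - 3
  for (cl in c(8L, 9L)) {
    for (i in 2:5) {
      for (j in 1:2) {
        v_or <- oracle_value(t0, cl, e$Fg[i], e$Gg[j], pol$season$n_days,
                             prey, pol$fitness, params, pol$cells)
        expect_equal(e$V[[t0]][i, j, cl], v_or, tolerance = 1e-10)
      }
    }
  }
})

test_that("with zero prey and declining fat, leaving is the optimal action", {
  prey <- toy_prey(0, 1, 0, 1)
  pol <- toy_policy(prey)
  e <- pol$per_length[[1]]
  pr <- action_probabilities(pol, list(L = 12, fat = e$Fg[4], G = 1.75,
                                       cell = 8, category = 1), day = 2)
  expect_equal(unname(pr["leave"]), 1)
  # value can only fall toward terminal when there is nothing to eat
  for (cl in c(8, 9)) {
    v_t <- sapply(seq_len(pol$season$n_days), function(t) e$V[[t]][4, 2, cl])
    expect_true(all(diff(v_t) >= -1e-12))
  }
})

test_that("policy treats symmetric cells symmetrically", {
  prey <- toy_prey(c(0, 450), c(0.5, 0.5), c(0, 450), c(0.5, 0.5))
  pol <- toy_policy(prey, pair_dist = 1)
  e <- pol$per_length[[1]]
  st8 <- list(L = 12, fat = e$Fg[3], G = 1.75, cell = 8, category = 2)
  st9 <- st8; st9$cell <- 9
  p8 <- action_probabilities(pol, st8, day = 3)
  p9 <- action_probabilities(pol, st9, day = 3)
  expect_equal(unname(p8["feed"]), unname(p9["feed"]), tolerance = 1e-12)
  expect_equal(unname(p8["travel_to_9"]), unname(p9["travel_to_8"]),
               tolerance = 1e-12)
  expect_equal(e$V[[3]][, , 8], e$V[[3]][, , 9], tolerance = 1e-12)
})

test_that("a uniform prey increment in one cell never decreases any value", {
  prey_lo <- toy_prey(c(0, 225), c(0.5, 0.5), c(225, 450), c(0.5, 0.5))
  prey_hi <- toy_prey(c(0, 225) + 112.5, c(0.5, 0.5), c(225, 450), c(0.5, 0.5))
  pol_lo <- toy_policy(prey_lo)
  pol_hi <- toy_policy(prey_hi)
  for (t in c(1, 3, 5)) {
    expect_true(all(pol_hi$per_length[[1]]$V[[t]] >=
                      pol_lo$per_length[[1]]$V[[t]] - 1e-12))
  }
})

test_that("values are monotone in fat and probabilities are proper", {
  pol <- quick_policy(n_fat = 16, n_fetal = 6, n_lengths = 1, K = 4)
  e <- pol$per_length[[1]]
  # non-decreasing in fat up to the small wobble that bilinear interpolation
  # of the softmax-averaged surface introduces near the starvation floor
  for (t in c(1, 60, 140)) {
    for (cl in c(1, 5, 9, 11)) {
      expect_true(all(apply(e$V[[t]][, , cl], 2,
                            function(col) all(diff(col) >= -1e-3))))
    }
  }
  st <- list(L = pol$lengths[1], fat = 0.5 * (e$Fg[7] + e$Fg[8]), G = 0.61,
             cell = 9, category = 2)
  pr <- action_probabilities(pol, st, day = 50)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  expect_true(all(pr >= 0))
  # exactly on a grid node the blend reproduces the node distribution
  st_node <- list(L = pol$lengths[1], fat = e$Fg[8], G = e$Gg[4],
                  cell = 9, category = 2)
  pr_node <- action_probabilities(pol, st_node, day = 50)
  expect_equal(sum(pr_node), 1, tolerance = 1e-12)
  # clamping outside the hull warns and still returns a distribution
  st_out <- st; st_out$fat <- e$Fg[16] * 1.2
  expect_warning(pr_out <- action_probabilities(pol, st_out, day = 50), "clamp")
  expect_equal(sum(pr_out), 1, tolerance = 1e-12)
})

test_that("seasonal reproduction is stable when the state grid is doubled", {
  prey <- quick_prey(K = 4)
  params <- bioenergetics_params()
  season <- season_grid()
  fn <- fitness_function("low")
  rep_at <- function(n_fat, n_fetal) {
    pol <- sdp_policy(default_cells(), prey, season, fn, params,
                      n_fat = n_fat, n_fetal = n_fetal, n_lengths = 1)
    reproduction_summary(simulate_population(pol, n_pop = 25, n_rep = 4,
                                             seed = 5))$mean
  }
  r1 <- rep_at(24, 8)
  r2 <- rep_at(48, 16)
  expect_gt(r1, 0.05) # the scenario actually produces reproduction
  expect_lt(abs(r2 - r1) / r1, 0.01)
})
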