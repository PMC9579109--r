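# Backward iteration: expected-fitness values over the discretized state grid
# and the probability distribution over the four behavioral actions.

#' Terminal expected-fitness values
#'
#' Values on the last possible foraging day: every remaining female departs,
#' so the terminal value at each (fat, fetal length) grid node is the
#' reproductive fitness at that departure state. Nodes below the starvation
#' floor are dead and worth zero.
#'
#' @param fitness A [fitness_function()].
#' @param L Maternal length (m).
#' @param fat_grid,fetal_grid Increasing state grids (kg, m).
#' @param params A [bioenergetics_params()] set.
#' @return Matrix `length(fat_grid) x length(fetal_grid)` of values in
#'   `[0, 1]`.
#' @export
terminal_values <- function(fitness, L, fat_grid, fetal_grid,
                            params = bioenergetics_params()) {
  V <- outer(fat_grid, fetal_grid, function(f, g) {
    reproductive_fitness(fitness, L, f, g, params)
  })
  V[fat_grid < fat_floor(L, params), ] <- 0
  V
}

#' Fit a state-dependent behavioral policy by backward iteration
#'
#' Solves the dynamic program for a pregnant female over the foraging season.
#' At each daily decision step a female may (1) leave the foraging grounds
#' (locking in the reproductive fitness of her current state), (2) feed in
#' her current cell, (3) travel within the cell (a partial foraging bout plus
#' a travel cost), or (4) travel to any other cell. Future values are
#' discounted by daily background survival; prey categories are redrawn
#' independently each day from the cell-and-period distribution, and the
#' stored value surface is the expectation over categories. Behavior
#' probabilities are produced either by softmax over action values
#' (temperature on the `[0, 1]` fitness scale) or by argmax with uniform
#' tie-sharing within `epsilon`.
#'
#' Because metabolic rate, storage capacity and the starvation floor scale
#' with body length, the policy is solved on a small grid of lengths spanning
#' `[length_min, length_max]`; simulation selects the nearest solved length.
#'
#' @param cells A [build_study_area()] map.
#' @param prey A [prey_field()].
#' @param season A [season_grid()].
#' @param fitness A [fitness_function()].
#' @param params A [bioenergetics_params()] set; its `length_min` is the
#'   minimum reproductive length L_min.
#' @param n_fat,n_fetal State-grid resolution (fat mass, fetal length).
#' @param fetal_max Upper bound of the fetal-length grid (m).
#' @param lengths Explicit vector of lengths to solve; default `n_lengths`
#'   values spanning the length range.
#' @param n_lengths Number of solved lengths.
#' @param rule Behavior-probability rule, `"softmax"` or `"argmax"`.
#' @param temperature Softmax temperature (fitness units).
#' @param epsilon Argmax tie tolerance (fitness units).
#' @return An object of class `sdp_policy` with `print`, `summary` and
#'   [simulate.sdp_policy()] methods.
#' @seealso [action_probabilities()], [simulate_population()]
#' @export
sdp_policy <- function(cells, prey, season, fitness,
                       params = bioenergetics_params(),
                       n_fat = 36L, n_fetal = 12L, fetal_max = 2.0,
                       lengths = NULL, n_lengths = 4L,
                       rule = c("softmax", "argmax"),
                       temperature = 3e-4, epsilon = 1e-6) {
  stopifnot(inherits(cells, "whale_cells"), inherits(prey, "prey_field"),
            inherits(season, "season_grid"), inherits(fitness, "fitness_function"))
  rule <- match.arg(rule)
  if (is.null(lengths)) {
    lengths <- if (n_lengths == 1L) {
      params$length_mean
    } else {
      seq(params$length_min, params$length_max, length.out = n_lengths)
    }
  }
  n_cells <- 11L
  linearity_mean <- params$linearity[1]
  tc <- cells$dist_km / linearity_mean * params$travel_MJ_km
  tw_cost <- params$within_cell_km / linearity_mean * params$travel_MJ_km
  s_day <- bin_survival(params$annual_mortality, season$bin_hours)^season$bins_per_day
  dive_mean <- params$dive_frac[1]

  # Daily intake (MJ) per cell x period x category: four 6-h bouts at the
  # mean dive fraction.
  intake <- lapply(c("early", "mid", "late"), function(p) {
    lapply(1:n_cells, function(cl) {
      d <- prey$cells[[cl]][[p]]
      list(I = season$bins_per_day * d$values * dive_mean, prob = d$prob)
    })
  })
  names(intake) <- c("early", "mid", "late")

  per_length <- lapply(lengths, function(L) {
    solve_one_length(L, cells, season, fitness, params, intake, tc, tw_cost,
                     s_day, n_fat, n_fetal, fetal_max, rule, temperature,
                     epsilon)
  })

  structure(list(lengths = lengths, per_length = per_length, cells = cells,
                 prey = prey, season = season, fitness = fitness,
                 params = params, rule = rule, temperature = temperature,
                 epsilon = epsilon, travel_cost = tc, within_cost = tw_cost,
                 day_survival = s_day, dive_mean = dive_mean,
                 intake = intake, n_fat = as.integer(n_fat),
                 n_fetal = as.integer(n_fetal)),
            class = "sdp_policy")
}

solve_one_length <- function(L, cells, season, fitness, params, intake, tc,
                             tw_cost, s_day, n_fat, n_fetal, fetal_max, rule,
                             temperature, epsilon) {
  n_cells <- 11L
  fmax <- fat_max(L, params)
  floor_kg <- fat_floor(L, params)
  Fg <- seq(0, fmax, length.out = n_fat)
  Gg <- seq(0, fetal_max, length.out = n_fetal)
  met <- metabolic_day(L, params)
  dG <- params$fetal_growth_m_day
  fcg <- fetal_cost(Gg, dG, params)
  term <- terminal_values(fitness, L, Fg, Gg, params)
  Rvec <- as.vector(term)  # leave-action value, time-invariant

  n_days <- season$n_days
  V <- vector("list", n_days + 1L)
  V[[n_days + 1L]] <- array(rep(term, n_cells), dim = c(n_fat, n_fetal, n_cells))

  env <- list(L = L, Fg = Fg, Gg = Gg, met = met, dG = dG, fcg = fcg,
              floor_kg = floor_kg, fmax = fmax, Rvec = Rvec, term = term,
              n_fat = n_fat, n_fetal = n_fetal)
  fat_pts <- rep(Fg, times = n_fetal)
  g_pts <- rep(Gg, each = n_fat)
  fet_pts <- rep(fcg, each = n_fat)

  act_val <- function(Vc, I, tcost) {
    a <- alloc_core(fat_pts, g_pts, I, met, fet_pts, tcost, dG, L, params)
    v <- s_day * interp2(Vc, Fg, Gg, a$fat, a$G)
    v[a$dead] <- 0
    v
  }

  for (t in n_days:1L) {
    p <- period_of_day(t, season)
    Vn <- V[[t + 1L]]
    Vt <- array(0, dim = c(n_fat, n_fetal, n_cells))
    for (cl in 1:n_cells) {
      dests <- setdiff(1:n_cells, cl)
      Atrav <- vapply(dests, function(d) act_val(Vn[, , d], 0, tc[cl, d]),
                      numeric(n_fat * n_fetal))
      cd <- intake[[p]][[cl]]
      K <- length(cd$I)
      acc <- numeric(n_fat * n_fetal)
      for (k in seq_len(K)) {
        A <- cbind(Rvec,
                   act_val(Vn[, , cl], cd$I[k], 0),
                   act_val(Vn[, , cl], 0.5 * cd$I[k], tw_cost),
                   Atrav)
        acc <- acc + cd$prob[k] * combine_values(A, rule, temperature)
      }
      m <- matrix(acc, n_fat, n_fetal)
      m[Fg < floor_kg, ] <- 0
      if (any(!is.finite(m))) {
        bad <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
        stop("non-finite value at day ", t, " cell ", cl, " fat index ",
             bad[1L], " fetal index ", bad[2L])
      }
      Vt[, , cl] <- m
    }
    V[[t]] <- Vt
  }
  c(env, list(V = V))
}

# Collapse a state x action value matrix to the policy value under the
# configured behavior-probability rule.
combine_values <- function(A, rule, temperature) {
  m <- A[, 1L]
  for (j in 2:ncol(A)) m <- pmax(m, A[, j])
  if (rule == "argmax") return(m)
  W <- exp((A - m) / temperature)
  rowSums(W * A) / rowSums(W)
}

# Behavior probabilities for a state x action value matrix.
policy_probs <- function(A, rule, temperature, epsilon) {
  m <- A[, 1L]
  for (j in 2:ncol(A)) m <- pmax(m, A[, j])
  if (rule == "argmax") {
    P <- (A >= m - epsilon) * 1
  } else {
    P <- exp((A - m) / temperature)
  }
  P / rowSums(P)
}

# Action-value arrays for one solved length, day and cell, against the
# next-day value slice. Returns the leave vector, feed and travel-within
# matrices (states x categories), and the travel matrix (states x
# destinations). Shared by backward iteration consumers and the simulator.
action_value_set <- function(pol, il, day, cell) {
  e <- pol$per_length[[il]]
  season <- pol$season
  Vn <- e$V[[day + 1L]]
  p <- period_of_day(day, season)
  cd <- pol$intake[[p]][[cell]]
  fat_pts <- rep(e$Fg, times = e$n_fetal)
  g_pts <- rep(e$Gg, each = e$n_fat)
  fet_pts <- rep(e$fcg, each = e$n_fat)
  av <- function(Vc, I, tcost) {
    a <- alloc_core(fat_pts, g_pts, I, e$met, fet_pts, tcost, e$dG, e$L,
                    pol$params)
    v <- pol$day_survival * interp2(Vc, e$Fg, e$Gg, a$fat, a$G)
    v[a$dead] <- 0
    v
  }
  dests <- setdiff(1:11, cell)
  list(leave = e$Rvec,
       feed = vapply(seq_along(cd$I), function(k) av(Vn[, , cell], cd$I[k], 0),
                     numeric(e$n_fat * e$n_fetal)),
       tw = vapply(seq_along(cd$I),
                   function(k) av(Vn[, , cell], 0.5 * cd$I[k], pol$within_cost),
                   numeric(e$n_fat * e$n_fetal)),
       travel = vapply(dests, function(d) av(Vn[, , d], 0, pol$travel_cost[cell, d]),
                       numeric(e$n_fat * e$n_fetal)),
       dests = dests, prob = cd$prob)
}

#' Behavior probabilities for a continuous state
#'
#' Evaluates the four-action probability distribution (with the travel action
#' expanded per destination cell) for a female at an arbitrary fat mass and
#' fetal length: the behavior rule is applied at the four surrounding state
#' grid nodes and blended bilinearly, then renormalized. States outside the
#' grid hull are clamped with a warning.
#'
#' @param policy An [sdp_policy()] fit.
#' @param state List with `L` (m), `fat` (kg), `G` (m), `cell` (1-11) and
#'   `category` (prey-category index experienced in the current bin).
#' @param day Season day (1-based) whose policy governs the decision.
#' @return Named probability vector over `leave`, `feed`, `travel_within`,
#'   and `travel_to_<cell>`; sums to 1.
#' @export
action_probabilities <- function(policy, state, day) {
  stopifnot(inherits(policy, "sdp_policy"))
  il <- which.min(abs(policy$lengths - state$L))
  e <- policy$per_length[[il]]
  if (state$fat < e$Fg[1L] - 1e-9 || state$fat > e$Fg[e$n_fat] + 1e-9 ||
      state$G < e$Gg[1L] - 1e-9 || state$G > e$Gg[e$n_fetal] + 1e-9) {
    warning("state outside the grid hull; clamped")
  }
  fat <- min(max(state$fat, e$Fg[1L]), e$Fg[e$n_fat])
  G <- min(max(state$G, e$Gg[1L]), e$Gg[e$n_fetal])
  avs <- action_value_set(policy, il, day, state$cell)
  k <- state$category
  A <- cbind(avs$leave, avs$feed[, k], avs$tw[, k], avs$travel)
  P <- policy_probs(A, policy$rule, policy$temperature, policy$epsilon)
  i0 <- min(max(findInterval(fat, e$Fg), 1L), e$n_fat - 1L)
  j0 <- min(max(findInterval(G, e$Gg), 1L), e$n_fetal - 1L)
  wf <- (fat - e$Fg[i0]) / (e$Fg[i0 + 1L] - e$Fg[i0])
  wg <- (G - e$Gg[j0]) / (e$Gg[j0 + 1L] - e$Gg[j0])
  idx <- c((j0 - 1L) * e$n_fat + i0, (j0 - 1L) * e$n_fat + i0 + 1L,
           j0 * e$n_fat + i0, j0 * e$n_fat + i0 + 1L)
  w <- c((1 - wf) * (1 - wg), wf * (1 - wg), (1 - wf) * wg, wf * wg)
  pr <- drop(w %*% P[idx, , drop = FALSE])
  pr <- pr / sum(pr)
  names(pr) <- c("leave", "feed", "travel_within",
                 paste0("travel_to_", avs$dests))
  pr
}

#' Expected fitness for a continuous state
#'
#' Bilinear interpolation of the category-averaged value surface.
#' @inheritParams action_probabilities
#' @export
expected_fitness <- function(policy, state, day) {
  il <- which.min(abs(policy$lengths - state$L))
  e <- policy$per_length[[il]]
  interp2(e$V[[day]][, , state$cell], e$Fg, e$Gg, state$fat, state$G)
}

#' @export
print.sdp_policy <- function(x, ...) {
  cat("State-dependent policy (", x$fitness$variant, " fitness, L_min ",
      x$params$length_min, " m)\n", sep = "")
  cat("  grid:", x$n_fat, "fat x", x$n_fetal, "fetal nodes;",
      length(x$lengths), "solved lengths (",
      paste(round(x$lengths, 2), collapse = ", "), "m )\n")
  cat("  behavior rule:", x$rule,
      if (x$rule == "softmax") paste("(temperature", x$temperature, ")") else
        paste("(epsilon", x$epsilon, ")"), "\n")
  invisible(x)
}

#' @export
summary.sdp_policy <- function(object, ...) {
  v1 <- sapply(seq_along(object$lengths), function(i) {
    e <- object$per_length[[i]]
    max(e$V[[1L]])
  })
  cat("Maximum expected fitness at season start, by solved length:\n")
  print(round(stats::setNames(v1, paste0(round(object$lengths, 2), "m")), 3))
  invisible(v1)
}
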