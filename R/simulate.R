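# Seeded forward Monte-Carlo simulation of pregnant-female populations over
# the foraging season, with optional acoustic disturbance.

#' Simulate populations of pregnant females under a fitted policy
#'
#' Each female draws static parameters (length, starting fat and fetal
#' length, arrival date, entry cell) at the start of her replicate. Before
#' arrival she is outside the study area. In every 6-h bin while in-area she
#' (1) may be disturbed (relocation to the nearest undisturbed cell, travel
#' cost, no foraging for the bin); (2) otherwise draws one of the four
#' behavioral actions from the governing day's policy probabilities,
#' evaluated at her current fat mass, fetal length, cell and the prey
#' category she experiences this bin; (3) updates her energy state through
#' the prioritized allocation rule with per-bin travel/dive parameter draws;
#' and (4) survives background mortality. Leaving is absorbing; any female
#' still present at season end departs. Reproduction is a Bernoulli draw with
#' probability equal to the reproductive fitness of the departure state.
#'
#' Randomness is organised so that runs with and without disturbance are
#' coupled: every random stream is indexed by (replicate, day, bin, female)
#' rather than consumed sequentially, so identical seeds give identical
#' draws regardless of trajectory differences. Permuting replicate seeds
#' permutes replicate outputs.
#'
#' @param policy An [sdp_policy()] fit.
#' @param exposure Optional [exposure_series()]; `NULL` for the
#'   disturbance-free scenario.
#' @param n_pop Females per population replicate.
#' @param n_rep Number of population replicates.
#' @param seed Master seed.
#' @param arrival_mean_day,arrival_sd_days Arrival-date distribution in
#'   season days (the default mean, day 32, is June 15 for a May 15 start;
#'   sd 5 days).
#' @param start_cells Cells a newly arrived female may enter (uniform draw);
#'   default the coastal nearshore strip.
#' @param response_prob Probability an exposed whale responds.
#' @param trace Keep a per-bin energy ledger (intake and cost components) for
#'   every female; only allowed for small runs.
#' @return An object of class `sdp_sim`.
#' @seealso [occupancy_series()], [disturbed_proportion()],
#'   [reproduction_summary()]
#' @export
simulate_population <- function(policy, exposure = NULL, n_pop = 50L,
                                n_rep = 100L, seed = 1L,
                                arrival_mean_day = 32, arrival_sd_days = 5,
                                start_cells = c(1L, 3L, 5L, 7L),
                                response_prob = 1, trace = FALSE) {
  stopifnot(inherits(policy, "sdp_policy"))
  season <- policy$season
  cells <- policy$cells
  params <- policy$params
  if (!is.null(exposure)) {
    if (!inherits(exposure, "exposure_series")) stop("exposure must be an exposure_series")
    es <- attr(exposure, "season")
    if (es$n_bins != season$n_bins || !identical(es$start, season$start)) {
      stop("exposure series and policy use different season grids")
    }
    pexp <- unclass(exposure)
  } else {
    pexp <- NULL
  }
  n_pop <- as.integer(n_pop); n_rep <- as.integer(n_rep)
  M <- n_pop * n_rep
  if (trace && M > 400L) stop("trace = TRUE is meant for small diagnostic runs")
  n_bins <- season$n_bins; n_days <- season$n_days; bpd <- season$bins_per_day
  rep_seeds <- vapply(seq_len(n_rep), function(r) child_seed(seed, r), integer(1))
  rep_of <- rep(seq_len(n_rep), each = n_pop)

  # --- static per-female draws, one stream per replicate -------------------
  L <- fat <- G <- arr_day <- cell0 <- u_repro <- numeric(M)
  for (r in seq_len(n_rep)) {
    idx <- which(rep_of == r)
    with_local_seed(child_seed(rep_seeds[r], 0L), {
      uL <- stats::runif(n_pop); uf <- stats::runif(n_pop)
      ug <- stats::runif(n_pop); ua <- stats::runif(n_pop)
      uc <- stats::runif(n_pop); ur <- stats::runif(n_pop)
      L[idx] <- qtruncnorm(uL, params$length_mean, params$length_sd,
                           params$length_min, params$length_max)
      fat[idx] <- qtruncnorm(uf, params$start_fat_frac[1], params$start_fat_frac[2],
                             params$start_fat_frac[3], params$start_fat_frac[4]) *
        total_mass(L[idx], params)
      G[idx] <- qtruncnorm(ug, params$start_fetal_m[1], params$start_fetal_m[2],
                           params$start_fetal_m[3], params$start_fetal_m[4])
      arr_day[idx] <- pmin(pmax(round(stats::qnorm(ua, arrival_mean_day,
                                                   arrival_sd_days)), 1), n_days)
      cell0[idx] <- start_cells[1L + floor(uc * length(start_cells))]
      u_repro[idx] <- ur
    })
  }
  arrival_bin <- (arr_day - 1L) * bpd + 1L
  il <- vapply(L, function(x) which.min(abs(policy$lengths - x)), integer(1))
  met_bin <- metabolic_day(L, params) / bpd
  dG_bin <- params$fetal_growth_m_day / bpd
  s_bin <- bin_survival(params$annual_mortality, season$bin_hours)

  # status: 0 pre-arrival, 1 in-area, 2 departed, 3 dead
  status <- integer(M)
  cur_cell <- integer(M)
  dep_bin <- rep(NA_integer_, M)
  dep_fat <- rep(NA_real_, M); dep_G <- rep(NA_real_, M)
  occ <- matrix(0L, nrow = M, ncol = n_bins)
  dist_flag <- matrix(FALSE, nrow = M, ncol = n_bins)
  if (trace) {
    tr <- list(intake = matrix(0, M, n_bins), met = matrix(0, M, n_bins),
               fetal = matrix(0, M, n_bins), travel = matrix(0, M, n_bins),
               fat = matrix(NA_real_, M, n_bins), G = matrix(NA_real_, M, n_bins),
               dG = matrix(0, M, n_bins))
  }

  # prey category lookup per cell x period
  cat_tab <- lapply(c("early", "mid", "late"), function(p) {
    lapply(1:11, function(cl) {
      d <- policy$prey$cells[[cl]][[p]]
      list(values = d$values, cum = cumsum(d$prob))
    })
  })
  names(cat_tab) <- c("early", "mid", "late")

  n_act <- 13L
  trimat <- upper.tri(matrix(0, n_act, n_act), diag = TRUE)

  for (day in seq_len(n_days)) {
    per <- period_of_day(day, season)
    # per-day action-value cache, keyed by length index x cell
    av_cache <- new.env(parent = emptyenv())
    get_av <- function(i_l, cl) {
      key <- paste0(i_l, "_", cl)
      if (is.null(av_cache[[key]])) {
        av_cache[[key]] <- action_value_set(policy, i_l, day, cl)
      }
      av_cache[[key]]
    }
    # random draws for the day, indexed (female, bin-of-day, stream)
    U <- array(NA_real_, dim = c(M, bpd, 7L))
    for (r in seq_len(n_rep)) {
      idx <- which(rep_of == r)
      with_local_seed(child_seed(rep_seeds[r], day), {
        U[idx, , ] <- array(stats::runif(n_pop * bpd * 7L),
                            dim = c(n_pop, bpd, 7L))
      })
    }
    for (b in seq_len(bpd)) {
      bin <- (day - 1L) * bpd + b
      arrivals <- which(status == 0L & arrival_bin == bin)
      if (length(arrivals)) {
        status[arrivals] <- 1L
        cur_cell[arrivals] <- cell0[arrivals]
      }
      active <- which(status == 1L)
      if (!length(active)) next
      dive <- qtruncnorm(U[active, b, 5L], params$dive_frac[1], params$dive_frac[2],
                         params$dive_frac[3], params$dive_frac[4])
      speedf <- qtruncnorm(U[active, b, 6L], params$speed_kmh[1], params$speed_kmh[2],
                           params$speed_kmh[3], params$speed_kmh[4]) / params$ref_speed_kmh
      linr <- qtruncnorm(U[active, b, 7L], params$linearity[1], params$linearity[2],
                         params$linearity[3], params$linearity[4])
      intake <- numeric(length(active))
      travel <- numeric(length(active))
      disturbed <- rep(FALSE, length(active))
      leaving <- rep(FALSE, length(active))
      dest <- cur_cell[active]

      if (!is.null(pexp)) {
        pe <- pexp[cbind(cur_cell[active], bin)] * response_prob
        disturbed <- U[active, b, 1L] < pe
        if (any(disturbed)) {
          src <- unique(cur_cell[active][disturbed])
          dmap <- integer(11L)
          for (s in src) dmap[s] <- nearest_undisturbed(cells, s, pexp[, bin])
          dd <- dmap[cur_cell[active][disturbed]]
          travel[disturbed] <- cells$dist_km[cbind(cur_cell[active][disturbed], dd)] /
            linr[disturbed] * params$travel_MJ_km * speedf[disturbed]
          dest[disturbed] <- dd
        }
      }

      und <- which(!disturbed)
      if (length(und)) {
        gi <- active[und]
        grp <- split(seq_along(und), paste0(il[gi], "_", cur_cell[gi]))
        for (g in grp) {
          f <- gi[g]          # global indices
          lu <- und[g]        # indices into the active-local vectors
          i_l <- il[f[1L]]; cl <- cur_cell[f[1L]]
          e <- policy$per_length[[i_l]]
          avs <- get_av(i_l, cl)
          ct <- cat_tab[[per]][[cl]]
          k <- findInterval(U[f, b, 3L], ct$cum) + 1L
          k <- pmin(k, length(ct$values))
          fa <- pmin(pmax(fat[f], e$Fg[1L]), e$Fg[e$n_fat])
          gg <- pmin(pmax(G[f], e$Gg[1L]), e$Gg[e$n_fetal])
          i0 <- pmin(pmax(findInterval(fa, e$Fg), 1L), e$n_fat - 1L)
          j0 <- pmin(pmax(findInterval(gg, e$Gg), 1L), e$n_fetal - 1L)
          wf <- (fa - e$Fg[i0]) / (e$Fg[i0 + 1L] - e$Fg[i0])
          wg <- (gg - e$Gg[j0]) / (e$Gg[j0 + 1L] - e$Gg[j0])
          P <- 0
          for (corner in 1:4) {
            ic <- i0 + (corner == 2L | corner == 4L)
            jc <- j0 + (corner >= 3L)
            w <- switch(corner, (1 - wf) * (1 - wg), wf * (1 - wg),
                        (1 - wf) * wg, wf * wg)
            idxc <- (jc - 1L) * e$n_fat + ic
            A <- cbind(avs$leave[idxc],
                       avs$feed[cbind(idxc, k)],
                       avs$tw[cbind(idxc, k)],
                       avs$travel[idxc, , drop = FALSE])
            P <- P + w * policy_probs(A, policy$rule, policy$temperature,
                                      policy$epsilon)
          }
          P <- P / rowSums(P)
          act <- 1L + rowSums((P %*% trimat) < U[f, b, 2L])
          act <- pmin(act, n_act)
          Ek <- ct$values[k]
          feed_i <- act == 2L; tw_i <- act == 3L; trav_i <- act >= 4L
          intake[lu[feed_i]] <- Ek[feed_i] * dive[lu[feed_i]]
          intake[lu[tw_i]] <- 0.5 * Ek[tw_i] * dive[lu[tw_i]]
          travel[lu[tw_i]] <- params$within_cell_km / linr[lu[tw_i]] *
            params$travel_MJ_km * speedf[lu[tw_i]]
          if (any(trav_i)) {
            dcells <- avs$dests[act[trav_i] - 3L]
            travel[lu[trav_i]] <- cells$dist_km[cbind(cl, dcells)] /
              linr[lu[trav_i]] * params$travel_MJ_km * speedf[lu[trav_i]]
            dest[lu[trav_i]] <- dcells
          }
          leaving[lu[act == 1L]] <- TRUE
        }
      }

      # departures lock in the pre-bin state
      if (any(leaving)) {
        lf <- active[leaving]
        dep_bin[lf] <- bin
        dep_fat[lf] <- fat[lf]; dep_G[lf] <- G[lf]
        status[lf] <- 2L
      }
      stay <- active[!leaving]
      sl <- which(!leaving)
      if (length(stay)) {
        fc <- fetal_cost(G[stay], dG_bin, params)
        a <- alloc_core(fat[stay], G[stay], intake[sl], met_bin[stay], fc,
                        travel[sl], dG_bin, L[stay], params)
        if (trace) {
          tr$intake[cbind(stay, bin)] <- intake[sl]
          tr$met[cbind(stay, bin)] <- met_bin[stay]
          tr$fetal[cbind(stay, bin)] <- fc
          tr$travel[cbind(stay, bin)] <- travel[sl]
          tr$dG[cbind(stay, bin)] <- a$G - G[stay]
        }
        fat[stay] <- a$fat; G[stay] <- a$G
        cur_cell[stay] <- dest[sl]
        died <- stay[a$dead]
        # background mortality
        died <- union(died, stay[U[stay, b, 4L] > s_bin])
        if (length(died)) status[died] <- 3L
        alive_now <- stay[status[stay] == 1L]
        occ[cbind(alive_now, bin)] <- cur_cell[alive_now]
        dwh <- active[disturbed]
        dwh <- dwh[status[dwh] == 1L]
        if (length(dwh)) dist_flag[cbind(dwh, bin)] <- TRUE
        if (trace) {
          tr$fat[cbind(stay, bin)] <- fat[stay]
          tr$G[cbind(stay, bin)] <- G[stay]
        }
      }
    }
  }
  # season end: remaining females depart
  left <- which(status == 1L)
  if (length(left)) {
    dep_bin[left] <- n_bins
    dep_fat[left] <- fat[left]; dep_G[left] <- G[left]
    status[left] <- 2L
  }
  fit_dep <- rep(0, M)
  dp <- which(status == 2L)
  fit_dep[dp] <- reproductive_fitness(policy$fitness, L[dp], dep_fat[dp],
                                      dep_G[dp], params)
  success <- status == 2L & u_repro < fit_dep

  outcome <- data.frame(replicate = rep_of, female = rep(seq_len(n_pop), n_rep),
                        L = L, arrival_bin = arrival_bin,
                        status = c("outside", "in_area", "departed", "dead")[status + 1L],
                        departure_bin = dep_bin, departure_fat_kg = dep_fat,
                        fetal_len_m = dep_G, fitness = fit_dep,
                        success = success)
  out <- list(occupancy = occ, disturbed = if (is.null(pexp)) NULL else dist_flag,
              outcome = outcome, n_pop = n_pop, n_rep = n_rep,
              season = season, cells = cells, seed = seed,
              has_exposure = !is.null(pexp),
              trace = if (trace) tr else NULL)
  class(out) <- "sdp_sim"
  out
}

#' @rdname simulate_population
#' @param object An `sdp_policy` fit.
#' @param nsim Number of population replicates.
#' @param ... Passed to [simulate_population()].
#' @export
simulate.sdp_policy <- function(object, nsim = 100L, seed = 1L, ...) {
  simulate_population(object, n_rep = nsim, seed = seed, ...)
}

#' @export
print.sdp_sim <- function(x, ...) {
  rs <- reproduction_summary(x)
  cat("Forward simulation:", x$n_rep, "replicates x", x$n_pop, "females",
      if (x$has_exposure) "(with disturbance)" else "(no disturbance)", "\n")
  cat(sprintf("  reproduction: mean %.3f (sd %.3f across replicates)\n",
              rs$mean, rs$sd))
  cat("  fates:", paste(names(table(x$outcome$status)),
                        table(x$outcome$status), collapse = ", "), "\n")
  invisible(x)
}

#' Occupancy proportions by area and cell
#'
#' Per-bin proportions of the population in the nearshore area (cells 1-7),
#' the offshore area (cells 8-11), or outside (not yet arrived, departed, or
#' dead); the three always partition the population. Weekly pooling averages
#' each replicate's 28 bins per week; across-replicate means and standard
#' deviations are attached.
#'
#' @param sim An `sdp_sim` result.
#' @return List with `area_bin` (array replicate x bin x area), `area_week`
#'   (replicate x week x area), `cell_week` (replicate x week x cell), and a
#'   `weekly` data frame of across-replicate summaries.
#' @export
occupancy_series <- function(sim) {
  stopifnot(inherits(sim, "sdp_sim"))
  n_bins <- sim$season$n_bins; n_weeks <- sim$season$n_weeks
  n_rep <- sim$n_rep; n_pop <- sim$n_pop
  rep_of <- rep(seq_len(n_rep), each = n_pop)
  area_bin <- array(0, dim = c(n_rep, n_bins, 3L),
                    dimnames = list(NULL, NULL, c("nearshore", "offshore", "outside")))
  cell_week <- array(0, dim = c(n_rep, n_weeks, 11L))
  wk <- rep(seq_len(n_weeks), each = 7L * sim$season$bins_per_day)
  for (r in seq_len(n_rep)) {
    o <- sim$occupancy[rep_of == r, , drop = FALSE]
    near <- colSums(o >= 1L & o <= 7L) / n_pop
    off <- colSums(o >= 8L) / n_pop
    area_bin[r, , 1L] <- near
    area_bin[r, , 2L] <- off
    area_bin[r, , 3L] <- 1 - near - off
    for (cl in 1:11) {
      cw <- colSums(o == cl) / n_pop
      cell_week[r, , cl] <- tapply(cw, wk, mean)
    }
  }
  area_week <- array(0, dim = c(n_rep, n_weeks, 3L),
                     dimnames = list(NULL, NULL, c("nearshore", "offshore", "outside")))
  for (a in 1:3) {
    for (r in seq_len(n_rep)) {
      area_week[r, , a] <- tapply(area_bin[r, , a], wk, mean)
    }
  }
  weekly <- do.call(rbind, lapply(c("nearshore", "offshore", "outside"), function(a) {
    m <- matrix(area_week[, , a], nrow = n_rep)
    data.frame(week = seq_len(n_weeks), area = a,
               mean = colMeans(m), sd = apply(m, 2, stats::sd))
  }))
  rownames(weekly) <- NULL
  list(area_bin = area_bin, area_week = area_week, cell_week = cell_week,
       weekly = weekly)
}

#' Proportion of the population disturbed per 6-h bin
#'
#' @param sim An `sdp_sim` run that included an exposure series.
#' @return List with `bin` (replicate x bin proportions) and `weekly`
#'   (replicate x week means), plus across-replicate summary columns.
#' @export
disturbed_proportion <- function(sim) {
  stopifnot(inherits(sim, "sdp_sim"))
  if (!sim$has_exposure) stop("simulation was run without an exposure series")
  n_rep <- sim$n_rep; n_pop <- sim$n_pop
  rep_of <- rep(seq_len(n_rep), each = n_pop)
  n_weeks <- sim$season$n_weeks
  wk <- rep(seq_len(n_weeks), each = 7L * sim$season$bins_per_day)
  pb <- t(vapply(seq_len(n_rep), function(r) {
    colSums(sim$disturbed[rep_of == r, , drop = FALSE]) / n_pop
  }, numeric(sim$season$n_bins)))
  pw <- t(apply(pb, 1, function(v) tapply(v, wk, mean)))
  list(bin = pb, weekly = pw,
       weekly_mean = colMeans(pw), weekly_sd = apply(pw, 2, stats::sd))
}

#' Per-replicate reproduction summary
#'
#' Proportion of each replicate's females that successfully reproduced (gave
#' birth and returned with a calf), with across-replicate mean and sd.
#' @param sim An `sdp_sim` result.
#' @export
reproduction_summary <- function(sim) {
  stopifnot(inherits(sim, "sdp_sim"))
  per_rep <- tapply(sim$outcome$success, sim$outcome$replicate, mean)
  list(per_replicate = as.numeric(per_rep), mean = mean(per_rep),
       sd = stats::sd(per_rep), n = sim$n_rep)
}
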