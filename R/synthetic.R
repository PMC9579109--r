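# Seeded generators for every input the pipeline consumes: prey surveys,
# seismic acoustic block grids, photo-ID day records, scan-survey block
# densities, and a calving roster. Each generator is the measurable inverse
# of its fitting stage, so fit-recovery tests close the loop without any
# field download. All outputs are synthetic stand-ins for the 2015 field and
# acoustic data streams.

#' Scenario ground truth for the synthetic generators
#'
#' Bundles every "true" parameter the generators draw from: lognormal prey
#' energy per cell and period (offshore richer than nearshore, cell 11
#' richest, nearshore declining over the season), a seismic-survey plan
#' (nearshore track early, then a long occupation near offshore cells 8-9),
#' spreading-loss acoustics, and the true regression coefficients for the
#' zero-inflated beta, hurdle-gamma and logistic generators.
#'
#' @param seed Master seed stored with the truth.
#' @return A `scenario_truth` list.
#' @export
scenario_truth <- function(seed = 1L) {
  prey <- expand.grid(cell = 1:11, period = c("early", "mid", "late"),
                      stringsAsFactors = FALSE)
  mean_tab <- rbind(
    c(500, 340, 240),   # 1 coastal
    c(430, 300, 220),   # 2
    c(560, 380, 270),   # 3 coastal, Piltun mouth
    c(430, 300, 220),   # 4
    c(500, 340, 240),   # 5 coastal
    c(430, 300, 220),   # 6
    c(500, 340, 240),   # 7 coastal
    c(1450, 1550, 1600),  # 8
    c(1500, 1600, 1650),  # 9
    c(1550, 1650, 1700),  # 10
    c(1650, 1750, 1850))  # 11 richest
  prey$mean_MJ <- mean_tab[cbind(prey$cell, match(prey$period, c("early", "mid", "late")))]
  prey$sigma_log <- ifelse(prey$cell <= 7, 0.35, 0.30)
  prey$mu_log <- log(prey$mean_MJ) - prey$sigma_log^2 / 2

  list(
    prey = prey,
    acoustic = list(source_level_db = 240, loss_coef = 20, noise_sd = 2,
                    window_min = 30, active_bins = c(2L, 3L),
                    nearshore_weeks = 5:8, offshore_weeks = 9:14,
                    blocks_nearshore = 8L, blocks_offshore = 4L),
    zib = list(alpha = c(0.8, 0.5, -0.35, 0.5, -0.4),
               mu = c(-1.2, 0.3, -0.15, -0.3, -0.2),
               phi = 12),
    hurdle = list(
      alpha_int = c(0.0, -2.5, 1.0, -0.3, 0.8, -0.5, 0.2),
      alpha_week = c(-0.3, -0.4, 0.1), # week, week2, week3
      alpha_coverage = 1.2,
      mu_int = log(c(0.08, 0.01, 0.15, 0.03, 0.12, 0.03, 0.05)),
      mu_week = c(-0.2, -0.15, 0.05),
      omega = 2),
    ppreg = c(-1.0, -0.35, 0.25, -0.10, 0.30), # int, week, week2, beaufort, vis
    week_center = 13, week_scale = 7,
    env = list(beaufort = c(2, 1, 0, 5), visibility = c(0.8, 0.15, 0.3, 1)),
    roster = list(n_females = 27L, years = 2008:2016, calve_prob = 0.35),
    seed = as.integer(seed))
}

#' Generate a benthic prey-energy survey
#'
#' Lognormal draws of available prey energy (MJ per 6-h bout) per cell and
#' period, suitable for [fit_prey_lognormal()].
#'
#' @param truth A [scenario_truth()].
#' @param n_samples Samples per cell x period stratum (>= 2).
#' @param seed RNG seed (defaults to the truth's).
#' @export
gen_prey_survey <- function(truth, n_samples = 40L, seed = truth$seed) {
  stopifnot(n_samples >= 2L)
  with_local_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(truth$prey)), function(i) {
      r <- truth$prey[i, ]
      data.frame(cell = r$cell, period = r$period,
                 energy_MJ = stats::rlnorm(n_samples, r$mu_log, r$sigma_log))
    }))
    rownames(out) <- NULL
    out
  })
}

#' Generate a seismic-survey acoustic block grid
#'
#' A moving airgun source follows the truth's survey plan (a nearshore pass
#' in the early weeks, then a longer occupation near offshore cells 8-9).
#' Each cell holds fixed blocks (1 km^2 nominal nearshore, 100 km^2
#' offshore); during active bins every block-window receives
#' `max SPL = SL - loss * log10(r_m) + noise` with the range in metres from
#' the source to the block centroid. Windows outside survey activity are not
#' emitted, so off-survey bins have zero exposure.
#'
#' @param truth A [scenario_truth()].
#' @param cells A [build_study_area()] map.
#' @param season A [season_grid()].
#' @param seed RNG seed.
#' @return Data frame with `block_id`, `cell`, `area_km2`, `timestamp`
#'   (POSIXct UTC), `max_spl_db`.
#' @export
gen_acoustic_field <- function(truth, cells, season, seed = truth$seed) {
  ac <- truth$acoustic
  with_local_seed(seed, {
    tab <- cells$table
    blocks <- do.call(rbind, lapply(1:11, function(cl) {
      nb <- if (cl <= 7) ac$blocks_nearshore else ac$blocks_offshore
      half <- sqrt(tab$area_km2[cl]) / 2
      data.frame(block_id = paste0(cl, "_", seq_len(nb)), cell = cl,
                 area_km2 = if (cl <= 7) 1 else 100,
                 bx = tab$x_km[cl] + stats::runif(nb, -half, half),
                 by = tab$y_km[cl] + stats::runif(nb, -half, half))
    }))
    near_days <- ((min(ac$nearshore_weeks) - 1L) * 7L + 1L):(max(ac$nearshore_weeks) * 7L)
    off_days <- ((min(ac$offshore_weeks) - 1L) * 7L + 1L):(max(ac$offshore_weeks) * 7L)
    src <- rbind(
      data.frame(day = near_days, x = 6,
                 y = seq(5, 35, length.out = length(near_days))),
      data.frame(day = off_days, x = 30,
                 y = 43 + 5 * sin(seq(0, 4 * pi, length.out = length(off_days)))))
    src <- src[src$day <= season$n_days, , drop = FALSE]
    origin <- as.POSIXct(paste(season$start, "00:00:00"), tz = "UTC")
    wpb <- as.integer(season$bin_hours * 60 / ac$window_min)
    recs <- vector("list", nrow(src))
    for (i in seq_len(nrow(src))) {
      d <- src$day[i]
      r_km <- sqrt((blocks$bx - src$x[i])^2 + (blocks$by - src$y[i])^2)
      base <- ac$source_level_db - ac$loss_coef * log10(pmax(r_km * 1000, 1))
      per_bin <- lapply(ac$active_bins, function(b) {
        t0 <- origin + ((d - 1) * 24 + (b - 1) * season$bin_hours) * 3600
        data.frame(
          block_id = rep(blocks$block_id, each = wpb),
          cell = rep(blocks$cell, each = wpb),
          area_km2 = rep(blocks$area_km2, each = wpb),
          timestamp = rep(t0 + (seq_len(wpb) - 1L) * ac$window_min * 60,
                          times = nrow(blocks)),
          max_spl_db = rep(base, each = wpb) +
            stats::rnorm(wpb * nrow(blocks), 0, ac$noise_sd))
      })
      recs[[i]] <- do.call(rbind, per_bin)
    }
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    out
  })
}

#' Generate photo-identification day records
#'
#' Surveyed days draw environmental covariates, compute the true
#' zero-inflated-beta linear predictors on the standardized-week scale, and
#' draw the daily proportion of the group seen nearshore: zero with
#' probability `1 - alpha`, otherwise beta with mean `mu` and precision
#' `phi`. Counts (`n_seen`) are the proportion discretised to the group
#' size; the continuous proportion is kept in `p_near`.
#'
#' @param truth A [scenario_truth()].
#' @param season A [season_grid()].
#' @param n_days Surveyed days.
#' @param n_group Group size (8 known pregnant, 18 all potentially
#'   pregnant).
#' @param seed RNG seed.
#' @export
gen_photoid <- function(truth, season, n_days = 99L, n_group = 18L,
                        seed = truth$seed) {
  with_local_seed(seed, {
    first <- 18L  # photo-ID effort starts about two and a half weeks in
    last <- min(season$n_days, 139L)
    pool <- first:last
    days <- sort(sample(pool, n_days, replace = n_days > length(pool)))
    week <- (days - 1L) %/% 7L + 1L
    bf <- rtruncnorm(length(days), truth$env$beaufort[1], truth$env$beaufort[2],
                     truth$env$beaufort[3], truth$env$beaufort[4])
    vis <- rtruncnorm(length(days), truth$env$visibility[1], truth$env$visibility[2],
                      truth$env$visibility[3], truth$env$visibility[4])
    X <- pid_design(week, bf, vis, truth$week_center, truth$week_scale)
    a <- stats::plogis(drop(X %*% truth$zib$alpha))
    m <- stats::plogis(drop(X %*% truth$zib$mu))
    pos <- stats::runif(length(days)) < a
    p <- numeric(length(days))
    p[pos] <- stats::rbeta(sum(pos), m[pos] * truth$zib$phi,
                           (1 - m[pos]) * truth$zib$phi)
    p <- pmin(p, 1 - 1e-9)
    data.frame(day = days, week = week, surveyed = TRUE, beaufort = bf,
               visibility = vis, p_near = p,
               n_seen = pmin(round(p * n_group), n_group), n_group = n_group)
  })
}

#' Generate scan-survey block density records
#'
#' Per survey and nearshore cell: a coverage fraction is drawn, the
#' cell-level density comes from the truth's hurdle-gamma model (week
#' polynomial per cell, coverage in the hurdle), and the implied count is
#' split across covered 1-km^2 blocks (the last block is pre-split into two
#' half-area records, exercising the boundary-block convention). Aggregating
#' the blocks recovers the cell density exactly.
#'
#' @param truth A [scenario_truth()].
#' @param cells A [build_study_area()] map.
#' @param season A [season_grid()].
#' @param n_surveys Number of scan surveys across the season.
#' @param cells_covered Cells to survey (nearshore by default).
#' @param blocks_per_cell Notional 1-km^2 blocks per cell.
#' @param seed RNG seed.
#' @export
gen_scan_surveys <- function(truth, cells, season, n_surveys = 300L,
                             cells_covered = 1:7, blocks_per_cell = 20L,
                             seed = truth$seed) {
  h <- truth$hurdle
  with_local_seed(seed, {
    days <- sort(sample(seq_len(season$n_days), n_surveys, replace = TRUE))
    week <- (days - 1L) %/% 7L + 1L
    w <- (week - truth$week_center) / truth$week_scale
    rows <- list()
    for (i in seq_len(n_surveys)) {
      for (cl in cells_covered) {
        coverage <- stats::rbeta(1, 5, 2)
        eta_a <- h$alpha_int[cl] + sum(h$alpha_week * c(w[i], w[i]^2, w[i]^3)) +
          h$alpha_coverage * coverage
        alpha <- stats::plogis(eta_a)
        mu <- exp(h$mu_int[cl] + sum(h$mu_week * c(w[i], w[i]^2, w[i]^3)))
        D <- if (stats::runif(1) < alpha) {
          stats::rgamma(1, shape = h$omega, rate = h$omega / mu)
        } else 0
        n_cov <- max(1L, round(coverage * blocks_per_cell))
        areas <- c(rep(1, n_cov - 1L), 0.5, 0.5)  # last block pre-split
        wts <- stats::rgamma(length(areas), 1, 1)
        Ntot <- D * sum(areas)
        Nj <- Ntot * wts / sum(wts)
        rows[[length(rows) + 1L]] <- data.frame(
          survey_id = i, day = days[i], week = week[i], cell = cl,
          block_id = paste0(i, "_", cl, "_", seq_along(areas)),
          D = Nj / areas, area_km2 = areas, coverage = coverage)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate daily pregnant-fraction count records
#'
#' Inverse of [fit_ppreg()]: daily identified-whale totals with the number of
#' pregnant females binomial in the truth's logistic model.
#'
#' @inheritParams gen_photoid
#' @export
gen_ppreg_counts <- function(truth, season, n_days = 99L, seed = truth$seed) {
  with_local_seed(seed, {
    pool <- 18:min(season$n_days, 139L)
    days <- sort(sample(pool, n_days, replace = n_days > length(pool)))
    week <- (days - 1L) %/% 7L + 1L
    bf <- rtruncnorm(length(days), truth$env$beaufort[1], truth$env$beaufort[2],
                     truth$env$beaufort[3], truth$env$beaufort[4])
    vis <- rtruncnorm(length(days), truth$env$visibility[1], truth$env$visibility[2],
                      truth$env$visibility[3], truth$env$visibility[4])
    w <- (week - truth$week_center) / truth$week_scale
    X <- cbind(1, w, w^2, bf, vis)
    p <- stats::plogis(drop(X %*% truth$ppreg))
    n_tot <- 3L + stats::rpois(length(days), 8)
    data.frame(day = days, week = week, beaufort = bf, visibility = vis,
               n_total = n_tot, n_preg = stats::rbinom(length(days), n_tot, p))
  })
}

#' Generate a calving roster with a two-year inter-birth interval
#'
#' Each reproductive female calves with the truth's annual probability in
#' any year where she did not calve the year before, so no female ever has
#' calves in consecutive years.
#'
#' @param truth A [scenario_truth()].
#' @param seed RNG seed.
#' @return Data frame with `female_id` and `calf_years` (semicolon list).
#' @export
gen_roster <- function(truth, seed = truth$seed) {
  r <- truth$roster
  with_local_seed(seed, {
    out <- lapply(seq_len(r$n_females), function(f) {
      yrs <- integer(0)
      for (y in r$years) {
        if (length(yrs) && y - yrs[length(yrs)] < 2L) next
        if (stats::runif(1) < r$calve_prob) yrs <- c(yrs, y)
      }
      data.frame(female_id = f,
                 calf_years = paste(yrs, collapse = ";"))
    })
    do.call(rbind, out)
  })
}

#' Count roster calves and compute the reproductive rate
#'
#' @param roster A [gen_roster()] table.
#' @param year1,year2 Consecutive calendar years.
#' @return List with the counts and the [reproductive_rate()].
#' @export
roster_rate <- function(roster, year1, year2) {
  yrs <- lapply(strsplit(roster$calf_years, ";", fixed = TRUE),
                function(s) as.integer(s[nzchar(s)]))
  c1 <- sum(vapply(yrs, function(v) year1 %in% v, logical(1)))
  c2 <- sum(vapply(yrs, function(v) year2 %in% v, logical(1)))
  list(n_females = nrow(roster), calves_year1 = c1, calves_year2 = c2,
       rate = reproductive_rate(nrow(roster), c1, c2))
}
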