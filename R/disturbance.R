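# Acoustic disturbance: block-level SPL grids -> per-cell exposure
# probabilities per 6-h bin, and the behavioral response rule.

#' Per-cell exposure probability from an acoustic block grid
#'
#' A block counts as disturbed within a 6-h bin if any of its 5-min (or
#' coarser) windows in that bin has a maximum sound pressure level at or above
#' the threshold (the comparison is inclusive: exactly 163.0 dB is exposure).
#' The cell-bin exposure probability is the fraction of blocks with data in
#' that cell and bin that are disturbed; cell-bins with no acoustic data have
#' probability zero.
#'
#' @param grid Data frame of acoustic records with columns `block_id`,
#'   `cell`, `area_km2`, `timestamp` (`POSIXct` or ISO-8601 character, UTC)
#'   and `max_spl_db` (dB re 1 uPa^2 SPL over the window).
#' @param cells A [build_study_area()] map.
#' @param season A [season_grid()].
#' @param threshold Disturbance threshold, dB re 1 uPa^2 SPL (163).
#' @return An `exposure_series` object: an 11 x `n_bins` probability matrix
#'   with the season attached.
#' @export
exposure_probability <- function(grid, cells, season, threshold = 163) {
  stopifnot(inherits(cells, "whale_cells"), inherits(season, "season_grid"))
  need <- c("block_id", "cell", "timestamp", "max_spl_db")
  miss <- setdiff(need, names(grid))
  if (length(miss)) stop("acoustic grid missing columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(grid$max_spl_db))) stop("non-finite SPL value in acoustic grid")
  unknown <- setdiff(unique(grid$cell), cells$table$id)
  if (length(unknown)) {
    stop("acoustic block mapped to unknown cell: ", paste(unknown, collapse = ", "))
  }
  ts <- grid$timestamp
  if (!inherits(ts, "POSIXct")) ts <- as.POSIXct(ts, tz = "UTC")
  origin <- as.POSIXct(paste(season$start, "00:00:00"), tz = "UTC")
  hrs <- as.numeric(difftime(ts, origin, units = "hours"))
  bin <- floor(hrs / season$bin_hours) + 1L
  keep <- bin >= 1L & bin <= season$n_bins
  p <- matrix(0, nrow = 11L, ncol = season$n_bins)
  if (any(keep)) {
    g <- data.frame(cell = grid$cell[keep], block = grid$block_id[keep],
                    bin = bin[keep], hit = grid$max_spl_db[keep] >= threshold)
    # any window >= threshold marks the block for that bin
    agg <- stats::aggregate(hit ~ cell + block + bin, data = g, FUN = any)
    num <- stats::aggregate(hit ~ cell + bin, data = agg, FUN = sum)
    den <- stats::aggregate(hit ~ cell + bin, data = agg, FUN = length)
    p[cbind(num$cell, num$bin)] <- num$hit / den$hit
  }
  structure(p, class = "exposure_series", season = season,
            threshold = threshold)
}

#' Build an exposure series directly from probabilities
#'
#' Convenience constructor for scenario experiments (e.g., exposure confined
#' to chosen cells and weeks).
#' @param p 11 x `n_bins` matrix of exposure probabilities in `[0, 1]`.
#' @param season A [season_grid()].
#' @param threshold Nominal threshold recorded with the series.
#' @export
exposure_series <- function(p, season, threshold = 163) {
  p <- as.matrix(p)
  stopifnot(nrow(p) == 11L, ncol(p) == season$n_bins,
            all(p >= 0), all(p <= 1))
  structure(unname(p), class = "exposure_series", season = season,
            threshold = threshold)
}

#' @export
print.exposure_series <- function(x, ...) {
  act <- colSums(unclass(x)) > 0
  cat("Exposure series: threshold", attr(x, "threshold"), "dB;",
      sum(act), "of", ncol(x), "bins with nonzero exposure\n")
  if (any(act)) {
    cat("  peak cell probabilities:",
        paste(round(apply(unclass(x), 1, max), 2), collapse = " "), "\n")
  }
  invisible(x)
}

#' Nearest undisturbed cell
#'
#' Destination of the behavioral response: the first cell in the current
#' cell's neighbor order with zero exposure in the bin; if every candidate is
#' exposed, the cell with minimal exposure (ties broken by neighbor order,
#' then ascending id for cells beyond the neighbor list). Cells 8 and 9 are
#' each other's first neighbor in the default map.
#'
#' @param cells A [build_study_area()] map.
#' @param cell Current cell id.
#' @param p_bin Numeric vector of length 11: exposure probability of every
#'   cell in the bin.
#' @return Destination cell id.
#' @export
nearest_undisturbed <- function(cells, cell, p_bin) {
  stopifnot(length(p_bin) == 11L)
  cand <- c(cells$neighbors[[as.character(cell)]],
            setdiff(1:11, c(cell, cells$neighbors[[as.character(cell)]])))
  clear <- cand[p_bin[cand] == 0]
  if (length(clear)) return(clear[1L])
  cand[which.min(p_bin[cand])]
}

#' Apply the disturbance response rule to one female for one bin
#'
#' With probability `p_exposure(cell, bin) * response_prob` the female is
#' disturbed: she relocates to the nearest undisturbed cell, pays the travel
#' cost, and forfeits the foraging opportunity for the 6-h bin. Otherwise the
#' state is returned unchanged.
#'
#' @param state List with `L`, `fat`, `G`, `cell`, `status`.
#' @param exposure An [exposure_series()].
#' @param bin Bin index.
#' @param cells A [build_study_area()] map.
#' @param params A [bioenergetics_params()] set.
#' @param response_prob Probability a whale exposed above threshold responds
#'   (default 1, the conservative assumption; 0.1 reflects the originating
#'   behavioral-response study).
#' @param u Optional uniform variate for the exposure draw (reproducible
#'   coupling); default drawn from the session RNG.
#' @return List with the (possibly updated) `state` and logical `disturbed`.
#' @export
apply_disturbance <- function(state, exposure, bin, cells,
                              params = bioenergetics_params(),
                              response_prob = 1, u = NULL) {
  stopifnot(state$status == "alive", state$cell %in% 1:11)
  p <- unclass(exposure)[state$cell, bin] * response_prob
  if (is.null(u)) u <- stats::runif(1)
  if (u >= p) return(list(state = state, disturbed = FALSE))
  dest <- nearest_undisturbed(cells, state$cell, unclass(exposure)[, bin])
  dist <- cells$dist_km[state$cell, dest]
  tcost <- dist / params$linearity[1] * params$travel_MJ_km
  season_bins <- 4
  met_bin <- metabolic_day(state$L, params) / season_bins
  dG_bin <- params$fetal_growth_m_day / season_bins
  fc <- fetal_cost(state$G, dG_bin, params)
  st <- allocate_energy(state,
                        list(intake = 0, metabolic_need = met_bin,
                             fetal_growth_cost = fc, travel_cost = tcost),
                        dG = dG_bin, params = params)
  st$cell <- dest
  list(state = st, disturbed = TRUE)
}
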