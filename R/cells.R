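# Study area: the 11 feeding cells and the season calendar.

#' Build and validate the feeding-cell map
#'
#' The Sakhalin feeding grounds are modeled as 11 abstract cells: seven
#' nearshore (of which cells 1, 3, 5 and 7 are the coastal strip monitored by
#' shore-based surveys) and four offshore (cells 8-11). Each cell carries an
#' area, planar centroid coordinates (used only for travel distances), and an
#' ordered neighbor list defining "next closest cell" semantics for the
#' disturbance-response rule. Cells 8 and 9 must be each other's first
#' neighbor.
#'
#' @param config A data frame with columns `id`, `zone` ("nearshore" or
#'   "offshore"), `coastal` (logical), `area_km2`, `x_km`, `y_km`, and
#'   `neighbors` (semicolon-separated ids in proximity order), or the path of
#'   a CSV/YAML file holding those columns. `NULL` uses the packaged default
#'   geometry.
#' @return An object of class `whale_cells`: the validated table plus a
#'   travel-distance matrix between cell centroids.
#' @examples
#' cells <- build_study_area()
#' table(cells$table$zone)
#' @export
build_study_area <- function(config = NULL) {
  if (is.null(config)) {
    config <- system.file("extdata", "cells_default.csv", package = "graywhaleSDP")
  }
  if (is.character(config)) config <- read_cell_table(config)
  tab <- as.data.frame(config, stringsAsFactors = FALSE)
  need <- c("id", "zone", "coastal", "area_km2", "x_km", "y_km", "neighbors")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("cell config is missing columns: ", paste(miss, collapse = ", "))
  tab$id <- as.integer(tab$id)
  tab$coastal <- as.logical(tab$coastal)
  if (anyDuplicated(tab$id)) {
    stop("duplicate cell id(s): ", paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  }
  bad <- tab$id[!tab$id %in% 1:11]
  if (length(bad)) stop("cell id out of range 1-11: ", paste(bad, collapse = ", "))
  if (nrow(tab) != 11L) stop("expected 11 cells, got ", nrow(tab))
  tab <- tab[order(tab$id), , drop = FALSE]
  rownames(tab) <- NULL
  near <- tab$id[tab$zone == "nearshore"]
  off <- tab$id[tab$zone == "offshore"]
  if (!identical(near, 1:7) || !identical(off, 8:11)) {
    stop("zones must be nearshore for cells 1-7 and offshore for cells 8-11")
  }
  if (!identical(tab$id[tab$coastal], c(1L, 3L, 5L, 7L))) {
    stop("coastal flag must mark exactly cells 1, 3, 5, 7")
  }
  nb <- lapply(strsplit(as.character(tab$neighbors), ";", fixed = TRUE),
               function(s) as.integer(trimws(s)))
  names(nb) <- tab$id
  for (i in tab$id) {
    ni <- nb[[as.character(i)]]
    if (length(ni) < 1L || anyNA(ni)) stop("cell ", i, " has an empty or malformed neighbor list")
    if (any(!ni %in% tab$id) || i %in% ni) stop("cell ", i, " lists an invalid neighbor")
    for (j in ni) {
      if (!i %in% nb[[as.character(j)]]) {
        stop("asymmetric neighbor relation: cell ", i, " lists cell ", j,
             " but not vice versa")
      }
    }
  }
  if (nb[["8"]][1L] != 9L || nb[["9"]][1L] != 8L) {
    stop("cells 8 and 9 must be each other's first neighbor (cell 8 first neighbor: ",
         nb[["8"]][1L], ")")
  }
  dm <- as.matrix(stats::dist(cbind(tab$x_km, tab$y_km)))
  dimnames(dm) <- list(tab$id, tab$id)
  structure(list(table = tab, neighbors = nb, dist_km = dm),
            class = "whale_cells")
}

read_cell_table <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML cell maps requires the 'yaml' package")
    }
    lst <- yaml::read_yaml(path)
    do.call(rbind, lapply(lst, function(cl) {
      data.frame(id = cl$id, zone = cl$zone, coastal = cl$coastal,
                 area_km2 = cl$area_km2, x_km = cl$x_km, y_km = cl$y_km,
                 neighbors = paste(cl$neighbors, collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}

#' Write a cell map back to CSV
#'
#' Round-trips bit-identically through [build_study_area()].
#' @param cells A `whale_cells` object.
#' @param path Output CSV path.
#' @export
write_cell_table <- function(cells, path) {
  stopifnot(inherits(cells, "whale_cells"))
  utils::write.csv(cells$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.whale_cells <- function(x, ...) {
  cat("Feeding-cell map: 11 cells (7 nearshore / 4 offshore),",
      sum(x$table$coastal), "coastal\n")
  cat("Total area:", round(sum(x$table$area_km2)), "km^2\n")
  invisible(x)
}

#' Season calendar for the foraging grounds
#'
#' The season opens in mid-May and spans up to 25 weeks, discretized into 6-h
#' bins (28 per week). Each week maps to one of three prey periods (early,
#' mid, late); the default splits the season into equal thirds.
#'
#' @param start Season start date (`Date`), default 15 May.
#' @param n_weeks Season length in weeks.
#' @param bin_hours Bin width in hours; the model is built around 6.
#' @param periods Optional integer/character vector of length `n_weeks` giving
#'   each week's period ("early", "mid", "late").
#' @return A `season_grid` object.
#' @export
season_grid <- function(start = as.Date("2015-05-15"), n_weeks = 25L,
                        bin_hours = 6L, periods = NULL) {
  n_weeks <- as.integer(n_weeks)
  stopifnot(n_weeks >= 1L, bin_hours == 6L)
  bins_per_day <- 24L %/% bin_hours
  n_days <- n_weeks * 7L
  n_bins <- n_weeks * 7L * bins_per_day
  if (is.null(periods)) {
    periods <- c("early", "mid", "late")[ceiling(3 * seq_len(n_weeks) / n_weeks)]
  }
  periods <- match.arg(as.character(periods), c("early", "mid", "late"),
                       several.ok = TRUE)
  if (length(periods) != n_weeks) stop("periods must have one entry per week")
  structure(list(start = start, n_weeks = n_weeks, n_days = n_days,
                 n_bins = n_bins, bin_hours = bin_hours,
                 bins_per_day = bins_per_day, periods = periods),
            class = "season_grid")
}

#' @export
print.season_grid <- function(x, ...) {
  cat("Season:", format(x$start), "+", x$n_weeks, "weeks (", x$n_bins,
      "six-hour bins); periods:",
      paste(rle(x$periods)$values, rle(x$periods)$lengths, collapse = " "), "\n")
  invisible(x)
}

#' Map a 6-h bin to its season week / prey period / day
#'
#' Bins are 1-based; bin 1 is the first 6 hours of the season.
#' @param bin Bin index (vectorised).
#' @param season A [season_grid()].
#' @return `period_of`: factor level "early"/"mid"/"late". `week_of_bin` and
#'   `day_of_bin`: integer indices within the season.
#' @export
period_of <- function(bin, season) {
  season$periods[week_of_bin(bin, season)]
}

#' @rdname period_of
#' @export
week_of_bin <- function(bin, season) {
  bin <- as.integer(bin)
  if (any(bin < 1L | bin > season$n_bins)) {
    stop("bin index outside the season (1..", season$n_bins, ")")
  }
  (bin - 1L) %/% (7L * season$bins_per_day) + 1L
}

#' @rdname period_of
#' @export
day_of_bin <- function(bin, season) {
  bin <- as.integer(bin)
  if (any(bin < 1L | bin > season$n_bins)) {
    stop("bin index outside the season (1..", season$n_bins, ")")
  }
  (bin - 1L) %/% season$bins_per_day + 1L
}

# Period of a season day (backward iteration works on the daily grid).
period_of_day <- function(day, season) {
  season$periods[(as.integer(day) - 1L) %/% 7L + 1L]
}
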