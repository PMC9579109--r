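# Stochastic prey-energy field: lognormal fits per cell x period and their
# discretization into equally spaced categories for the dynamic program.

#' Fit lognormal prey-energy distributions per cell and period
#'
#' Daily available prey energy (MJ per 6-h foraging bout) in each cell and
#' season period is modeled as lognormal. The fit is maximum likelihood on the
#' log scale: `mu_log` is the mean and `sigma_log` the population (n
#' denominator) standard deviation of the log samples.
#'
#' @param samples Data frame with columns `cell`, `period`, `energy_MJ`; all
#'   energies must be strictly positive and every cell x period stratum must
#'   contain at least two samples.
#' @return Data frame with columns `cell`, `period`, `mu_log`, `sigma_log`.
#' @examples
#' s <- data.frame(cell = 1, period = "early", energy_MJ = exp(c(0, 2)))
#' fit_prey_lognormal(s) # mu_log 1, sigma_log 1
#' @export
fit_prey_lognormal <- function(samples) {
  stopifnot(all(c("cell", "period", "energy_MJ") %in% names(samples)))
  if (any(!is.finite(samples$energy_MJ)) || any(samples$energy_MJ <= 0)) {
    stop("prey energy samples must be positive and finite")
  }
  key <- interaction(samples$cell, samples$period, drop = TRUE)
  out <- do.call(rbind, lapply(split(samples, key), function(d) {
    if (nrow(d) < 2L) {
      stop("need >= 2 samples for cell ", d$cell[1L], " period ", d$period[1L],
           " (sigma is undefined from a single point)")
    }
    lx <- log(d$energy_MJ)
    data.frame(cell = d$cell[1L], period = d$period[1L],
               mu_log = mean(lx),
               sigma_log = sqrt(mean((lx - mean(lx))^2)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$cell, match(out$period, c("early", "mid", "late"))), ,
      drop = FALSE]
}

#' Discretize a lognormal prey distribution into equally spaced categories
#'
#' Category values are `K` equally spaced points between the lognormal
#' `1 - coverage` and `coverage` quantiles; each category receives the
#' lognormal probability mass of the half-open interval nearest to it
#' (interval boundaries at category midpoints, extended to 0 and infinity at
#' the ends), renormalized to sum to one.
#'
#' @param mu_log,sigma_log Lognormal log-scale location and scale.
#' @param K Number of categories (>= 1).
#' @param coverage Quantile bracketing the category range, in (0.5, 1).
#' @return List with numeric vectors `values` (MJ per bout, increasing) and
#'   `prob` (summing to 1).
#' @export
discretize_prey <- function(mu_log, sigma_log, K = 10L, coverage = 0.995) {
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (coverage <= 0.5 || coverage >= 1) stop("coverage must be in (0.5, 1)")
  if (sigma_log < 0) stop("sigma_log must be >= 0")
  if (sigma_log < 1e-8 || K == 1L) {
    # Degenerate: all mass on the point nearest the (near-)deterministic value.
    v <- exp(mu_log)
    if (K == 1L) return(list(values = v, prob = 1))
    lo <- stats::qlnorm(1 - coverage, mu_log, max(sigma_log, 1e-8))
    hi <- stats::qlnorm(coverage, mu_log, max(sigma_log, 1e-8))
    vals <- seq(lo, hi, length.out = K)
    p <- numeric(K)
    p[which.min(abs(vals - v))] <- 1
    return(list(values = vals, prob = p))
  }
  lo <- stats::qlnorm(1 - coverage, mu_log, sigma_log)
  hi <- stats::qlnorm(coverage, mu_log, sigma_log)
  vals <- seq(lo, hi, length.out = K)
  cuts <- c(0, (vals[-K] + vals[-1L]) / 2, Inf)
  p <- diff(stats::plnorm(cuts, mu_log, sigma_log))
  p <- p / sum(p)
  list(values = vals, prob = p)
}

#' Assemble the discretized prey field used by iteration and simulation
#'
#' @param params Data frame as returned by [fit_prey_lognormal()] (or read
#'   from its CSV form), covering every cell 1-11 for periods early/mid/late.
#' @param K Categories per distribution.
#' @param coverage Discretization coverage quantile.
#' @return A `prey_field` object: per cell, per period, the category values
#'   and probabilities plus the generating lognormal parameters.
#' @export
prey_field <- function(params, K = 10L, coverage = 0.995) {
  stopifnot(all(c("cell", "period", "mu_log", "sigma_log") %in% names(params)))
  periods <- c("early", "mid", "late")
  field <- vector("list", 11L)
  for (cl in 1:11) {
    field[[cl]] <- vector("list", 3L)
    names(field[[cl]]) <- periods
    for (p in periods) {
      row <- params[params$cell == cl & params$period == p, , drop = FALSE]
      if (nrow(row) != 1L) stop("prey parameters missing for cell ", cl, " period ", p)
      d <- discretize_prey(row$mu_log, row$sigma_log, K = K, coverage = coverage)
      d$mu_log <- row$mu_log
      d$sigma_log <- row$sigma_log
      field[[cl]][[p]] <- d
    }
  }
  structure(list(cells = field, K = as.integer(K), coverage = coverage,
                 params = params),
            class = "prey_field")
}

#' @export
print.prey_field <- function(x, ...) {
  mn <- sapply(1:11, function(cl) {
    mean(sapply(x$cells[[cl]], function(d) sum(d$values * d$prob)))
  })
  cat("Prey field: K =", x$K, "categories, coverage", x$coverage, "\n")
  cat("Season-mean energy per bout (MJ), cells 1-11:\n")
  print(round(mn))
  invisible(x)
}

# Mean category energy for one cell x period (MJ per bout).
prey_mean <- function(field, cell, period) {
  d <- field$cells[[cell]][[period]]
  sum(d$values * d$prob)
}
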