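# Field-data comparison statistics: zero-inflated beta and hurdle-gamma
# likelihoods and their Bayesian regression fits, logistic regression of the
# pregnant fraction, block-to-cell density aggregation, pregnant-female
# density scaling, Cohen's d, and reproductive-rate bookkeeping.

#' Zero-inflated beta log-likelihood
#'
#' Daily proportions of pregnant females seen nearshore are zero on days with
#' no sightings and beta-distributed otherwise: a zero contributes
#' `log(1 - alpha)`; a positive value contributes `log(alpha)` plus the log
#' beta density in the mean-precision parameterization (`shape1 = mu * phi`,
#' `shape2 = (1 - mu) * phi`). The support is `[0, 1)`: a value of exactly 1
#' is an error.
#'
#' @param y Proportions in `[0, 1)`.
#' @param alpha Probability of a nonzero day, scalar or per-observation.
#' @param mu Beta mean in (0, 1), scalar or per-observation.
#' @param phi Beta precision (> 0).
#' @return Total log-likelihood.
#' @export
zib_loglik <- function(y, alpha, mu, phi) {
  if (any(y < 0) || any(y >= 1)) stop("zero-inflated beta support is [0, 1)")
  if (any(alpha <= 0) || any(alpha >= 1) || any(mu <= 0) || any(mu >= 1) ||
      any(phi <= 0)) stop("parameters outside their domain")
  n <- length(y)
  alpha <- rep_len(alpha, n); mu <- rep_len(mu, n)
  z <- y == 0
  sum(log1p(-alpha[z])) +
    sum(log(alpha[!z]) +
          stats::dbeta(y[!z], mu[!z] * phi, (1 - mu[!z]) * phi, log = TRUE))
}

#' Hurdle-gamma log-likelihood
#'
#' Cell densities are zero with probability `1 - alpha` and gamma-distributed
#' otherwise, in the mean-shape parameterization (`shape = omega`,
#' `rate = omega / mu`).
#'
#' @param d Densities (>= 0).
#' @param alpha Probability of a positive density.
#' @param mu Gamma mean (> 0).
#' @param omega Gamma shape (> 0).
#' @export
hurdle_gamma_loglik <- function(d, alpha, mu, omega) {
  if (any(d < 0)) stop("densities must be non-negative")
  if (any(alpha <= 0) || any(alpha >= 1) || any(mu <= 0) || any(omega <= 0)) {
    stop("parameters outside their domain")
  }
  n <- length(d)
  alpha <- rep_len(alpha, n); mu <- rep_len(mu, n)
  z <- d == 0
  sum(log1p(-alpha[z])) +
    sum(log(alpha[!z]) +
          stats::dgamma(d[!z], shape = omega, rate = omega / mu[!z], log = TRUE))
}

# Design matrix for the photo-ID covariate set: intercept, visibility,
# Beaufort, standardized week and its square.
pid_design <- function(week, beaufort, visibility, center, scale) {
  w <- (week - center) / scale
  cbind(1, visibility, beaufort, w, w^2)
}

pid_names <- function(prefix) {
  paste0(prefix, c("_int", "_vis", "_beaufort", "_week", "_week2"))
}

new_pcod_fit <- function(family, draws, par_names, diag, extra = list()) {
  colnames(draws) <- par_names
  structure(c(list(family = family, draws = draws, par_names = par_names,
                   accept = diag$accept, rhat = diag$rhat,
                   at_bound = diag$at_bound), extra),
            class = "pcod_fit")
}

#' Fit the zero-inflated beta regression for nearshore proportions
#'
#' Both the nonzero-day probability and the beta mean are modeled on the
#' logit scale as functions of visibility, Beaufort sea state, week of year,
#' and week squared; the precision is a constant on the log scale. Posterior
#' draws come from adaptive Metropolis sampling with flat priors on the
#' unconstrained scales; split-Rhat convergence diagnostics are attached and
#' a warning is raised when any exceeds the threshold.
#'
#' @param days Data frame with columns `p_near` (in `[0, 1)`), `week`,
#'   `beaufort`, `visibility`.
#' @param n_iter,warmup,n_chains MCMC controls.
#' @param week_scale Optional `c(center, scale)` for the week covariate;
#'   default uses the data mean and sd (stored with the fit).
#' @param rhat_max Convergence flag threshold.
#' @param seed RNG seed for the sampler.
#' @return A `pcod_fit` object (family `"zib"`).
#' @export
fit_zib <- function(days, n_iter = 3000L, warmup = 1000L, n_chains = 2L,
                    week_scale = NULL, rhat_max = 1.1, seed = NULL) {
  stopifnot(all(c("p_near", "week", "beaufort", "visibility") %in% names(days)))
  if (nrow(days) < 20L) stop("need at least 20 surveyed days")
  if (is.null(week_scale)) {
    week_scale <- c(mean(days$week), stats::sd(days$week))
  }
  X <- pid_design(days$week, days$beaufort, days$visibility,
                  week_scale[1], week_scale[2])
  y <- days$p_near
  p <- ncol(X)
  ll <- function(theta) {
    a <- stats::plogis(drop(X %*% theta[1:p]))
    m <- stats::plogis(drop(X %*% theta[(p + 1):(2 * p)]))
    phi <- exp(theta[2 * p + 1])
    a <- pmin(pmax(a, 1e-10), 1 - 1e-10)
    m <- pmin(pmax(m, 1e-10), 1 - 1e-10)
    out <- try(zib_loglik(y, a, m, phi), silent = TRUE)
    if (inherits(out, "try-error") || !is.finite(out)) return(-1e10)
    out
  }
  mu0 <- if (any(y > 0)) min(max(mean(y[y > 0]), 0.05), 0.95) else 0.5
  init <- c(stats::qlogis(min(max(mean(y > 0), 0.05), 0.95)), rep(0, p - 1),
            stats::qlogis(mu0), rep(0, p - 1), log(5))
  res <- mh_sample(ll, init, n_iter = n_iter, warmup = warmup,
                   n_chains = n_chains, seed = seed)
  fit <- new_pcod_fit("zib", res$draws,
                      c(pid_names("alpha"), pid_names("mu"), "log_phi"), res,
                      list(week_scale = week_scale, n = nrow(days)))
  check_convergence(fit, rhat_max)
  fit
}

#' Fit the per-cell hurdle-gamma density regression
#'
#' The probability of a positive density is a logit function of standardized
#' week, week squared, week cubed and the proportion of the cell covered by
#' the survey; the gamma mean uses the week polynomial on the log scale and
#' the shape is constant. Sparse cells (few positive surveys) can be
#' restricted to a single week term.
#'
#' @param records Data frame for one cell with columns `D` (whales/km^2),
#'   `week`, `coverage`.
#' @param sparse Restrict to one explanatory variable (week) per submodel.
#' @inheritParams fit_zib
#' @return A `pcod_fit` (family `"hurdle_gamma"`).
#' @export
fit_hurdle_gamma <- function(records, sparse = FALSE, n_iter = 3000L,
                             warmup = 1000L, n_chains = 2L, week_scale = NULL,
                             rhat_max = 1.1, seed = NULL) {
  stopifnot(all(c("D", "week", "coverage") %in% names(records)))
  if (nrow(records) < 30L) stop("need at least 30 survey records")
  n_pos <- sum(records$D > 0)
  if (n_pos == 0L) {
    stop("no positive densities in this cell: the gamma mean is undefined; ",
         "fit the hurdle only")
  }
  if (is.null(week_scale)) {
    week_scale <- c(mean(records$week), stats::sd(records$week))
  }
  w <- (records$week - week_scale[1]) / week_scale[2]
  if (sparse) {
    Xa <- cbind(1, w); Xm <- cbind(1, w)
    a_nm <- c("alpha_int", "alpha_week"); m_nm <- c("mu_int", "mu_week")
  } else {
    Xa <- cbind(1, w, w^2, w^3, records$coverage)
    Xm <- cbind(1, w, w^2, w^3)
    a_nm <- c("alpha_int", "alpha_week", "alpha_week2", "alpha_week3",
              "alpha_coverage")
    m_nm <- c("mu_int", "mu_week", "mu_week2", "mu_week3")
  }
  pa <- ncol(Xa); pm <- ncol(Xm)
  d <- records$D
  ll <- function(theta) {
    a <- stats::plogis(drop(Xa %*% theta[1:pa]))
    m <- exp(drop(Xm %*% theta[(pa + 1):(pa + pm)]))
    om <- exp(theta[pa + pm + 1])
    a <- pmin(pmax(a, 1e-10), 1 - 1e-10)
    out <- try(hurdle_gamma_loglik(d, a, pmax(m, 1e-10), om), silent = TRUE)
    if (inherits(out, "try-error") || !is.finite(out)) return(-1e10)
    out
  }
  init <- c(stats::qlogis(min(max(n_pos / nrow(records), 0.05), 0.95)),
            rep(0, pa - 1), log(mean(d[d > 0])), rep(0, pm - 1), 0)
  res <- mh_sample(ll, init, n_iter = n_iter, warmup = warmup,
                   n_chains = n_chains, seed = seed)
  fit <- new_pcod_fit("hurdle_gamma", res$draws, c(a_nm, m_nm, "log_omega"),
                      res, list(week_scale = week_scale, n = nrow(records),
                                n_pos = n_pos, sparse = sparse))
  check_convergence(fit, rhat_max)
  fit
}

#' Fit every nearshore cell's hurdle-gamma regression
#'
#' @param records Data frame with a `cell` column plus the columns of
#'   [fit_hurdle_gamma()].
#' @param sparse_threshold Cells with fewer positive surveys than this are
#'   fitted with the single-covariate model.
#' @param ... Passed to [fit_hurdle_gamma()].
#' @return Named list of `pcod_fit` objects, one per cell present.
#' @export
fit_hurdle_gamma_cells <- function(records, sparse_threshold = 20L, ...) {
  stopifnot("cell" %in% names(records))
  out <- lapply(split(records, records$cell), function(d) {
    fit_hurdle_gamma(d, sparse = sum(d$D > 0) < sparse_threshold, ...)
  })
  out
}

#' Logistic regression of the pregnant fraction among identified whales
#'
#' Binomial-logit model of the daily number of pregnant females among all
#' identified whales as a function of standardized week, week squared,
#' Beaufort sea state, and visibility. Days with zero identified whales are
#' dropped (with a message).
#'
#' @param counts Data frame with `n_preg`, `n_total`, `week`, `beaufort`,
#'   `visibility`.
#' @inheritParams fit_zib
#' @return A `pcod_fit` (family `"logistic"`).
#' @export
fit_ppreg <- function(counts, n_iter = 3000L, warmup = 1000L, n_chains = 2L,
                      week_scale = NULL, rhat_max = 1.1, seed = NULL) {
  stopifnot(all(c("n_preg", "n_total", "week", "beaufort", "visibility") %in%
                  names(counts)))
  drop0 <- counts$n_total == 0
  if (any(drop0)) {
    message("dropping ", sum(drop0), " day(s) with no identified whales")
    counts <- counts[!drop0, , drop = FALSE]
  }
  if (any(counts$n_preg > counts$n_total)) stop("n_preg exceeds n_total")
  if (is.null(week_scale)) {
    week_scale <- c(mean(counts$week), stats::sd(counts$week))
  }
  w <- (counts$week - week_scale[1]) / week_scale[2]
  X <- cbind(1, w, w^2, counts$beaufort, counts$visibility)
  ll <- function(theta) {
    p <- stats::plogis(drop(X %*% theta))
    sum(stats::dbinom(counts$n_preg, counts$n_total, p, log = TRUE))
  }
  init <- c(stats::qlogis(min(max(sum(counts$n_preg) / sum(counts$n_total),
                                  0.02), 0.98)), rep(0, 4))
  res <- mh_sample(ll, init, n_iter = n_iter, warmup = warmup,
                   n_chains = n_chains, seed = seed)
  fit <- new_pcod_fit("logistic", res$draws,
                      c("int", "week", "week2", "beaufort", "vis"), res,
                      list(week_scale = week_scale, n = nrow(counts)))
  check_convergence(fit, rhat_max)
  fit
}

check_convergence <- function(fit, rhat_max) {
  if (any(fit$rhat > rhat_max)) {
    warning("possible non-convergence: max split-Rhat ",
            round(max(fit$rhat), 3), " for ",
            fit$par_names[which.max(fit$rhat)])
  }
  if (fit$at_bound > 0.001) {
    warning("posterior mass near the flat-prior bounds (",
            round(100 * fit$at_bound, 2), "% of draws); widen the box")
  }
  invisible(fit)
}

#' @export
print.pcod_fit <- function(x, ...) {
  cat("Bayesian", x$family, "fit (", nrow(x$draws), "posterior draws,",
      "acceptance", round(x$accept, 2), ", max Rhat",
      round(max(x$rhat), 3), ")\n")
  print(round(coef(x), 3))
  invisible(x)
}

#' @export
coef.pcod_fit <- function(object, ...) {
  stats::setNames(colMeans(object$draws), object$par_names)
}

#' @export
summary.pcod_fit <- function(object, prob = 0.90, ...) {
  qs <- apply(object$draws, 2, stats::quantile,
              probs = c((1 - prob) / 2, 0.5, 1 - (1 - prob) / 2))
  data.frame(parameter = object$par_names, mean = colMeans(object$draws),
             sd = apply(object$draws, 2, stats::sd),
             lower = qs[1L, ], median = qs[2L, ], upper = qs[3L, ],
             rhat = object$rhat, row.names = NULL)
}

#' Posterior predictions from a regression fit
#'
#' For the zero-inflated beta and hurdle-gamma families the predicted mean
#' response is `alpha * mu` (`what = "mean"`); `"alpha"` and `"mu"` return
#' the submodel components, and for the logistic family `"p"` returns the
#' predicted probability. Predictions at ideal conditions use Beaufort 0 and
#' visibility 1.
#'
#' @param object A `pcod_fit`.
#' @param newdata Data frame with the covariates the family uses (`week`,
#'   plus `beaufort`/`visibility` or `coverage`).
#' @param what One of "mean", "alpha", "mu", "p".
#' @param draws Return the full posterior draw matrix instead of its mean.
#' @param ... Unused.
#' @export
predict.pcod_fit <- function(object, newdata, what = "mean", draws = FALSE, ...) {
  ws <- object$week_scale
  w <- (newdata$week - ws[1]) / ws[2]
  th <- object$draws
  if (object$family == "logistic") {
    X <- cbind(1, w, w^2, newdata$beaufort, newdata$visibility)
    P <- stats::plogis(th %*% t(X))
    out <- P
  } else if (object$family == "zib") {
    X <- pid_design(newdata$week, newdata$beaufort, newdata$visibility,
                    ws[1], ws[2])
    p <- ncol(X)
    A <- stats::plogis(th[, 1:p] %*% t(X))
    Mu <- stats::plogis(th[, (p + 1):(2 * p)] %*% t(X))
    out <- switch(what, alpha = A, mu = Mu, mean = A * Mu, p = A * Mu)
  } else {
    if (isTRUE(object$sparse)) {
      Xa <- cbind(1, w); Xm <- cbind(1, w)
    } else {
      Xa <- cbind(1, w, w^2, w^3, newdata$coverage)
      Xm <- cbind(1, w, w^2, w^3)
    }
    pa <- ncol(Xa); pm <- ncol(Xm)
    A <- stats::plogis(th[, 1:pa] %*% t(Xa))
    Mu <- exp(th[, (pa + 1):(pa + pm)] %*% t(Xm))
    out <- switch(what, alpha = A, mu = Mu, mean = A * Mu, p = A * Mu)
  }
  if (draws) out else colMeans(out)
}

#' Aggregate block densities to a cell density for one survey
#'
#' Block densities are converted back to counts (`N = D * A`), summed over
#' the blocks covered in the survey, and divided by the total covered block
#' area. A survey-cell with no block records is undefined and returns `NA`
#' (not zero).
#'
#' @param records Data frame with columns `D` (whales/km^2) and `area_km2`
#'   for the blocks of one survey within one cell.
#' @return Density in whales/km^2, or `NA_real_` when no blocks were
#'   surveyed.
#' @export
aggregate_block_density <- function(records) {
  if (is.null(records) || nrow(records) == 0L) return(NA_real_)
  stopifnot(all(c("D", "area_km2") %in% names(records)))
  if (any(records$D < 0) || any(records$area_km2 <= 0)) {
    stop("block densities must be >= 0 and areas > 0")
  }
  sum(records$D * records$area_km2) / sum(records$area_km2)
}

#' Aggregate every survey x cell in a scan table
#'
#' @param scans Data frame with `survey_id`, `cell`, `D`, `area_km2`, and
#'   optionally `coverage` and `week` (carried through).
#' @return Data frame with one row per survey x cell: `D` (aggregated),
#'   summed covered `area_km2`, and any carried covariates.
#' @export
aggregate_scan_table <- function(scans) {
  stopifnot(all(c("survey_id", "cell", "D", "area_km2") %in% names(scans)))
  sp <- split(scans, list(scans$survey_id, scans$cell), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    row <- data.frame(survey_id = d$survey_id[1L], cell = d$cell[1L],
                      D = aggregate_block_density(d),
                      area_km2 = sum(d$area_km2))
    if ("coverage" %in% names(d)) row$coverage <- d$coverage[1L]
    if ("week" %in% names(d)) row$week <- d$week[1L]
    row
  }))
  rownames(out) <- NULL
  out[order(out$cell, out$survey_id), , drop = FALSE]
}

#' Pregnant-female density surfaces
#'
#' Field side: weekly whale density times the predicted pregnant fraction.
#' Model side: the predicted proportion of the modeled population in a cell,
#' times the group size, divided by the cell area.
#'
#' @param D Weekly whale densities (whales/km^2).
#' @param p_preg Weekly pregnant fractions (same length).
#' @export
pregnant_density_field <- function(D, p_preg) {
  stopifnot(length(D) == length(p_preg))
  D * p_preg
}

#' @rdname pregnant_density_field
#' @param proportion Weekly modeled proportion of the population in the cell.
#' @param n_group Number of (potentially) pregnant females represented.
#' @param area_km2 Cell area.
#' @export
pregnant_density_model <- function(proportion, n_group, area_km2) {
  proportion * n_group / area_km2
}

#' Cohen's d standardized mean difference
#'
#' `d = (mean1 - mean2) / s_pooled` with the pooled standard deviation
#' `sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`. Effect categories:
#' none (|d| < 0.2), small (0.2 <= |d| < 0.5), intermediate
#' (0.5 <= |d| < 0.8), large (|d| >= 0.8). Equal means with zero pooled sd
#' give d = 0; unequal means with zero pooled sd give a signed infinite d.
#'
#' @param mean1,sd1,n1 First group summary (sd >= 0, n >= 2).
#' @param mean2,sd2,n2 Second group summary.
#' @return An `effect_size` object with elements `d` and `category`.
#' @export
cohens_d <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(sd1 >= 0, sd2 >= 0, n1 >= 2, n2 >= 2)
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (sp == 0) {
    d <- if (mean1 == mean2) 0 else sign(mean1 - mean2) * Inf
  } else {
    d <- (mean1 - mean2) / sp
  }
  structure(list(d = d, category = effect_category(d)), class = "effect_size")
}

#' @rdname cohens_d
#' @param d A Cohen's d value.
#' @export
effect_category <- function(d) {
  a <- abs(d)
  ifelse(a < 0.2, "none",
         ifelse(a < 0.5, "small", ifelse(a < 0.8, "intermediate", "large")))
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Cohen's d = %.3f (%s effect)\n", x$d, x$category))
  invisible(x)
}

#' Successful reproductive rate under the two-year inter-birth rule
#'
#' With an inter-birth interval of at least two years, females that produced
#' a calf in year one cannot calve in year two, so the rate is
#' `calves_year2 / (n_females - calves_year1)`.
#'
#' @param n_females Known reproductive females in the population.
#' @param calves_year1 Calves produced in the first year.
#' @param calves_year2 Calves identified the following year.
#' @param digits Rounding for the reported rate (2, matching display
#'   precision).
#' @return The rounded rate; the exact value is attached as
#'   `attr(, "exact")`.
#' @examples
#' reproductive_rate(27, 11, 14) # 0.88
#' reproductive_rate(33, 11, 14) # 0.64
#' @export
reproductive_rate <- function(n_females, calves_year1, calves_year2,
                              digits = 2) {
  if (calves_year1 > n_females) stop("calves_year1 exceeds n_females")
  den <- n_females - calves_year1
  if (den <= 0) stop("no females available to be pregnant (denominator <= 0)")
  rate <- calves_year2 / den
  structure(round(rate, digits), exact = rate)
}

#' Fraction of calves matched to their mothers
#'
#' @param matched Calves identified with their mothers.
#' @param total_calves Total calves identified.
#' @return Integer percent.
#' @examples
#' mother_match_fraction(9, 11) # 82
#' mother_match_fraction(8, 14) # 57
#' @export
mother_match_fraction <- function(matched, total_calves) {
  if (total_calves <= 0) stop("total_calves must be positive")
  if (matched > total_calves) stop("matched exceeds total_calves")
  as.integer(round(100 * matched / total_calves))
}
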