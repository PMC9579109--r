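# Zero-inflated beta / hurdle-gamma likelihoods, Bayesian fits, density
# aggregation, Cohen's d, and reproductive-rate bookkeeping.

test_that("zero-inflated beta log-likelihood matches closed forms", {
  # all zeros: only the zero branch contributes
  expect_equal(zib_loglik(rep(0, 10), alpha = 0.3, mu = 0.5, phi = 2),
               10 * log(0.7))
  # Beta(1, 1) is uniform: a positive value contributes only log(alpha)
  expect_equal(zib_loglik(0.5, alpha = 0.4, mu = 0.5, phi = 2), log(0.4))
  expect_error(zib_loglik(1, 0.5, 0.5, 2), "\\[0, 1\\)")
  expect_error(zib_loglik(0.5, 1.2, 0.5, 2), "domain")
})

test_that("hurdle-gamma log-likelihood matches closed forms", {
  expect_equal(hurdle_gamma_loglik(rep(0, 7), alpha = 0.25, mu = 1, omega = 2),
               7 * log(0.75))
  # omega = 1 is exponential: density at its mean is exp(-1)/mu
  mu <- 3.7
  expect_equal(hurdle_gamma_loglik(mu, alpha = 0.6, mu = mu, omega = 1),
               log(0.6) + log(exp(-1) / mu))
  expect_error(hurdle_gamma_loglik(-0.1, 0.5, 1, 1), "non-negative")
})

test_that("both hurdle densities integrate to one (atom + quadrature)", {
  for (pars in list(c(0.3, 0.4, 5), c(0.8, 0.15, 22))) {
    a <- pars[1]; mu <- pars[2]; phi <- pars[3]
    dens <- function(y) {
      vapply(y, function(yy) exp(zib_loglik(yy, a, mu, phi) - log(a)) * a,
             numeric(1))
    }
    q <- stats::integrate(dens, 1e-12, 1 - 1e-12, rel.tol = 1e-9)
    expect_equal((1 - a) + q$value, 1, tolerance = 1e-6)
  }
  for (pars in list(c(0.4, 2, 1.5), c(0.9, 0.2, 4))) {
    a <- pars[1]; mu <- pars[2]; om <- pars[3]
    dens <- function(d) {
      vapply(d, function(dd) exp(hurdle_gamma_loglik(dd, a, mu, om)),
             numeric(1))
    }
    q <- stats::integrate(dens, 1e-12, Inf, rel.tol = 1e-9)
    expect_equal((1 - a) + q$value, 1, tolerance = 1e-6)
  }
})

test_that("block densities aggregate by count over covered area", {
  one <- data.frame(D = 2, area_km2 = 1)
  expect_equal(aggregate_block_density(one), 2)
  two <- data.frame(D = c(2, 1), area_km2 = c(0.5, 1.5))
  expect_equal(aggregate_block_density(two), (1 + 1.5) / 2)
  zero <- data.frame(D = c(0, 0), area_km2 = c(1, 1))
  expect_equal(aggregate_block_density(zero), 0)
  expect_true(is.na(aggregate_block_density(NULL)))
  expect_error(aggregate_block_density(data.frame(D = -1, area_km2 = 1)), ">= 0")

  # invariance under re-partitioning a block with the same total count
  a <- data.frame(D = c(3, 1), area_km2 = c(2, 1))
  b <- data.frame(D = c(3, 3, 1), area_km2 = c(1.2, 0.8, 1))
  expect_equal(aggregate_block_density(a), aggregate_block_density(b))
})

test_that("Cohen's d and its categories follow the standard definition", {
  es <- cohens_d(1.0, 0.5, 30, 0.5, 0.5, 30)
  expect_equal(es$d, 1.0)
  expect_equal(es$category, "large")
  expect_equal(cohens_d(0.7, 0.2, 10, 0.7, 0.3, 10)$d, 0)
  expect_equal(cohens_d(0.7, 0.2, 10, 0.7, 0.3, 10)$category, "none")
  # antisymmetry
  expect_equal(cohens_d(2, 1, 12, 1, 1, 12)$d, -cohens_d(1, 1, 12, 2, 1, 12)$d)
  # degenerate sds
  expect_equal(cohens_d(1, 0, 5, 1, 0, 5)$d, 0)
  expect_equal(cohens_d(2, 0, 5, 1, 0, 5)$d, Inf)
  # category boundaries are half-open at 0.2 / 0.5 / 0.8
  expect_equal(effect_category(c(0.19, 0.2, 0.49, 0.5, 0.79, 0.8, -0.85)),
               c("none", "small", "small", "intermediate", "intermediate",
                 "large", "large"))
})

test_that("reproductive-rate bookkeeping reproduces the worked examples", {
  expect_equal(as.numeric(reproductive_rate(27, 11, 14)), 0.88)
  expect_equal(attr(reproductive_rate(27, 11, 14), "exact"), 14 / 16)
  expect_equal(as.numeric(reproductive_rate(33, 11, 14)), 0.64)
  expect_equal(as.numeric(reproductive_rate(20, 0, 0)), 0)
  expect_error(reproductive_rate(10, 10, 1), "denominator")
  expect_error(reproductive_rate(10, 11, 1), "exceeds")

  expect_equal(mother_match_fraction(9, 11), 82L)
  expect_equal(mother_match_fraction(8, 14), 57L)
  expect_equal(mother_match_fraction(0, 5), 0L)
  expect_error(mother_match_fraction(1, 0), "positive")
})

test_that("pregnant-density scaling works on both the field and model sides", {
  expect_equal(pregnant_density_field(c(1, 2), c(1, 1)), c(1, 2))
  expect_equal(pregnant_density_model(0.2, 10, 50), 0.04)
  expect_equal(pregnant_density_field(2, 0.3), 0.6)
})

test_that("the logistic fit recovers a constant pregnant fraction and matches glm", {
  truth <- scenario_truth(5)
  truth$ppreg <- c(qlogis(0.25), 0, 0, 0, 0)
  counts <- gen_ppreg_counts(truth, season_grid(), n_days = 120, seed = 31)
  fit <- fit_ppreg(counts, n_iter = 2500, warmup = 800, seed = 1)
  expect_s3_class(fit, "pcod_fit")
  # posterior mean of the full linear predictor at average covariates
  pr <- predict(fit, data.frame(week = 13, beaufort = 2, visibility = 0.8))
  expect_equal(unname(pr), 0.25, tolerance = 0.05)
  # independent cross-check: glm point estimates within posterior uncertainty
  w <- (counts$week - fit$week_scale[1]) / fit$week_scale[2]
  gl <- glm(cbind(n_preg, n_total - n_preg) ~ w + I(w^2) + beaufort + visibility,
            family = binomial, data = counts)
  s <- summary(fit)
  expect_true(all(abs(coef(gl) - s$mean) < 3.5 * pmax(s$sd, 1e-3)))
})

test_that("zib and hurdle-gamma fits recover generating parameters (single run)", {
  truth <- scenario_truth(7)
  season <- season_grid()
  days <- gen_photoid(truth, season, n_days = 400, seed = 21)
  fit <- fit_zib(days, n_iter = 2500, warmup = 800,
                 week_scale = c(truth$week_center, truth$week_scale), seed = 2)
  s <- summary(fit)
  true_vec <- c(truth$zib$alpha, truth$zib$mu, log(truth$zib$phi))
  covered <- true_vec >= s$lower & true_vec <= s$upper
  expect_gte(mean(covered), 8 / 11) # most 90% CIs cover on one realization
  expect_true(all(fit$rhat < 1.1))

  scans <- gen_scan_surveys(truth, default_cells(), season, n_surveys = 260,
                            cells_covered = 5, seed = 22)
  agg <- aggregate_scan_table(scans)
  fit_h <- fit_hurdle_gamma(agg, n_iter = 2500, warmup = 800,
                            week_scale = c(truth$week_center, truth$week_scale),
                            seed = 3)
  sh <- summary(fit_h)
  h <- truth$hurdle
  true_h <- c(h$alpha_int[5], h$alpha_week, h$alpha_coverage,
              h$mu_int[5], h$mu_week, log(h$omega))
  covered_h <- true_h >= sh$lower & true_h <= sh$upper
  expect_gte(mean(covered_h), 7 / 10)
  # the coverage effect on the hurdle is recovered with its positive sign
  expect_gt(sh$mean[sh$parameter == "alpha_coverage"], 0)
})

test_that("degenerate regression inputs are flagged", {
  truth <- scenario_truth(3)
  days <- gen_photoid(truth, season_grid(), n_days = 60, seed = 4)
  days$p_near <- 0 # all-zero data: alpha posterior collapses toward zero
  fit <- suppressWarnings(fit_zib(days, n_iter = 1200, warmup = 500, seed = 5))
  pr <- predict(fit, data.frame(week = 13, beaufort = 2, visibility = 0.8),
                what = "alpha")
  expect_lt(unname(pr), 0.1)
  expect_error(fit_zib(days[1:10, ]), "20")

  counts <- gen_ppreg_counts(truth, season_grid(), n_days = 50, seed = 6)
  counts$n_total[1:3] <- 0
  expect_message(fit_ppreg(counts, n_iter = 800, warmup = 300, seed = 7),
                 "dropping")
})
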