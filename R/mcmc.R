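# Adaptive random-walk Metropolis sampler used by the regression fits.
# Flat (uniform) priors inside a wide box; the posterior is proportional to
# the likelihood there. Proposals are multivariate normal with covariance
# taken from the inverse Hessian at the posterior mode, with the global scale
# adapted during warmup toward a standard random-walk acceptance rate.

mh_sample <- function(loglik, init, n_iter = 3000L, warmup = 1000L,
                      n_chains = 2L, bound = 25, seed = NULL) {
  d <- length(init)
  with_local_seed(seed, {
    opt <- stats::optim(init, function(p) -loglik(p), method = "BFGS",
                        control = list(maxit = 500))
    mode <- opt$par
    H <- try(stats::optimHess(mode, function(p) -loglik(p)), silent = TRUE)
    Sigma <- NULL
    if (!inherits(H, "try-error")) {
      ev <- eigen(H, symmetric = TRUE)
      vals <- pmax(ev$values, 1e-8 * max(abs(ev$values), 1))
      Sigma <- ev$vectors %*% diag(1 / vals, d) %*% t(ev$vectors)
    }
    if (is.null(Sigma) || any(!is.finite(Sigma))) Sigma <- diag(0.01, d)
    Lch <- t(chol((Sigma + t(Sigma)) / 2))
    base_scale <- 2.38 / sqrt(d)

    run_chain <- function(start) {
      cur <- start
      ll_cur <- loglik(cur)
      sc <- base_scale
      keep <- matrix(NA_real_, n_iter - warmup, d)
      acc <- 0L
      for (i in seq_len(n_iter)) {
        prop <- cur + sc * drop(Lch %*% stats::rnorm(d))
        if (all(abs(prop) <= bound)) {
          ll_prop <- loglik(prop)
          if (is.finite(ll_prop) && log(stats::runif(1)) < ll_prop - ll_cur) {
            cur <- prop; ll_cur <- ll_prop
            if (i > warmup) acc <- acc + 1L
            a <- 1
          } else a <- 0
        } else a <- 0
        if (i <= warmup) sc <- exp(log(sc) + (a - 0.30) / sqrt(i + 10))
        if (i > warmup) keep[i - warmup, ] <- cur
      }
      list(draws = keep, accept = acc / (n_iter - warmup))
    }

    chains <- lapply(seq_len(n_chains), function(ch) {
      start <- mode + 0.5 * drop(Lch %*% stats::rnorm(d))
      if (any(abs(start) > bound)) start <- mode
      run_chain(start)
    })
    draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
    list(draws = draws, mode = mode,
         accept = mean(vapply(chains, `[[`, numeric(1), "accept")),
         rhat = split_rhat(lapply(chains, `[[`, "draws")),
         at_bound = mean(abs(draws) > 0.99 * bound))
  })
}

# Split-chain potential scale reduction factor per parameter.
split_rhat <- function(chain_list) {
  halves <- list()
  for (m in chain_list) {
    n <- nrow(m); h <- n %/% 2L
    halves <- c(halves, list(m[seq_len(h), , drop = FALSE],
                             m[(h + 1L):(2L * h), , drop = FALSE]))
  }
  d <- ncol(halves[[1L]])
  vapply(seq_len(d), function(j) {
    xs <- lapply(halves, function(m) m[, j])
    n <- length(xs[[1L]]); mns <- vapply(xs, mean, numeric(1))
    vrs <- vapply(xs, stats::var, numeric(1))
    B <- n * stats::var(mns); W <- mean(vrs)
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}
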