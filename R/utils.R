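# Internal numerical and RNG helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not perturb the
#' caller's random stream. A `NULL` seed leaves the stream untouched.
#' @noRd
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a parent seed and an index, staying inside the
# 32-bit signed range R requires for set.seed().
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(index)) %% 2147483562) + 1L
}

#' Truncated-normal draws by inverse-CDF
#' @noRd
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf, u = NULL) {
  if (sd <= 0) return(rep(min(max(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (phi - plo < 1e-12) return(rep(min(max(mean, lower), upper), n))
  if (is.null(u)) u <- stats::runif(n)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

# Map uniforms in (0,1) to a truncated normal; vectorised over u.
qtruncnorm <- function(u, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(rep(min(max(mean, lower), upper), length(u)))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

#' Bilinear interpolation on a rectangular grid
#'
#' `V` is an `nx x ny` matrix of values on `xg` (rows) and `yg` (columns).
#' Query points are clamped to the grid hull. Degenerate one-point axes are
#' handled by dropping the interpolation weight on that axis.
#' @noRd
interp2 <- function(V, xg, yg, x, y) {
  nx <- length(xg); ny <- length(yg)
  x <- pmin(pmax(x, xg[1L]), xg[nx])
  y <- pmin(pmax(y, yg[1L]), yg[ny])
  if (nx > 1L) {
    ix <- pmin(pmax(findInterval(x, xg), 1L), nx - 1L)
    wx <- (x - xg[ix]) / (xg[ix + 1L] - xg[ix])
  } else {
    ix <- rep(1L, length(x)); wx <- rep(0, length(x))
  }
  if (ny > 1L) {
    iy <- pmin(pmax(findInterval(y, yg), 1L), ny - 1L)
    wy <- (y - yg[iy]) / (yg[iy + 1L] - yg[iy])
  } else {
    iy <- rep(1L, length(y)); wy <- rep(0, length(y))
  }
  ix1 <- if (nx > 1L) ix + 1L else ix
  iy1 <- if (ny > 1L) iy + 1L else iy
  v00 <- V[(iy - 1L) * nx + ix]
  v10 <- V[(iy - 1L) * nx + ix1]
  v01 <- V[(iy1 - 1L) * nx + ix]
  v11 <- V[(iy1 - 1L) * nx + ix1]
  (1 - wx) * (1 - wy) * v00 + wx * (1 - wy) * v10 +
    (1 - wx) * wy * v01 + wx * wy * v11
}

# Row-wise cumulative sums via an upper-triangular product (fast for the
# small action sets used when sampling behaviors).
row_cumsum <- function(m) {
  k <- ncol(m)
  m %*% upper.tri(matrix(0, k, k), diag = TRUE)
}

# Stable hash of an arbitrary R object (provenance snapshots).
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
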