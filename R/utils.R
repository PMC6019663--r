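#' @keywords internal
"_PACKAGE"

# Evaluate an expression under a fixed RNG seed, restoring the caller's
# RNG state afterwards. A NULL seed leaves the stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gaussian smoothing along the columns of a matrix, edge-renormalized: the
# kernel is truncated at 3 sigma and, near the ends, re-normalized over the
# in-bounds support so that a constant input is reproduced exactly.
# stats::filter runs all columns in one pass, which keeps rendering and
# detection fast.
smooth_cols <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  n <- nrow(m)
  pad <- matrix(0, half, ncol(m))
  num <- stats::filter(rbind(pad, m, pad), k, sides = 2)
  den <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), k, sides = 2)
  rows <- (half + 1):(half + n)
  unname(as.matrix(num[rows, , drop = FALSE]) / den[rows])
}

# Gaussian smoothing of a vector (see smooth_cols).
smooth1d <- function(v, sigma) {
  if (sigma <= 0) return(v)
  as.vector(smooth_cols(matrix(v, ncol = 1), sigma))
}

# Smooth (Gaussian-process-like) zero-mean noise on a regular grid.
# `dx` is the grid step and `length_scale` the correlation length, both in
# the same unit; the output is rescaled so its marginal sd equals `sd`.
gp_noise <- function(n, dx, sd, length_scale = 1) {
  if (sd <= 0) return(rep(0, n))
  sigma_px <- length_scale / dx
  z <- smooth1d(stats::rnorm(n), sigma_px)
  half <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(seq(-half, half), sd = sigma_px)
  k <- k / sum(k)
  # white noise through a normalized kernel has sd sqrt(sum(k^2))
  z * sd / sqrt(sum(k^2))
}

# Sub-sample peak localization: fit a parabola through (i-1, i, i+1) around
# the discrete argmax and return the refined fractional index.
parabolic_peak <- function(y) {
  i <- which.max(y)
  n <- length(y)
  if (i == 1L || i == n) return(i)
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom >= 0) return(i) # flat or degenerate neighbourhood
  i + 0.5 * (y[i - 1] - y[i + 1]) / denom
}
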