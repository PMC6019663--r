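#' Spearman rank correlation with confidence interval
#'
#' Spearman's r_s with midranks for ties, a 95% confidence interval by the
#' Fisher z transform with variance 1/(n - 3), and a two-sided p-value: exact
#' by full permutation enumeration for n <= 8 without ties, otherwise the
#' t approximation t = r sqrt((n-2)/(1-r^2)) on n - 2 degrees of freedom.
#'
#' @param x,y equal-length numeric vectors, n >= 4, no missing values.
#' @param conf confidence level (default 0.95).
#' @return A `correlation_result`: `r_s`, `ci_low`, `ci_high`, `p`, `n`,
#'   `p_method`.
#' @export
spearman_ci <- function(x, y, conf = 0.95) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  n <- length(x)
  if (n < 4) stop("need at least 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant input vector")
  rx <- rank(x); ry <- rank(y)
  r <- stats::cor(rx, ry)

  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  hw <- stats::qnorm(1 - (1 - conf) / 2) / sqrt(n - 3)
  ci <- tanh(c(z - hw, z + hw))
  ci <- pmin(pmax(ci, -1), 1)

  ties <- anyDuplicated(rx) > 0 || anyDuplicated(ry) > 0
  if (n <= 8 && !ties) {
    p <- spearman_perm_p(rx, ry)
    p_method <- "exact permutation"
  } else {
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    p_method <- "t approximation"
  }
  structure(
    list(r_s = r, ci_low = min(ci[1], r), ci_high = max(ci[2], r),
         p = p, n = n, p_method = p_method),
    class = "correlation_result"
  )
}

# Exact two-sided permutation p for Spearman's r at small n: enumerate all
# n! permutations of the (untied) ranks and count |r_perm| >= |r_obs|. With
# the rank sds fixed, |r| is monotone in the centered cross-product, so only
# that is compared.
spearman_perm_p <- function(rx, ry) {
  n <- length(rx)
  perms <- permutations_of(n)
  center <- n * mean(rx) * mean(ry)
  c_obs <- abs(sum(rx * ry) - center)
  c_all <- abs(as.vector(perms %*% rx) - center)
  mean(c_all >= c_obs - 1e-12)
}

# All permutations of 1..n as rows (n <= 8: at most 40320 x 8).
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- k
    remap <- sub
    remap[sub >= k] <- remap[sub >= k] + 1L
    out[rows, -1L] <- remap
  }
  out
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r_s = %.2f (95%% CI %.2f-%.2f), p = %.3g (%s), n = %d\n",
              x$r_s, x$ci_low, x$ci_high, x$p, x$p_method, x$n))
  invisible(x)
}

#' Mean-split subgroup correlations
#'
#' Partitions one method's records at the mean expired volume into a low
#' (volume <= mean) and a high stratum and reports the Spearman correlation
#' between measurement and volume in each — the subgroup analysis used to
#' show that diaphragm measurements track volume less tightly at high lung
#' volumes, where accessory muscles contribute.
#'
#' @param table study table data.frame with columns `method`, `value`,
#'   `volume_l` (see [simulate_cohort()]).
#' @param method which method's records to analyze ("area", "mmode",
#'   "bmode").
#' @return A `split_correlation`: `mean_cut` (liters), `low`, `high`
#'   (each a [spearman_ci()] result), `n_low`, `n_high`.
#' @export
split_by_mean <- function(table, method) {
  rec <- table[table$method == method, ]
  if (nrow(rec) < 8) stop("need at least 8 records to split")
  mean_cut <- mean(rec$volume_l)
  low <- rec$volume_l <= mean_cut
  if (sum(low) < 4) stop("low-volume stratum has fewer than 4 records")
  if (sum(!low) < 4) stop("high-volume stratum has fewer than 4 records")
  structure(
    list(mean_cut = mean_cut,
         low = spearman_ci(rec$value[low], rec$volume_l[low]),
         high = spearman_ci(rec$value[!low], rec$volume_l[!low]),
         n_low = sum(low), n_high = sum(!low), method = method),
    class = "split_correlation"
  )
}

#' @export
print.split_correlation <- function(x, ...) {
  cat(sprintf("mean-split at %.2f l (%s):\n  low  (n=%d): ", x$mean_cut,
              x$method, x$n_low))
  print(x$low)
  cat(sprintf("  high (n=%d): ", x$n_high))
  print(x$high)
  invisible(x)
}

#' One-way intraclass correlation ICC(1,1)
#'
#' Single-rater, one-way random-effects intraclass correlation from the
#' one-way ANOVA mean squares: ICC = (MSB - MSW) / (MSB + (k - 1) MSW),
#' with a p-value from the F test of the between-targets effect. This is the
#' agreement statistic for two raters independently re-measuring the same
#' clips.
#'
#' @param ratings numeric matrix, targets (rows) x raters (columns); complete,
#'   >= 5 targets, >= 2 raters.
#' @return An `icc_result`: `icc`, `p`, `n_targets`, `n_raters`, `msb`, `msw`.
#' @export
icc_oneway <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("ratings matrix must be complete")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5) stop("need at least 5 targets")
  if (k < 2) stop("need at least 2 raters")
  row_means <- rowMeans(ratings)
  grand <- mean(ratings)
  msb <- k * sum((row_means - grand)^2) / (n - 1)
  msw <- sum((ratings - row_means)^2) / (n * (k - 1))
  if (msb < .Machine$double.eps && msw < .Machine$double.eps)
    stop("degenerate ratings: no variance between or within targets")
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  p <- if (msw == 0) 0 else
    stats::pf(msb / msw, n - 1, n * (k - 1), lower.tail = FALSE)
  structure(
    list(icc = icc, p = p, n_targets = n, n_raters = k, msb = msb, msw = msw),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(1,1) = %.2f, p = %.3g (%d targets, %d raters)\n",
              x$icc, x$p, x$n_targets, x$n_raters))
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact 95% interval for a proportion via the Beta-quantile
#' construction: lower bound qbeta(alpha/2; k, n-k+1) (0 when k = 0), upper
#' bound qbeta(1-alpha/2; k+1, n-k) (1 when k = n).
#'
#' @param k successes (0..n).
#' @param n trials (>= 1).
#' @param conf confidence level (default 0.95).
#' @return A `proportion_ci`: `k`, `n`, `point` (k/n), `ci_low`, `ci_high`.
#' @examples
#' clopper_pearson(2, 10) # 20%, 95% CI 0.03-0.56
#' @export
clopper_pearson <- function(k, n, conf = 0.95) {
  if (length(k) != 1 || length(n) != 1 || anyNA(c(k, n)))
    stop("`k` and `n` must be single numbers")
  if (n < 1) stop("need at least one trial")
  if (k < 0 || k > n || k != round(k) || n != round(n))
    stop("`k` must be an integer count in 0..n")
  alpha <- 1 - conf
  lo <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  structure(list(k = k, n = n, point = k / n, ci_low = lo, ci_high = hi),
            class = "proportion_ci")
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(sprintf("%d/%d = %.0f%% (95%% CI %.2f-%.2f)\n",
              x$k, x$n, 100 * x$point, x$ci_low, x$ci_high))
  invisible(x)
}
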