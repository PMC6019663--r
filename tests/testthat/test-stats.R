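test_that("Spearman correlation handles the canonical cases", {
  expect_equal(spearman_ci(1:8, (1:8)^3)$r_s, 1)
  expect_equal(spearman_ci(1:8, -(1:8))$r_s, -1)
  # hand-computed: d^2 = (1,1,1,1,0), r_s = 1 - 6*4/120 = 0.8
  r <- spearman_ci(1:5, c(2, 1, 4, 3, 5))
  expect_equal(r$r_s, 0.8)
  expect_identical(r$p_method, "exact permutation")
  expect_error(spearman_ci(rep(1, 6), 1:6), "constant")
  expect_error(spearman_ci(1:3, 1:3), "at least 4")
  expect_error(spearman_ci(c(1, 2, NA, 4), 1:4), "missing")
})

test_that("exact permutation p matches the cor.test exact distribution", {
  withr::with_seed(5, {
    for (i in 1:8) {
      n <- sample(5:8, 1)
      x <- sample(100, n); y <- sample(100, n)
      mine <- spearman_ci(x, y)
      ref <- stats::cor.test(x, y, method = "spearman", exact = TRUE)
      expect_equal(mine$r_s, unname(ref$estimate))
      expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    }
  })
})

test_that("Spearman r and p are invariant under strictly monotone transforms", {
  withr::with_seed(3, {
    x <- rnorm(30); y <- x + rnorm(30)
    base <- spearman_ci(x, y)
    tr <- spearman_ci(exp(x), y^3 + 5 * y)
    expect_equal(tr$r_s, base$r_s)
    expect_equal(tr$p, base$p)
    expect_equal(tr$ci_low, base$ci_low)
  })
})

test_that("Fisher-z interval contains r_s and stays within [-1, 1]", {
  withr::with_seed(8, {
    for (i in 1:20) {
      n <- sample(5:40, 1)
      r <- spearman_ci(rnorm(n), rnorm(n))
      expect_true(r$ci_low <= r$r_s && r$r_s <= r$ci_high)
      expect_gte(r$ci_low, -1)
      expect_lte(r$ci_high, 1)
    }
  })
  perfect <- spearman_ci(1:10, 1:10)
  expect_lte(perfect$ci_high, 1)
})

test_that("mean-split subgroup correlations partition at the volume mean", {
  tab <- data.frame(subject_id = 1, breath_id = 1:12, method = "area",
                    value = 1:12, units = "cm2", volume_l = 1:12 / 2)
  sp <- split_by_mean(tab, "area")
  expect_equal(sp$mean_cut, mean(tab$volume_l))
  expect_identical(sp$n_low + sp$n_high, 12L)
  expect_identical(sp$n_low, 6L) # symmetric data: equal strata
  # noise-free monotone cohort: both strata perfect
  expect_equal(sp$low$r_s, 1)
  expect_equal(sp$high$r_s, 1)
  expect_error(split_by_mean(tab[1:6, ], "area"), "at least 8")
  expect_error(split_by_mean(tab, "mmode"), "at least 8")
})

test_that("one-way ICC matches the ANOVA mean squares and the F test", {
  withr::with_seed(12, {
    tgt <- rnorm(30, sd = 2)
    mat <- cbind(tgt + rnorm(30), tgt + rnorm(30), tgt + rnorm(30))
    mine <- icc_oneway(mat)
    # independent oracle: one-way ANOVA via stats::aov
    df <- data.frame(value = as.vector(mat),
                     target = factor(rep(seq_len(30), 3)))
    av <- summary(stats::aov(value ~ target, data = df))[[1]]
    msb <- av["target", "Mean Sq"]; msw <- av["Residuals", "Mean Sq"]
    expect_equal(mine$icc, (msb - msw) / (msb + 2 * msw), tolerance = 1e-10)
    expect_equal(mine$p, av["target", "Pr(>F)"], tolerance = 1e-10)
  })
})

test_that("ICC is exactly 1 for duplicated raters and near 0 for noise", {
  mat <- cbind(1:10, 1:10)
  expect_equal(icc_oneway(mat)$icc, 1)
  withr::with_seed(6, {
    noise <- matrix(rnorm(4000), 2000, 2)
    expect_lt(abs(icc_oneway(noise)$icc), 0.05)
  })
  expect_error(icc_oneway(matrix(1, 10, 2)), "degenerate")
  expect_error(icc_oneway(matrix(1:8, 4, 2)), "at least 5")
  expect_error(icc_oneway(matrix(1:10, 10, 1)), "at least 2")
})

test_that("ICC estimator recovers the variance ratio at large n", {
  withr::with_seed(9, {
    tgt <- rnorm(2000, sd = 3) # sigma_b^2 = 9, sigma_w^2 = 1 -> ICC 0.9
    mat <- cbind(tgt + rnorm(2000), tgt + rnorm(2000))
    expect_lt(abs(icc_oneway(mat)$icc - 0.9), 0.02)
  })
})

test_that("Clopper-Pearson intervals reproduce exact bounds", {
  ci <- clopper_pearson(2, 10)
  expect_equal(round(ci$ci_low, 2), 0.03)
  expect_equal(round(ci$ci_high, 2), 0.56)
  expect_equal(clopper_pearson(10, 10)$ci_high, 1)
  expect_equal(round(clopper_pearson(10, 10)$ci_low, 2),
               round(0.025^(1 / 10), 2)) # 0.69
  expect_equal(clopper_pearson(0, 10)$ci_low, 0)
  # against the stats::binom.test oracle
  for (k in c(0, 3, 7, 10)) {
    mine <- clopper_pearson(k, 10)
    ref <- stats::binom.test(k, 10)$conf.int
    expect_equal(c(mine$ci_low, mine$ci_high), as.numeric(ref),
                 tolerance = 1e-12)
  }
  expect_error(clopper_pearson(11, 10), "0..n")
  expect_error(clopper_pearson(1, 0), "one trial")
})

test_that("Clopper-Pearson coverage is at least nominal for every p", {
  n <- 10
  bounds <- t(vapply(0:n, function(k) {
    ci <- clopper_pearson(k, n)
    c(ci$ci_low, ci$ci_high)
  }, numeric(2)))
  withr::with_seed(13, {
    for (p in seq(0.1, 0.9, by = 0.1)) {
      k <- stats::rbinom(5000, n, p)
      covered <- bounds[k + 1, 1] <= p & p <= bounds[k + 1, 2]
      expect_gte(mean(covered), 0.95)
    }
  })
})
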