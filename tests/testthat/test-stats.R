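test_that("spearman correlation handles monotone data and ties", {
  x <- c(1, 2, 3, 5, 8, 13)
  r <- spearman_cor(x, x^2 + 1)
  expect_equal(r$r, 1)
  expect_equal(spearman_cor(x, -x^3)$r, -1)
  # tie handling matches the midrank product-moment formula
  set.seed(7)
  for (i in 1:20) {
    a <- sample(1:4, 8, replace = TRUE)
    b <- sample(1:4, 8, replace = TRUE)
    if (sd(a) == 0 || sd(b) == 0) next
    ra <- rank(a); rb <- rank(b)
    oracle <- sum((ra - mean(ra)) * (rb - mean(rb))) /
      sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
    expect_equal(spearman_cor(a, b)$r, oracle, tolerance = 1e-12)
  }
  expect_error(spearman_cor(1:5, rep(2, 5)), "constant")
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
  expect_error(spearman_cor(1:5, 1:4), "equal length")
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(11)
  x <- runif(30); y <- runif(30)
  r0 <- spearman_cor(x, y)$r
  expect_equal(spearman_cor(exp(3 * x), y)$r, r0)
  expect_equal(spearman_cor(x, y^3)$r, r0)
})

test_that("Mann-Whitney U matches exhaustive pair counting", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mann_whitney(1:3, 1:3)$U, 4.5)  # n^2 / 2 under symmetry
  expect_equal(mann_whitney(1:3, 1:3)$p, 1)
  set.seed(13)
  for (i in 1:20) {
    a <- sample(1:5, sample(2:6, 1), replace = TRUE)
    b <- sample(1:5, sample(2:6, 1), replace = TRUE)
    u_oracle <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    expect_equal(mann_whitney(a, b)$U, u_oracle)
  }
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney p equals the enumeration distribution", {
  # tiny-sample oracle: full permutation distribution of U
  set.seed(17)
  for (i in 1:8) {
    a <- sample(1:4, 4, replace = TRUE)
    b <- sample(1:4, 5, replace = TRUE)
    pooled <- c(a, b)
    n1 <- length(a)
    mu <- n1 * length(b) / 2
    r <- rank(pooled)
    us <- combn(length(pooled), n1, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
    u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    p_oracle <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
    expect_equal(mann_whitney(a, b)$p, p_oracle)
  }
})

test_that("binned averaging pools, averages and excludes singleton bins", {
  bs <- bin_average(c(1e6, 2e6, 6e6), c(1, 2, 3), width = 5e6)
  expect_equal(nrow(bs$bins), 1L)
  expect_equal(bs$bins$x_mean, 1.5e6)
  expect_equal(bs$bins$y_mean, 1.5)
  expect_equal(bs$excluded$bin, 1)
  expect_equal(bs$excluded$reason, "single_point")
  # conservation: retained plus excluded counts equal n
  expect_equal(sum(bs$bins$n) + sum(bs$excluded$n), bs$n_points)

  one <- bin_average(c(1, 2, 3), c(5, 6, 7), width = 10)
  expect_equal(nrow(one$bins), 1L)
  expect_equal(one$bins$y_mean, 6)

  lonely <- bin_average(c(1, 12, 25), c(1, 2, 3), width = 10)
  expect_equal(nrow(lonely$bins), 0L)
  expect_equal(nrow(lonely$excluded), 3L)
  expect_error(bin_average(numeric(0), numeric(0)), "empty")
  expect_error(bin_average(-1, 1, 10), "non-negative")
})

test_that("two-regime fitting recovers a known breakpoint", {
  d <- two_regime_data(1)
  fit <- fit_two_regime(bin_average(d$x, d$y, 5e6))
  expect_lt(abs(fit$threshold - d$thr), 5e6 + 1e-9)
  expect_gt(fit$lower$r2, 0.9)
  expect_lt(fit$lower$p_slope, 0.01)
  expect_false("no_trend" %in% fit$flags)
  # the threshold sits on a bin boundary
  expect_equal(fit$threshold %% 5e6, 0)
  # confidence band brackets the fitted line
  expect_true(all(fit$lower$band$lwr <= fit$lower$band$fit &
                    fit$lower$band$fit <= fit$lower$band$upr))
})

test_that("degenerate two-regime inputs are flagged", {
  set.seed(5)
  x <- runif(200, 0, 1e8)
  lin <- fit_two_regime(bin_average(x, 2e-6 * x, 5e6))  # exactly linear
  expect_true("degenerate_linear" %in% lin$flags)
  # exact ties resolve to the smallest candidate threshold
  expect_equal(lin$threshold, min(lin$candidates$threshold))
  expect_equal(lin$upper$slope, lin$lower$slope, tolerance = 1e-9)

  flat <- fit_two_regime(bin_average(x, rnorm(200, 3, 0.5), 5e6))
  expect_true("no_trend" %in% flat$flags)
  expect_gte(flat$lower$p_slope, 0.05)
  expect_error(fit_two_regime(bin_average(c(1, 1.5), c(1, 2), 10)),
               "retained bins")
})

test_that("the threshold ignores affine rescaling of the response", {
  d <- two_regime_data(9)
  f1 <- fit_two_regime(bin_average(d$x, d$y, 5e6))
  f2 <- fit_two_regime(bin_average(d$x, 100 * d$y - 7, 5e6))
  expect_equal(f1$threshold, f2$threshold)
  expect_equal(f1$lower$r2, f2$lower$r2, tolerance = 1e-9)
})

test_that("breakpoint recovery holds across seeds", {
  errs <- vapply(1:40, function(s) {
    d <- two_regime_data(s)
    abs(fit_two_regime(bin_average(d$x, d$y, 5e6))$threshold - d$thr)
  }, numeric(1))
  expect_lte(median(errs), 5e6)
})

test_that("cohort comparison reports means, SEMs and the U test", {
  set.seed(21)
  a <- data.frame(vol = rnorm(30, 10), sph = runif(30))
  tab <- cohort_compare(a, a, c("vol", "sph"))
  expect_equal(tab$mean_a, tab$mean_b)
  expect_equal(tab$U, rep(30^2 / 2, 2))
  expect_equal(tab$signif, c("ns", "ns"))
  expect_error(cohort_compare(a, a, "nope"), "unknown variable")
  b <- a
  b$vol <- b$vol + 10
  tab2 <- cohort_compare(a, b, "vol")
  expect_lt(tab2$p, 0.001)
  expect_equal(tab2$signif, "***")
})
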