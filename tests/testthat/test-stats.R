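test_that("percent_change matches the worked perfusion-index examples", {
  expect_equal(round(percent_change(139, 104)), 25)
  expect_equal(round(percent_change(139, 84)), 40)
  expect_equal(percent_change(42, 42), 0)
  expect_equal(percent_change(10, 0), 100)
  expect_error(percent_change(0, 10), "positive")
})

test_that("percent_change is antitone in the later mean", {
  later <- seq(0, 200, by = 10)
  pc <- vapply(later, function(l) percent_change(139, l), numeric(1))
  expect_true(all(diff(pc) < 0))
})

test_that("reduction_ratio does plain pre/post arithmetic", {
  expect_equal(round(reduction_ratio(5.5, 3.5), 3), 0.364)
  expect_equal(reduction_ratio(7, 7), 0)
  expect_equal(reduction_ratio(3, 0), 1)
  expect_error(reduction_ratio(0, 1), "positive")
})

test_that("degenerate ANOVA inputs behave as documented", {
  const <- list(a = rep(5, 4), b = rep(5, 4), c = rep(5, 4))
  r <- anova_dunnett(const)
  expect_equal(r$F, 0)
  expect_equal(r$comparisons$p_adjusted, c(1, 1))
  expect_error(anova_dunnett(list(a = 1:3, b = 2)), "n >= 2")
  expect_error(anova_dunnett(list(a = 1:3)), "at least 2 groups")
})

test_that("one comparison equals the pooled two-sided t-test to 1e-6", {
  set.seed(42)
  for (rep in 1:5) {
    a <- rnorm(4 + rep)
    b <- rnorm(7, mean = rep / 3)
    r <- anova_dunnett(list(control = a, treated = b))
    tt <- t.test(b, a, var.equal = TRUE)
    expect_equal(r$comparisons$p_adjusted, tt$p.value, tolerance = 1e-6)
    expect_equal(r$comparisons$t, unname(tt$statistic), tolerance = 1e-8)
  }
})

test_that("adjusted p-values match the equicoordinate multivariate-t tail (mvtnorm)", {
  skip_if_not_installed("mvtnorm")
  set.seed(7)
  vals <- list(baseline = rnorm(47, 139, 60), sham = rnorm(46, 104, 50),
               hd1 = rnorm(35, 119, 60), hd2 = rnorm(23, 84, 50))
  r <- anova_dunnett(vals)
  n <- vapply(vals, length, integer(1))
  df2 <- sum(n) - length(n)
  lam <- sqrt(n[-1] / (n[-1] + n[1]))
  corr <- outer(lam, lam)
  diag(corr) <- 1
  set.seed(1)
  for (i in seq_len(length(n) - 1)) {
    ti <- abs(r$comparisons$t[i])
    p_mv <- 1 - mvtnorm::pmvt(
      lower = -rep(ti, length(lam)), upper = rep(ti, length(lam)),
      corr = corr, df = df2,
      algorithm = mvtnorm::GenzBretz(abseps = 1e-6, maxpts = 500000)
    )[1]
    expect_lt(abs(r$comparisons$p_adjusted[i] - p_mv), 5e-5)
  }
  expect_true(all(r$comparisons$p_adjusted >= r$comparisons$p_unadjusted))
})

test_that("Monte-Carlo and quadrature routes agree", {
  set.seed(3)
  vals <- list(a = rnorm(10), b = rnorm(8, 0.8), c = rnorm(12, -0.4))
  ri <- anova_dunnett(vals)
  rm_ <- anova_dunnett(vals, method = "mc", mc_draws = 2e5, seed = 11)
  expect_equal(ri$comparisons$p_adjusted, rm_$comparisons$p_adjusted, tolerance = 1e-2)
})

test_that("adjusted p-values are invariant to reordering non-control groups", {
  set.seed(9)
  vals <- list(ctrl = rnorm(9), g1 = rnorm(7, 1), g2 = rnorm(11, -0.5), g3 = rnorm(6))
  r1 <- anova_dunnett(vals)
  r2 <- anova_dunnett(vals[c("ctrl", "g3", "g1", "g2")])
  m1 <- r1$comparisons[order(r1$comparisons$group), ]
  m2 <- r2$comparisons[order(r2$comparisons$group), ]
  expect_equal(m1$p_adjusted, m2$p_adjusted, tolerance = 1e-12)
  expect_equal(r1$F, r2$F)
})

test_that("data.frame input with a designated control works", {
  df <- data.frame(
    group = factor(rep(c("base", "t1"), each = 4), levels = c("base", "t1")),
    value = c(1, 2, 3, 4, 5, 6, 7, 8)
  )
  r <- anova_dunnett(df)
  expect_equal(r$control, "base")
  expect_equal(r$comparisons$diff, 4)
})
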