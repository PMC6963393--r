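test_that("icc matches the loop-based ANOVA oracle on random small datasets", {
  set.seed(51)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    k <- sample(2:3, 1)
    Y <- matrix(rnorm(n * k, 50, 10), n, k)
    for (model in c("oneway", "twoway-consistency", "twoway-agreement")) {
      est <- suppressWarnings(icc(Y, model = model))
      expect_equal(est$value, oracle_icc(Y, model), tolerance = 1e-10)
    }
  }
})

test_that("identical non-constant measurements give ICC = 1", {
  v <- c(3, 9, 1, 7, 5, 8)
  est <- icc(v, v)
  expect_equal(est$value, 1)
  expect_equal(est$band, "almost perfect")
})

test_that("independent measurements give ICC near 0 at large n", {
  set.seed(52)
  n <- 2000
  est <- icc(rnorm(n), rnorm(n))
  expect_lt(abs(est$value), 3 / sqrt(n))
})

test_that("consistency ICC ignores a constant offset; agreement ICC does not", {
  set.seed(53)
  s <- rnorm(30, 100, 15)
  a <- s + rnorm(30, 0, 5)
  b <- s + rnorm(30, 0, 5)
  shift <- 25
  cons0 <- icc(a, b, model = "twoway-consistency")$value
  cons1 <- icc(a, b + shift, model = "twoway-consistency")$value
  expect_equal(cons1, cons0, tolerance = 1e-10)
  agr0 <- icc(a, b, model = "twoway-agreement")$value
  agr1 <- icc(a, b + shift, model = "twoway-agreement")$value
  expect_lt(agr1, agr0 - 0.1)
})

test_that("degenerate icc inputs error", {
  expect_error(icc(c(1, 2), c(1, 2)), "at least 3")
  expect_error(icc(rep(1, 5), rep(1, 5)), "zero total variance")
  expect_error(icc(c(1, NA, 2, 3), c(1, 2, 3, 4)), "finite")
  expect_warning(icc(c(1, 2, 4), c(1, 2, 5)), "CI floor")
})

test_that("F-based intervals bracket the estimate and shrink with n", {
  set.seed(54)
  s <- rnorm(40, 0, 2)
  a <- s + rnorm(40); b <- s + rnorm(40)
  for (model in c("oneway", "twoway-consistency", "twoway-agreement")) {
    est <- icc(a, b, model = model, ci_method = "f")
    expect_lte(est$ci_low, est$value)
    expect_gte(est$ci_high, est$value)
  }
  small <- icc(a[1:10], b[1:10], ci_method = "f")
  big <- icc(a, b, ci_method = "f")
  expect_lt(big$ci_high - big$ci_low, small$ci_high - small$ci_low)
})

test_that("the six-band interpretation scale maps values as printed", {
  expect_equal(interpret_icc(0.861), "almost perfect")
  expect_equal(interpret_icc(0.809), "almost perfect")
  expect_equal(interpret_icc(0.491), "moderate")
  expect_equal(interpret_icc(0), "poor")
  expect_equal(interpret_icc(-0.2), "poor")
  expect_equal(interpret_icc(0.20), "slight")
  expect_equal(interpret_icc(0.21), "fair")
  expect_equal(interpret_icc(0.40), "fair")
  expect_equal(interpret_icc(0.60), "moderate")
  expect_equal(interpret_icc(0.80), "substantial")
  expect_equal(interpret_icc(0.81), "almost perfect")
  expect_equal(interpret_icc(1), "almost perfect")
  expect_error(interpret_icc(1.2), "\\[-1, 1\\]")
})

test_that("fisher z is the half-log ratio and round-trips", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.861), 0.5 * log(1.861 / 0.139), tolerance = 1e-12)
  for (r in c(-0.9, -0.3, 0.2, 0.7, 0.99)) {
    expect_equal(fisher_z_inv(fisher_z(r)), r, tolerance = 1e-12)
  }
  expect_error(fisher_z(1), "< 1")
  expect_error(fisher_z(-1.2), "< 1")
})

test_that("compare_icc is antisymmetric with p = 0.5 at equality", {
  set.seed(55)
  s <- rnorm(40, 0, 2)
  ea <- icc(s + rnorm(40), s + rnorm(40))
  eb <- icc(s + rnorm(40, 0, 1.4), s + rnorm(40, 0, 1.4))
  same <- compare_icc(ea, ea)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_raw, 0.5)
  ab <- compare_icc(ea, eb)
  ba <- compare_icc(eb, ea)
  expect_equal(ab$statistic, -ba$statistic, tolerance = 1e-12)
  two <- compare_icc(ea, eb, alternative = "two.sided")
  expect_equal(two$p_raw, 2 * pnorm(-abs(ab$statistic)), tolerance = 1e-12)
  expect_error(compare_icc(0.8, 0.5, n_a = 3, n_b = 40), "n > 3")
})

test_that("bonferroni multiplies and clips", {
  expect_equal(bonferroni(c(0.01, 0.03)), c(0.02, 0.06))
  expect_equal(bonferroni(0.9, m = 5), 1)
  expect_equal(bonferroni(c(0.2, 0.4), m = 1), c(0.2, 0.4))
  expect_equal(bonferroni(c(0.01, 0.2, 0.5)),
               p.adjust(c(0.01, 0.2, 0.5), "bonferroni"))
  expect_error(bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("bootstrap comparison favours the genuinely better-agreeing method", {
  set.seed(56)
  s <- rnorm(40, 50, 10)
  ref <- s + rnorm(40, 0, 1)
  good <- s + rnorm(40, 0, 1)
  bad <- s + rnorm(40, 0, 25)
  cmp <- compare_icc_boot(ref, good, bad, n_boot = 400, seed = 8)
  expect_gt(cmp$statistic, 0)
  expect_lt(cmp$p_raw, 0.05)
})
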