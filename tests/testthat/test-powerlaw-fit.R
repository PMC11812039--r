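test_that("log binning uses half-open power-of-lambda bins above xm", {
  b <- log_bin(diameter_sample(c(1, 2, 4)), xm = 1, lambda = 2)
  expect_identical(unname(b$counts), c(1L, 1L, 1L))  # boundaries go up
  expect_identical(b$n_excluded, 0L)

  b2 <- log_bin(diameter_sample(c(0.5, 1.5)), xm = 1, lambda = 2)
  expect_identical(unname(b2$counts), 1L)
  expect_identical(b2$n_excluded, 1L)

  # a value built by repeated multiplication lands in its intended bin
  xm <- 0.3
  d <- xm
  for (i in 1:3) d <- d * 3
  b3 <- log_bin(diameter_sample(c(xm, d)), xm = xm, lambda = 3)
  expect_identical(as.integer(names(b3$counts))[b3$counts > 0], c(0L, 3L))

  expect_error(log_bin(diameter_sample(0.2), xm = 1), "no diameters")
  expect_error(log_bin(diameter_sample(1), xm = 1, lambda = 1), "lambda")
})

test_that("closed-form alpha-hat maximises the binned likelihood", {
  b <- log_bin(diameter_sample(c(1, 1, 1, 2)), xm = 1, lambda = 2)
  f <- fit_alpha(b)
  expect_equal(f$alpha_hat, log(5) / log(2), tolerance = 1e-12)
  expect_equal(f$alpha_hat, grid_search_alpha(b$counts, 2), tolerance = 1e-3)

  # equal counts in m bins: S = m(m-1)/2, alpha = log(1 + 2/(m-1))/log(lambda)
  for (m in c(3L, 5L, 8L)) {
    d <- 1.01 * 2^(0:(m - 1))
    fm <- fit_alpha(log_bin(diameter_sample(d), xm = 1, lambda = 2))
    expect_equal(fm$alpha_hat, log(1 + 2 / (m - 1)) / log(2))
  }

  # random seeded count tables: closed form equals grid-search argmax
  set.seed(55)
  for (i in 1:25) {
    nb <- sample(2:8, 1)
    counts <- stats::setNames(stats::rpois(nb, 5) + 1L, 0:(nb - 1))
    d <- rep(1.0001 * 2^(0:(nb - 1)), counts)
    f <- fit_alpha(log_bin(diameter_sample(d), xm = 1, lambda = 2))
    expect_equal(f$alpha_hat, grid_search_alpha(counts, 2), tolerance = 1e-3)
  }

  # all mass in bin 0: alpha unbounded above
  expect_error(fit_alpha(log_bin(diameter_sample(c(1, 1.5)), xm = 1)),
               "degenerate")
})

test_that("the estimator recovers alpha and is scale invariant", {
  s <- sample_diameters(2, 1, 1e4, seed = 61)
  f <- fit_alpha(log_bin(s, 1, 2))
  expect_equal(f$alpha_hat, 2, tolerance = 0.05 / 2)

  # multiplying all diameters and xm by any constant changes nothing
  for (const in c(0.01, 2.54, 1000)) {
    sc <- diameter_sample(s$diameters * const)
    fc <- fit_alpha(log_bin(sc, const, 2))
    expect_identical(fc$alpha_hat, f$alpha_hat)
  }

  # lambda robustness: estimates agree across bin bases on large samples
  for (a in c(1.5, 2, 3)) {
    d <- sample_diameters(a, 1, 2000, seed = 70 + round(a))
    ah <- sapply(c(1.5, 2, 3), function(l) fit_alpha(log_bin(d, 1, l))$alpha_hat)
    expect_lt(diff(range(ah)), 0.15)
  }
})

test_that("fitted alpha follows the cumulative, not density, convention", {
  # the tail-curve slope is -alpha; the density exponent would be alpha + 1
  s <- sample_diameters(2, 1, 5e4, seed = 77)
  tc <- tail_curve(s)
  pts <- tc[tc$diameter >= 1 & tc$percent_ge > 0.2, ]  # avoid extreme-tail noise
  slope <- stats::coef(stats::lm(log(pts$percent_ge) ~ log(pts$diameter)))[[2]]
  ah <- fit_alpha(log_bin(s, 1, 2))$alpha_hat
  expect_equal(slope, -ah, tolerance = 0.1 / 2)
  expect_gt(abs(slope + (ah + 1)), 0.5)  # clearly not the density exponent
})

test_that("bootstrap intervals behave like confidence intervals", {
  s <- sample_diameters(2, 1, 1e4, seed = 81)
  bt <- bootstrap_ci(s, 1, 2, n_boot = 2000, seed = 81, level = 0.95)
  expect_lt(bt$ci[["lower"]], 2)
  expect_gt(bt$ci[["upper"]], 2)
  expect_lt(diff(bt$ci), 0.2)
  # reproducible under seed
  bt2 <- bootstrap_ci(s, 1, 2, n_boot = 2000, seed = 81, level = 0.95)
  expect_identical(bt$ci, bt2$ci)
  # nested in level
  bt68 <- bootstrap_ci(s, 1, 2, n_boot = 2000, seed = 81, level = 0.68)
  expect_lt(diff(bt68$ci), diff(bt$ci))
  # 1/sqrt(n) widening for small samples
  small <- sample_diameters(2, 1, 50, seed = 82)
  big <- sample_diameters(2, 1, 5000, seed = 82)
  w_small <- diff(bootstrap_ci(small, 1, 2, 2000, seed = 1)$ci)
  w_big <- diff(bootstrap_ci(big, 1, 2, 2000, seed = 1)$ci)
  expect_gt(w_small, w_big)
  expect_error(bootstrap_ci(s, 1, 2, n_boot = 10), "at least 1000")
})

test_that("bootstrap coverage is near nominal at moderate n", {
  hits <- vapply(1:200, function(i) {
    s <- sample_diameters(2, 1, 400, seed = 3000 + i)
    ci <- bootstrap_ci(s, 1, 2, n_boot = 1000, seed = i)$ci
    ci[["lower"]] <= 2 && 2 <= ci[["upper"]]
  }, logical(1))
  expect_gte(mean(hits), 0.85)
})

test_that("tail curves are exceedance percentages at distinct diameters", {
  tc <- tail_curve(diameter_sample(c(1, 2, 3)))
  expect_equal(tc$diameter, c(1, 2, 3))
  expect_equal(tc$percent_ge, c(100, 200 / 3, 100 / 3))

  one <- tail_curve(diameter_sample(rep(2.5, 10)))
  expect_identical(nrow(one), 1L)
  expect_equal(one$percent_ge, 100)

  tc2 <- tail_curve(sample_diameters(3, 1, 1000, seed = 5))
  expect_equal(tc2$percent_ge[1], 100)
  expect_true(all(diff(tc2$percent_ge) < 0))
  expect_true(all(diff(tc2$diameter) > 0))
})

test_that("threshold diagnostic flags cutoffs that keep small-scale curvature", {
  clean <- sample_diameters(2, 1, 5000, seed = 4)
  f <- fit_powerlaw(clean, 1, ci = FALSE)
  dg <- threshold_diagnostic(clean, f)
  expect_true(dg$available)
  expect_false(dg$flag)

  # censoring of small branches (artist omits thin strokes) bends the tail
  # curve at small d; a cutoff below the censoring scale is flagged
  cens <- with_censored_sample()
  low <- fit_powerlaw(cens, 0.3, ci = FALSE)
  expect_true(threshold_diagnostic(cens, low)$flag)
  high <- fit_powerlaw(cens, 2, ci = FALSE)
  expect_false(threshold_diagnostic(cens, high)$flag)
  # the automatic scan lands between the two
  auto <- choose_xm(cens)
  expect_gt(auto, 0.3)
  expect_lte(auto, 2)

  # too few distinct diameters in the first bin: unavailable, not an error
  coarse <- diameter_sample(c(1, 1, 2, 4))
  fc <- fit_powerlaw(coarse, 1, ci = FALSE)
  expect_false(threshold_diagnostic(coarse, fc)$available)
})
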