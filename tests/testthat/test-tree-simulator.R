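test_that("the generator is bit-reproducible and leaves the RNG alone", {
  t1 <- generate_tree(alpha = 2, seed = 17)
  t2 <- generate_tree(alpha = 2, seed = 17)
  expect_identical(t1$branches, t2$branches)
  t3 <- generate_tree(alpha = 2, seed = 18)
  expect_false(identical(t1$branches, t3$branches))

  set.seed(99)
  before <- runif(5)
  set.seed(99)
  invisible(generate_tree(alpha = 2, seed = 1))
  expect_identical(runif(5), before)  # caller's stream untouched
})

test_that("radii and lengths obey the scaling relation at every ramification", {
  for (a in c(1.3, 2, 3)) {
    tr <- generate_tree(alpha = a, beta = a + 0.4, seed = 7)
    b <- tr$branches
    for (pid in unique(stats::na.omit(b$parent_id))) {
      kids <- b[!is.na(b$parent_id) & b$parent_id == pid, ]
      par <- b[b$id == pid, ]
      expect_identical(nrow(kids), 2L)
      expect_lt(abs(sum(kids$radius^a) - par$radius^a) / par$radius^a, 1e-9)
      bb <- a + 0.4
      expect_lt(abs(sum(kids$length^bb) - par$length^bb) / par$length^bb, 1e-9)
      expect_identical(kids$generation, rep(par$generation + 1L, 2))
      # children start where the parent ends
      expect_equal(kids$x0, rep(par$x1, 2))
      expect_equal(kids$y0, rep(par$y1, 2))
    }
    # endpoint geometry consistent with length and angle
    expect_equal(b$x1, b$x0 + b$length * cos(b$angle))
    expect_equal(b$y1, b$y0 + b$length * sin(b$angle))
  }
})

test_that("stopping rule bounds radii and symmetric trees stop at a fixed generation", {
  tr <- generate_tree(alpha = 2, stop_ratio = 0.1, seed = 5)
  b <- tr$branches
  internal <- b$id %in% b$parent_id
  expect_true(all(b$radius[internal] >= 0.1 * tr$trunk_radius))
  # terminals were cut from a parent at or above the stop radius, so they
  # sit above stop_ratio * r0 * u_min * (1 + u_min^alpha)^(-1/alpha)
  u_min <- tr$asymmetry[1]
  floor_r <- 0.1 * tr$trunk_radius * u_min * (1 + u_min^2)^(-1 / 2)
  expect_true(all(b$radius[!internal] >= floor_r))

  # symmetric tree stopped at generation g: exactly 2^g terminals, and the
  # count equals the transect prediction (r0/r_tip)^alpha as an integer
  for (g in c(4L, 7L)) {
    stop_ratio <- 2^(-(g - 0.5) / 2)  # between gen g-1 and gen g radii
    sym <- generate_tree(alpha = 2, asymmetry_low = 1, asymmetry_high = 1,
                         stop_ratio = stop_ratio, seed = 1)
    bs <- sym$branches
    term <- bs[!(bs$id %in% bs$parent_id), ]
    expect_identical(nrow(term), as.integer(2^g))
    expect_true(all(term$generation == g))
    r_tip <- term$radius[1]
    expect_identical(round(branch_count(sym$trunk_radius, r_tip, 2)), 2^g)
  }
})

test_that("higher alpha yields more ramifications in the same radius contrast", {
  # median over seeds of total branch count is ordered alpha 1 < 2 < 3
  counts <- sapply(1:20, function(s) {
    sapply(c(1, 2, 3), function(a)
      nrow(generate_tree(alpha = a, stop_ratio = 0.1, seed = s)$branches))
  })
  med <- apply(counts, 1, stats::median)
  expect_true(all(diff(med) > 0))
  # and pairwise per seed for the budget-limited default geometry
  expect_true(all(counts[2, ] > counts[1, ]))
  expect_true(all(counts[3, ] > counts[2, ]))
})

test_that("the branch budget guards against runaway recursion", {
  expect_error(generate_tree(alpha = 3, stop_ratio = 0.01, seed = 1,
                             max_branches = 500), "budget")
  expect_error(generate_tree(alpha = 2, stop_ratio = 1.5), "stop_ratio")
  expect_error(generate_tree(alpha = 2, asymmetry_low = 0), "asymmetry")
})

test_that("pareto sampling matches its analytic tail", {
  # inverse-transform endpoints
  expect_equal(1 * 1^(-1 / 2), 1)            # U = 1 -> d = xm
  expect_equal(1 * 0.5^(-1 / 2), sqrt(2))    # U = 1/2, alpha = 2

  s <- sample_diameters(2, 1, 1e5, seed = 12)
  expect_true(all(s$diameters >= 1))
  # P(d >= 2) = (1/2)^2 = 0.25, Monte-Carlo tolerance ~3 sigma
  expect_equal(mean(s$diameters >= 2), 0.25, tolerance = 0.01 / 0.25)

  for (a in c(1.5, 2, 3)) {
    d <- sample_diameters(a, 1, 1e5, seed = 40 + a)$diameters
    expect_lt(ks_to_pareto(d, a, 1), 0.01)
  }
  # reproducible, and scale carries through xm
  expect_identical(sample_diameters(2, 1, 100, seed = 3)$diameters * 7,
                   sample_diameters(2, 7, 100, seed = 3)$diameters)
  expect_error(sample_diameters(2, 1, 0), "at least 1")
  expect_error(sample_diameters(2, -1, 10), "positive")
})

test_that("tree_to_diameters doubles radii and applies seeded noise", {
  tri <- generate_tree(alpha = 2, stop_ratio = 0.75, seed = 2)  # one split
  exact <- tree_to_diameters(tri, noise_cv = 0)
  expect_identical(exact$diameters, 2 * tri$branches$radius)

  noisy1 <- tree_to_diameters(tri, noise_cv = 0.05, seed = 8)
  noisy2 <- tree_to_diameters(tri, noise_cv = 0.05, seed = 8)
  expect_identical(noisy1$diameters, noisy2$diameters)
  expect_false(identical(noisy1$diameters, exact$diameters))
  # median-1 noise: log factors centred on zero
  big <- generate_tree(alpha = 3, seed = 4)
  f <- tree_to_diameters(big, noise_cv = 0.1, seed = 1)$diameters /
    (2 * big$branches$radius)
  expect_equal(stats::median(log(f)), 0, tolerance = 0.02)
})

test_that("estimator round trip recovers alpha from a noisy symmetric tree", {
  # symmetric alpha = 2 tree spanning a 16-fold radius contrast
  sym <- generate_tree(alpha = 2, asymmetry_low = 1, asymmetry_high = 1,
                       stop_ratio = 2^(-7.5 / 2), seed = 1)
  expect_gte(max(sym$branches$radius) / min(sym$branches$radius), 16 * (1 - 1e-9))
  smp <- tree_to_diameters(sym, noise_cv = 0.02, seed = 21)
  fit <- fit_powerlaw(smp, xm = min(smp$diameters), n_boot = 2000, seed = 21)
  expect_gte(2, fit$ci[["lower"]])
  expect_lte(2, fit$ci[["upper"]])
})
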