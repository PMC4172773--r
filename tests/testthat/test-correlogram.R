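test_that("distance classes partition the pairs exactly once", {
  # 4 points on a unit line with breaks (0, 1.5, 3]: 3 short + 3 long pairs
  pts <- cbind(x = 0:3, y = 0)
  cl <- distance_classes(pts, breaks = c(0, 1.5, 3))
  expect_equal(cl$n_pairs, c(3L, 3L))
  expect_equal(sum(cl$n_pairs), choose(4, 2))
  # n = 3: conservation regardless of binning
  cl3 <- distance_classes(cbind(x = c(0, 1, 5), y = 0))
  expect_equal(sum(cl3$n_pairs), 3L)
  expect_error(distance_classes(cbind(x = c(0, 0, 0), y = c(0, 0, 0))),
               "coincident")
  expect_error(distance_classes(pts[1:2, ]), "at least 3")
  # coincident pair lands in the first bin
  cl0 <- distance_classes(cbind(x = c(0, 0, 1, 2), y = 0), breaks = c(0, 1, 2))
  expect_equal(sum(cl0$n_pairs), 6L)
})

test_that("Sturges' rule on the pair count sets the default bin count", {
  set.seed(1)
  pts <- cbind(x = runif(20), y = runif(20))
  cl <- distance_classes(pts)
  expect_length(cl$n_pairs, ceiling(log2(choose(20, 2)) + 1))
  expect_equal(cl$breaks[1], 0)
  expect_equal(cl$breaks[length(cl$breaks)], max(dist(pts)))
})

test_that("Moran's I: alternating pattern, gradient, and brute-force oracle", {
  pts <- cbind(x = 1:4, y = 0)
  cl <- distance_classes(pts, breaks = c(0, 1.5, 3))
  expect_equal(morans_i(c(1, -1, 1, -1), cl, 1), -1, tolerance = 1e-12)
  # smooth gradient on a transect: positive I in the first class
  pts2 <- cbind(x = 1:15, y = 0)
  cl2 <- distance_classes(pts2, breaks = c(0, 2, 15))
  expect_gt(morans_i(1:15 + 0.01 * rnorm(15), cl2, 1), 0)
  # random fields against the double-loop oracle
  for (seed in 1:5) {
    set.seed(seed)
    pts3 <- cbind(x = runif(10, 0, 10), y = runif(10, 0, 10))
    v <- rnorm(10)
    cl3 <- distance_classes(pts3, n_classes = 3)
    for (b in which(cl3$n_pairs > 0))
      expect_equal(morans_i(v, cl3, b),
                   oracle_moran(v, pts3, cl3$breaks[b], cl3$breaks[b + 1],
                                include_lo = b == 1),
                   tolerance = 1e-10)
  }
  expect_error(morans_i(rep(1, 4), cl, 1), "zero variance")
})

test_that("mean of I over shuffles approaches -1/(n-1)", {
  set.seed(7)
  pts <- cbind(x = runif(12), y = runif(12))
  cl <- distance_classes(pts, n_classes = 2)
  v <- rnorm(12)
  sims <- replicate(4000, morans_i(sample(v), cl, 1))
  expect_equal(mean(sims), -1 / 11, tolerance = 0.01)
})

test_that("Moran's I is invariant to affine transforms of the values", {
  set.seed(3)
  pts <- cbind(x = runif(10), y = runif(10))
  cl <- distance_classes(pts, n_classes = 2)
  v <- rnorm(10)
  expect_equal(morans_i(10 - 3.2 * v, cl, 1), morans_i(v, cl, 1),
               tolerance = 1e-10)
})

test_that("observed I agrees with ape's Moran.I on a regular design", {
  # ape::Moran.I row-normalizes its weights; with a constant neighbor count
  # per point that rescaling cancels and the binary-weight I is recovered,
  # so a ring of equidistant points gives an exact external cross-check.
  n <- 12
  th <- 2 * pi * (seq_len(n) - 1) / n
  pts <- cbind(x = 10 * cos(th), y = 10 * sin(th))
  chord <- sqrt(sum((pts[1, ] - pts[2, ])^2))
  cl <- distance_classes(pts, breaks = c(0, chord + 1e-9, 25))
  expect_equal(cl$n_pairs[1], n)  # each point exactly 2 neighbors
  D <- as.matrix(dist(pts))
  W <- (D > 0 & D <= chord + 1e-9) * 1
  for (seed in 1:5) {
    set.seed(seed)
    v <- rnorm(n)
    ref <- ape::Moran.I(v, W)
    expect_equal(morans_i(v, cl, 1), ref$observed, tolerance = 1e-10)
    expect_equal(-1 / (n - 1), ref$expected)
  }
})

test_that("Holm step-down: worked example, bounds, and p.adjust oracle", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(1, 4)), rep(1, 4))
  expect_error(holm_adjust(numeric(0)), "empty")
  expect_error(holm_adjust(c(0.5, 0)), "0, 1")
  for (seed in 1:10) {
    set.seed(seed)
    p <- runif(7)
    adj <- holm_adjust(p)
    expect_equal(adj, p.adjust(p, "holm"), tolerance = 1e-12)
    expect_true(all(adj >= p))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
})

test_that("correlogram is deterministic under a fixed seed", {
  set.seed(2)
  pts <- cbind(x = runif(25, 0, 50), y = runif(25, 0, 50))
  v <- rnorm(25)
  a <- correlogram(v, pts, n_perm = 199, seed = 42)
  b <- correlogram(v, pts, n_perm = 199, seed = 42)
  expect_identical(a, b)
  d <- correlogram(v, pts, n_perm = 199, seed = 43)
  expect_false(identical(a$perm_pvalues, d$perm_pvalues))
  expect_true(all(a$perm_pvalues > 0 & a$perm_pvalues <= 1, na.rm = TRUE))
  expect_true(all(a$holm_pvalues >= a$perm_pvalues, na.rm = TRUE))
  expect_error(correlogram(v, pts, n_perm = 199, seed = "nope"), "seed")
  expect_warning(correlogram(v, pts, n_perm = 49, seed = 1), "resolution")
})

test_that("a planted patchy field yields positive short-range I, crossing near the range", {
  sim <- simulate_cube(sim_config(n_trees = 120, n_years = 4,
                                  spatial_range_m = 15, trend_slope = 0,
                                  pulse_years = numeric(0), noise_sd = 0.4,
                                  seed = 5))
  fit <- run_analysis(sim$cube, "by_year", n_perm = 199, seed = 5)
  cg <- fit$correlogram
  first <- which(cg$n_pairs > 0)[1]
  expect_gt(cg$morans_i[first], 0)
  expect_true(cg$perm_pvalues[first] <= 0.05)
  # beyond the patch scale the correlogram falls below its short-range level
  far <- which(cg$class_centers > 40 & cg$n_pairs > 20)
  expect_true(all(cg$morans_i[far] < cg$morans_i[first]))
})
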