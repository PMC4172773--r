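fit_small <- function(n = 6, p = 3, Tn = 4, seed = 1) {
  st <- rand_std_stack(n, p, Tn, seed)
  comp <- suppressWarnings(
    compromise_pca(build_compromise(st, interstructure(st)), n_axes = 2))
  list(st = st, comp = comp, intra = project_tables(st, comp))
}

test_that("identical tables project onto the compromise's own geometry", {
  v <- array(rnorm(6 * 3), c(6, 3, 1))[, , rep(1, 4)]
  cube <- ring_cube(v, letters[1:6], c("RW", "LW", "RD"), 2000:2003)
  st <- standardize_stack(slice_cube(cube, "by_year"))
  comp <- compromise_pca(build_compromise(st, interstructure(st)))
  intra <- project_tables(st, comp)
  for (k in 1:4) {
    expect_equal(unname(intra$row_coords[k, , ]), unname(comp$row_scores),
                 tolerance = 1e-8)
    # anchor: a table equal to the compromise reproduces its loadings
    expect_equal(unname(intra$var_coords[k, , ]),
                 unname(comp$variable_loadings), tolerance = 1e-8)
  }
})

test_that("row projections match the element-wise matrix-product oracle", {
  f <- fit_small(n = 5, p = 3, Tn = 3, seed = 8)
  V <- f$comp$axes
  for (k in 1:3) {
    Xk <- f$st$tables[[k]]
    manual <- matrix(0, 5, 2)
    for (i in 1:5) for (m in 1:2) for (j in 1:3)
      manual[i, m] <- manual[i, m] + Xk[i, j] * V[j, m]
    expect_equal(unname(f$intra$row_coords[k, , ]), manual, tolerance = 1e-10)
  }
  expect_error(project_tables(f$st, f$comp, n_axes = 10), "available")
})

test_that("envelope bounds follow the pinned type-7 quantile rule", {
  # coords 1..100 in every table: bounds 3.475 / 97.525, six rows flagged
  K <- 3
  rc <- array(rep(1:100, each = K), c(K, 100, 1),
              dimnames = list(paste0("t", 1:K), paste0("r", 1:100), "Axis1"))
  intra <- structure(list(mode = "by_year", row_coords = rc,
                          row_keys = paste0("r", 1:100)),
                     class = "pta_intrastructure")
  out <- envelope_outliers(intra)
  expect_equal(out$envelope$lower, rep(3.475, K), tolerance = 1e-12)
  expect_equal(out$envelope$upper, rep(97.525, K), tolerance = 1e-12)
  flagged <- which(out$outlier_flags[1, ])
  expect_identical(unname(flagged), c(1L, 2L, 3L, 98L, 99L, 100L))
  expect_equal(unname(out$outlier_counts[c(1, 50, 100)]), c(K, 0, K))

  # degenerate all-equal coordinates flag nothing (strict inequality)
  rc0 <- array(5, c(K, 10, 1),
               dimnames = list(paste0("t", 1:K), paste0("r", 1:10), "Axis1"))
  intra0 <- structure(list(mode = "by_year", row_coords = rc0,
                           row_keys = paste0("r", 1:10)),
                      class = "pta_intrastructure")
  expect_equal(sum(envelope_outliers(intra0)$outlier_flags), 0L)
})

test_that("outlier counts aggregate flags and respect scaling invariance", {
  f <- fit_small(n = 40, p = 4, Tn = 6, seed = 3)
  out <- envelope_outliers(f$intra)
  expect_equal(unname(out$outlier_counts),
               unname(colSums(out$outlier_flags)))
  # per table at most 5% + 2/rows outside (type-7 quantile construction)
  frac <- rowMeans(out$outlier_flags)
  expect_true(all(frac <= 0.05 + 2 / 40))
  # common positive rescaling of a table's coordinates changes nothing
  f2 <- f$intra
  f2$row_coords[2, , ] <- 13.7 * f2$row_coords[2, , ]
  out2 <- envelope_outliers(f2)
  expect_identical(out2$outlier_flags, out$outlier_flags)
})

test_that("across = 'tables' computes the envelope over tables at fixed row", {
  f <- fit_small(n = 8, p = 3, Tn = 5, seed = 12)
  out <- envelope_outliers(f$intra, across = "tables")
  co <- f$intra$row_coords[, , 1]
  for (r in seq_len(ncol(co))) {
    q <- quantile(co[, r], c(0.025, 0.975), type = 7, names = FALSE)
    expect_equal(unname(unlist(out$envelope[r, c("lower", "upper")])), q)
    expect_identical(unname(out$outlier_flags[, r]),
                     unname(co[, r] < q[1] | co[, r] > q[2]))
  }
  expect_equal(unname(out$outlier_counts),
               unname(rowSums(out$outlier_flags)))
})

test_that("null-world outlier rate stays near the 5% envelope mass", {
  # no table-specific departures: flags behave like binomial(K, ~0.05)
  rates <- vapply(101:120, function(seed) {
    f <- suppressWarnings(fit_small(n = 60, p = 3, Tn = 5, seed = seed))
    mean(envelope_outliers(f$intra)$outlier_flags)
  }, numeric(1))
  # with 60 rows the type-7 envelope leaves ~2 rows out on each side
  expect_gt(mean(rates), 0.02)
  expect_lt(mean(rates), 0.05 + 2 / 60)
})

test_that("quantiles need at least 3 values", {
  rc <- array(1:4, c(2, 2, 1),
              dimnames = list(c("a", "b"), c("r1", "r2"), "Axis1"))
  intra <- structure(list(mode = "by_year", row_coords = rc,
                          row_keys = c("r1", "r2")),
                     class = "pta_intrastructure")
  expect_error(envelope_outliers(intra), "at least 3")
  expect_error(envelope_outliers(intra, across = "tables"), "at least 3")
})
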