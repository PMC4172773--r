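test_that("vectorial correlation: self, sign flip, and brute-force oracle", {
  st <- rand_std_stack(n = 4, p = 2, Tn = 3, seed = 3)
  xk <- st$tables[[1]]; xl <- st$tables[[2]]
  expect_equal(vectorial_correlation(xk, xk), 1, tolerance = 1e-12)
  expect_equal(vectorial_correlation(xk, xk, method = "rv"), 1,
               tolerance = 1e-12)
  expect_equal(vectorial_correlation(xk, -xk), -1, tolerance = 1e-12)
  for (seed in 1:10) {
    st2 <- rand_std_stack(n = 4, p = 2, Tn = 2, seed = seed)
    a <- st2$tables[[1]]; b <- st2$tables[[2]]
    expect_equal(vectorial_correlation(a, b), oracle_mean_cor(a, b),
                 tolerance = 1e-12)
  }
  expect_error(vectorial_correlation(xk, xl[1:3, ]), "identical dimensions")
  expect_error(vectorial_correlation(xk + 5, xl), "standardized")
})

test_that("mean_cor and rv coincide on standardized equal-norm tables", {
  # population standardization gives every table Frobenius norm sqrt(n p)
  st <- rand_std_stack(n = 9, p = 4, Tn = 5, seed = 21)
  for (k in 1:4) {
    a <- st$tables[[k]]; b <- st$tables[[k + 1]]
    expect_equal(vectorial_correlation(a, b, "mean_cor"),
                 vectorial_correlation(a, b, "rv"), tolerance = 1e-10)
  }
})

test_that("interstructure matrix is symmetric with unit diagonal", {
  st <- rand_std_stack(n = 8, p = 3, Tn = 6, seed = 5)
  res <- interstructure_matrix(st)
  R <- res$r_matrix
  expect_identical(dim(R), c(6L, 6L))
  expect_equal(max(abs(R - t(R))), 0)
  expect_equal(unname(diag(R)), rep(1, 6), tolerance = 1e-12)
  one <- slice_cube(rand_cube(4, 2, 1, 1), "by_year")
  expect_error(interstructure_matrix(standardize_stack(one)), "at least 2")
})

test_that("identical tables give the rank-one limit exactly", {
  v <- array(rnorm(5 * 3), c(5, 3, 1))[, , rep(1, 4)]  # 4 identical years
  cube <- ring_cube(v, letters[1:5], c("RW", "LW", "RD"), 2000:2003)
  st <- standardize_stack(slice_cube(cube, "by_year"))
  inter <- interstructure(st)
  expect_equal(unname(inter$r_matrix), matrix(1, 4, 4), tolerance = 1e-12)
  expect_equal(inter$eigenvalues[1], 4, tolerance = 1e-10)
  expect_equal(inter$eigenvalues[-1], rep(0, 3), tolerance = 1e-10)
  expect_equal(unname(inter$weights), rep(1 / 4, 4), tolerance = 1e-10)
})

test_that("identity inter-table matrix spreads inertia uniformly", {
  res <- structure(list(r_matrix = diag(3), method = "mean_cor",
                        mode = "by_year"),
                   class = "pta_interstructure")
  res <- interstructure_eigen(res)
  expect_equal(res$inertia_pct, rep(100 / 3, 3), tolerance = 1e-10)
  expect_equal(sum(res$eigenvalues), 3, tolerance = 1e-10)
})

test_that("eigenvalues match the characteristic-polynomial oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    B <- matrix(rnorm(25), 5)
    A <- crossprod(B) / 5  # random symmetric PSD
    res <- structure(list(r_matrix = A, method = "mean_cor", mode = "x"),
                     class = "pta_interstructure")
    res <- suppressWarnings(interstructure_eigen(res))
    expect_equal(res$eigenvalues, oracle_eigenvalues(A), tolerance = 1e-8)
    expect_equal(sum(res$eigenvalues), sum(diag(A)), tolerance = 1e-8)
  }
})

test_that("all-positive R implies one-signed axis-1 scores and weights", {
  for (seed in 1:10) {
    # correlated tables: common structure plus noise keeps all R > 0
    set.seed(seed)
    base <- matrix(rnorm(8 * 3), 8, 3)
    v <- array(NA_real_, c(8, 3, 5))
    for (t in 1:5) v[, , t] <- base + 0.3 * matrix(rnorm(24), 8, 3)
    cube <- ring_cube(v, letters[1:8], c("RW", "LW", "RD"), 2000:2004)
    inter <- interstructure(standardize_stack(slice_cube(cube, "by_year")))
    expect_true(all(inter$r_matrix > 0))
    s1 <- inter$table_scores[, 1]
    expect_true(all(s1 > 0) || all(s1 < 0))
    expect_true(all(inter$weights > 0))
    expect_equal(sum(inter$weights), 1, tolerance = 1e-12)
  }
})

test_that("permuting table order permutes R and weights consistently", {
  st <- rand_std_stack(n = 6, p = 3, Tn = 5, seed = 13)
  perm <- c(3, 1, 5, 2, 4)
  stp <- st
  stp$tables <- st$tables[perm]
  stp$table_keys <- st$table_keys[perm]
  a <- suppressWarnings(interstructure(st))
  b <- suppressWarnings(interstructure(stp))
  expect_equal(unname(b$r_matrix), unname(a$r_matrix[perm, perm]),
               tolerance = 1e-12)
  expect_equal(unname(b$weights), unname(a$weights[perm]), tolerance = 1e-10)
  expect_equal(b$eigenvalues, a$eigenvalues, tolerance = 1e-10)
})

test_that("non-symmetric matrices are rejected", {
  res <- structure(list(r_matrix = matrix(c(1, 0.5, 0.2, 1), 2),
                        method = "mean_cor", mode = "x"),
                   class = "pta_interstructure")
  expect_error(interstructure_eigen(res), "not symmetric")
})
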