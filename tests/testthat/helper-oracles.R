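# Independent brute-force oracles. These deliberately avoid the code paths
# they are used to check (no eigen() for the eigen oracle, explicit loops for
# the matrix-product oracles).

# eigenvalues via the characteristic polynomial (Faddeev-LeVerrier + polyroot)
oracle_eigenvalues <- function(A) {
  k <- nrow(A)
  coefs <- 1
  M <- diag(k)
  for (j in seq_len(k)) {
    M <- A %*% M
    cj <- -sum(diag(M)) / j
    coefs <- c(coefs, cj)
    M <- M + cj * diag(k)
  }
  sort(Re(polyroot(rev(coefs))), decreasing = TRUE)
}

# Moran's I by explicit double loop over all ordered point pairs
oracle_moran <- function(values, coords, lo, hi, include_lo = FALSE) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0; W <- 0
  for (h in seq_len(n)) for (i in seq_len(n)) {
    if (h == i) next
    d <- sqrt(sum((coords[h, ] - coords[i, ])^2))
    inside <- if (include_lo) d >= lo && d <= hi else d > lo && d <= hi
    if (inside) {
      num <- num + z[h] * z[i]
      W <- W + 1
    }
  }
  (n / W) * num / sum(z^2)
}

# mean of per-column Pearson correlations, computed from first principles
oracle_mean_cor <- function(xk, xl) {
  p <- ncol(xk)
  out <- numeric(p)
  for (j in seq_len(p)) {
    a <- xk[, j] - mean(xk[, j]); b <- xl[, j] - mean(xl[, j])
    out[j] <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }
  mean(out)
}

# random complete cube with coordinates
rand_cube <- function(n = 6, p = 3, Tn = 4, seed = 1) {
  set.seed(seed)
  ring_cube(array(rnorm(n * p * Tn), c(n, p, Tn)),
            sprintf("t%02d", seq_len(n)), paste0("V", seq_len(p)),
            2000 + seq_len(Tn),
            coords = cbind(x = runif(n, 0, 50), y = runif(n, 0, 50)))
}

# standardized random stack
rand_std_stack <- function(n = 6, p = 3, Tn = 4, seed = 1,
                           mode = "by_year") {
  standardize_stack(slice_cube(rand_cube(n, p, Tn, seed), mode))
}

# long-format TSV for a tiny cube, returning the temp path
write_toy_long <- function(df, sep = "\t") {
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = sep, row.names = FALSE, quote = FALSE)
  f
}

# location of the original deposited ring file, if the user has supplied it
dataset_s1_path <- function() {
  p <- getOption("ptacube.dataset_s1", Sys.getenv("PTACUBE_DATASET_S1", ""))
  if (is.character(p) && nzchar(p) && file.exists(p)) p else NULL
}
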