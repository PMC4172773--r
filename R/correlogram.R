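#' Distance classes for a correlogram
#'
#' Partitions the n(n-1)/2 inter-point distances into bins. The default is
#' equal-width bins from 0 to the maximum inter-point distance, the bin count
#' set by Sturges' rule on the pair count (`ceiling(log2(P) + 1)`). Each pair
#' falls in exactly one class; coincident points (distance 0) fall in the
#' first. Classes with fewer than 20 pairs are flagged unreliable.
#'
#' @param coords n x 2 matrix of planar coordinates (meters).
#' @param n_classes override the Sturges bin count.
#' @param breaks explicit increasing break vector (overrides `n_classes`);
#'   first break at 0, last at or above the maximum distance.
#' @return a `distance_classes` list: `breaks`, `centers`, `n_pairs`,
#'   `reliable`, and `pairs` (per class, a 2-column index matrix).
#' @export
distance_classes <- function(coords, n_classes = NULL, breaks = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 3L) stop("need at least 3 points")
  d <- as.vector(stats::dist(coords))
  if (max(d) == 0) stop("all points coincident")
  P <- length(d)
  if (is.null(breaks)) {
    if (is.null(n_classes)) n_classes <- ceiling(log2(P) + 1)
    breaks <- seq(0, max(d), length.out = n_classes + 1)
  } else {
    breaks <- sort(unique(as.numeric(breaks)))
    if (breaks[1] > 0) breaks <- c(0, breaks)
    if (max(d) > breaks[length(breaks)])
      stop("largest distance ", format(max(d)), " exceeds last break")
  }
  nb <- length(breaks) - 1L
  cls <- findInterval(d, breaks, rightmost.closed = TRUE, left.open = TRUE)
  cls[d == 0] <- 1L
  # pair index (h, i) in the same order as dist(): column-major lower triangle
  h <- rep(seq_len(n - 1), times = (n - 1):1)
  i <- unlist(lapply(seq_len(n - 1), function(k) (k + 1):n))
  pairs <- lapply(seq_len(nb), function(b) {
    sel <- cls == b
    cbind(h = h[sel], i = i[sel])
  })
  n_pairs <- vapply(pairs, nrow, integer(1))
  stopifnot(sum(n_pairs) == P)
  structure(list(breaks = breaks,
                 centers = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 n_pairs = n_pairs, reliable = n_pairs >= 20,
                 pairs = pairs, n_points = n),
            class = "distance_classes")
}

# Moran's I for centered values z over one pair set (binary symmetric weights)
.moran_pairs <- function(z, pairs) {
  n <- length(z)
  P <- nrow(pairs)
  S <- sum(z[pairs[, 1]] * z[pairs[, 2]])
  (n * S) / (P * sum(z^2))
}

#' Moran's I for one distance class
#'
#' `I(d) = (n/W) * sum_hi w_hi z_h z_i / sum_i z_i^2` with binary weights
#' `w_hi = 1` for pairs in the class, `z` the centered values. Under
#' exchangeability its expectation is `-1/(n-1)`.
#'
#' @param values numeric vector, one value per point.
#' @param classes a [distance_classes()] structure.
#' @param class index of the class to evaluate.
#' @return the Moran's I statistic.
#' @export
morans_i <- function(values, classes, class = 1L) {
  stopifnot(inherits(classes, "distance_classes"))
  if (length(values) != classes$n_points)
    stop("values length does not match the points used for the classes")
  if (stats::var(values) == 0) stop("values have zero variance")
  pairs <- classes$pairs[[class]]
  if (is.null(pairs) || nrow(pairs) == 0) stop("class ", class, " has no pairs")
  .moran_pairs(values - mean(values), pairs)
}

#' Holm step-down adjustment
#'
#' `adj_(i) = max_{j <= i} min(1, (m - j + 1) * p_(j))` over the ascending
#' order statistics, mapped back to the input order. Never below the input;
#' monotone in the sorted order.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
holm_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) stop("empty p-value vector")
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(pvalues)
  o <- order(pvalues)
  adj <- pmin(1, (m - seq_len(m) + 1) * pvalues[o])
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Moran's I permutation correlogram with Holm correction
#'
#' Computes Moran's I per distance class, then assesses each class by random
#' permutation of the values over the points: one shared, seeded permutation
#' stream is used for every class, and the class-wise p-value is the add-one
#' two-sided tail `(1 + #(|I_perm - E| >= |I_obs - E|)) / (n_perm + 1)` with
#' `E = -1/(n-1)`. Holm's step-down is applied across the tested classes and
#' the correlogram is declared globally significant when the smallest
#' Holm-adjusted p-value is at or below `alpha` (equivalently, min p <=
#' alpha/m — note this needs `n_perm + 1 >= m/alpha` to be attainable at
#' all).
#'
#' @param values numeric vector, one value per point.
#' @param coords n x 2 coordinate matrix.
#' @param classes optional precomputed [distance_classes()]; built from
#'   `coords` with defaults otherwise.
#' @param n_perm number of permutations (default 1000; < 99 draws a warning).
#' @param seed mandatory integer seed for the permutation stream.
#' @param alpha significance level for the global call.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return a `moran_correlogram` object: `class_breaks`, `class_centers`,
#'   `n_pairs`, `reliable`, `morans_i`, `expected_i`, `perm_pvalues`,
#'   `holm_pvalues`, `globally_significant`, `n_permutations`, `seed`,
#'   `alpha`, `alternative`.
#' @export
correlogram <- function(values, coords, classes = NULL, n_perm = 1000L,
                        seed, alpha = 0.05,
                        alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (missing(seed) || is.null(seed) || is.na(suppressWarnings(as.integer(seed))))
    stop("a valid integer seed is required for the permutation stream")
  seed <- as.integer(seed)
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("n_perm must be positive")
  if (n_perm < 99L)
    warning("n_perm = ", n_perm, " gives a minimum p-value of ",
            format(1 / (n_perm + 1)), "; resolution may be insufficient")
  coords <- as.matrix(coords)
  if (length(values) != nrow(coords))
    stop("values and coords are not aligned")
  if (stats::var(values) == 0) stop("values have zero variance")
  if (is.null(classes)) classes <- distance_classes(coords)
  nb <- length(classes$n_pairs)
  tested <- which(classes$n_pairs > 0)
  n <- length(values)
  e_i <- -1 / (n - 1)
  z <- values - mean(values)
  i_obs <- rep(NA_real_, nb)
  for (b in tested) i_obs[b] <- .moran_pairs(z, classes$pairs[[b]])

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  exceed <- integer(nb)
  stat <- function(i_val) switch(alternative,
    two.sided = abs(i_val - e_i),
    greater   = i_val - e_i,
    less      = e_i - i_val)
  s_obs <- stat(i_obs)
  for (r in seq_len(n_perm)) {
    zp <- z[sample.int(n)]
    for (b in tested) {
      ip <- .moran_pairs(zp, classes$pairs[[b]])
      if (stat(ip) >= s_obs[b]) exceed[b] <- exceed[b] + 1L
    }
  }
  pv <- rep(NA_real_, nb)
  pv[tested] <- (1 + exceed[tested]) / (n_perm + 1)
  hp <- rep(NA_real_, nb)
  hp[tested] <- holm_adjust(pv[tested])
  structure(list(class_breaks = classes$breaks,
                 class_centers = classes$centers,
                 n_pairs = classes$n_pairs, reliable = classes$reliable,
                 morans_i = i_obs, expected_i = e_i,
                 perm_pvalues = pv, holm_pvalues = hp,
                 globally_significant = min(hp, na.rm = TRUE) <= alpha,
                 n_permutations = n_perm, seed = seed, alpha = alpha,
                 alternative = alternative),
            class = "moran_correlogram")
}

#' @export
print.moran_correlogram <- function(x, ...) {
  cat("moran_correlogram: ", length(x$class_centers), " classes, ",
      x$n_permutations, " permutations (seed ", x$seed, ")\n", sep = "")
  df <- data.frame(center = round(x$class_centers, 2), n_pairs = x$n_pairs,
                   I = round(x$morans_i, 4), p = x$perm_pvalues,
                   p_holm = round(x$holm_pvalues, 4))
  print(df, row.names = FALSE)
  cat("globally significant at alpha = ", x$alpha, ": ",
      x$globally_significant, "\n", sep = "")
  invisible(x)
}
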