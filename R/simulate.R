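#' Default descriptor loading patterns for the simulator
#'
#' Sign/magnitude patterns over the 11 standard ring descriptors that mimic
#' the structures the analysis is meant to recover: a patchy between-tree
#' factor loading positively on MAD, LD, RW, Co and RSD (dense-latewood
#' trees), a defoliation-like pulse depressing growth and latewood density,
#' and a warming-like trend lowering earlywood density (ED, MID) while
#' raising latewood density (LD).
#'
#' @param which one of `"spatial"`, `"pulse"`, `"trend"`.
#' @return a named numeric vector over [ring_descriptor_codes()].
#' @export
default_loadings <- function(which = c("spatial", "pulse", "trend")) {
  which <- match.arg(which)
  codes <- ring_descriptor_codes()
  v <- switch(which,
    spatial = c(RW = 0.7, LW = 0.3, RD = 0.4, ED = 0.2, LD = 0.9, MID = 0.1,
                MAD = 0.9, Co = 0.8, RSD = 0.8, ESD = 0.4, LSD = 0.5),
    pulse   = c(RW = -0.8, LW = -0.5, RD = -0.4, ED = 0.1, LD = -0.9,
                MID = 0.2, MAD = -0.8, Co = -0.7, RSD = -0.6, ESD = -0.2,
                LSD = -0.3),
    trend   = c(RW = 0.1, LW = 0.3, RD = -0.3, ED = -0.8, LD = 0.7,
                MID = -0.8, MAD = 0.5, Co = 0.6, RSD = 0.5, ESD = 0.2,
                LSD = 0.3))
  v[codes]
}

#' Configuration of the synthetic datacube generator
#'
#' The defaults state a world shaped like a 149-tree larch stand followed
#' over 41 years (1967-2007) on a 95 m x 60 m plot (diagonal 112 m, the
#' scale of the largest inter-tree distances reported for such stands):
#' a spatially autocorrelated between-tree factor with an exponential
#' correlation range of 15 m (patches of 30-40 m), five defoliation-like
#' pulse years, a smooth monotone trend, and i.i.d. Gaussian residual noise
#' at signal-to-noise 2 (`noise_sd = 0.5 * ||loadings_spatial||`).
#'
#' @param n_trees,n_years dimensions of the cube (n_trees >= 3).
#' @param start_year first calendar year.
#' @param loadings_spatial,loadings_pulse,loadings_trend length-p descriptor
#'   loading vectors (defaults: [default_loadings()]).
#' @param spatial_range_m range (m) of the isotropic exponential correlation
#'   of the between-tree factor.
#' @param pulse_years named numeric vector, names = calendar years, values =
#'   pulse amplitudes; `NULL` states the default world: pulses at the 6th,
#'   13th, 14th, 30th and 41st years (when present) with amplitude
#'   `3 * noise_sd`.
#' @param trend_slope multiplier of the standardized linear trend.
#' @param noise_sd residual standard deviation; `NULL` = `0.5 *
#'   ||loadings_spatial||` (signal-to-noise 2).
#' @param plot_size_m width/height of the plot rectangle (m).
#' @param seed integer seed; same seed, same cube, bit for bit.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_trees = 149L, n_years = 41L, start_year = 1967L,
                       loadings_spatial = default_loadings("spatial"),
                       loadings_pulse = default_loadings("pulse"),
                       loadings_trend = default_loadings("trend"),
                       spatial_range_m = 15, pulse_years = NULL,
                       trend_slope = 1, noise_sd = NULL,
                       plot_size_m = c(95, 60), seed = 1L) {
  if (n_trees < 3L) stop("n_trees must be at least 3")
  p <- length(loadings_spatial)
  if (length(loadings_pulse) != p || length(loadings_trend) != p)
    stop("loading vectors must share one length")
  if (is.null(noise_sd)) noise_sd <- 0.5 * sqrt(sum(loadings_spatial^2))
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  years <- seq.int(start_year, length.out = n_years)
  if (is.null(pulse_years)) {
    at <- intersect(c(6L, 13L, 14L, 30L, 41L), seq_len(n_years))
    pulse_years <- stats::setNames(rep(3 * noise_sd, length(at)),
                                   years[at])
  }
  py <- as.integer(names(pulse_years))
  if (length(py) && !all(py %in% years))
    stop("pulse year(s) outside the simulated span: ",
         paste(setdiff(py, years), collapse = ", "))
  structure(list(n_trees = as.integer(n_trees), n_years = as.integer(n_years),
                 start_year = as.integer(start_year),
                 loadings_spatial = loadings_spatial,
                 loadings_pulse = loadings_pulse,
                 loadings_trend = loadings_trend,
                 spatial_range_m = spatial_range_m,
                 pulse_years = pulse_years, trend_slope = trend_slope,
                 noise_sd = noise_sd, plot_size_m = plot_size_m,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# population-sd standardization of a vector
.std <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) stop("cannot standardize a constant vector")
  (x - mean(x)) / s
}

#' Simulate a datacube with known latent structure
#'
#' Draws tree coordinates uniformly on the plot rectangle, a spatial factor
#' `s` as a standardized Gaussian-process realization with isotropic
#' exponential correlation `exp(-d / range)` (falling back to a
#' sum-of-Gaussian-bumps field with a warning if the covariance factorization
#' fails), a pulse series `f` nonzero only at the pulse years, and a
#' standardized linear trend `g`, then assembles
#' `X[i, j, t] = a_j s_i + b_j f_t + c_j g_t + e_ijt`,
#' `e ~ N(0, noise_sd^2)` i.i.d.
#'
#' @param config a [sim_config()].
#' @return a list with `cube` (a [ring_cube()]) and `truth` (class
#'   `latent_truth`: `tree_coords`, `spatial_factor`, `temporal_pulse`,
#'   `temporal_trend`, `seed`).
#' @export
simulate_cube <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  n <- config$n_trees; Tn <- config$n_years
  p <- length(config$loadings_spatial)
  years <- seq.int(config$start_year, length.out = Tn)
  coords <- cbind(x = stats::runif(n, 0, config$plot_size_m[1]),
                  y = stats::runif(n, 0, config$plot_size_m[2]))
  s <- .sim_spatial_factor(coords, config$spatial_range_m)
  f <- stats::setNames(rep(0, Tn), years)
  if (length(config$pulse_years))
    f[names(config$pulse_years)] <- config$pulse_years
  g <- config$trend_slope * .std(seq_len(Tn))
  a <- config$loadings_spatial
  b <- config$loadings_pulse
  cc <- config$loadings_trend
  X <- outer(s, a) %o% rep(1, Tn) +
    rep(1, n) %o% outer(b, f) +
    rep(1, n) %o% outer(cc, g)
  if (config$noise_sd > 0)
    X <- X + array(stats::rnorm(n * p * Tn, sd = config$noise_sd), c(n, p, Tn))
  cube <- ring_cube(X, sprintf("T%03d", seq_len(n)),
                    names(a) %||% paste0("V", seq_len(p)),
                    years, coords = coords)
  truth <- structure(list(tree_coords = coords, spatial_factor = s,
                          temporal_pulse = f, temporal_trend = g,
                          seed = config$seed, config = config),
                     class = "latent_truth")
  list(cube = cube, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# GP with exponential correlation; bump-field fallback
.sim_spatial_factor <- function(coords, range_m) {
  n <- nrow(coords)
  D <- as.matrix(stats::dist(coords))
  S <- exp(-D / range_m)
  L <- tryCatch(chol(S + diag(1e-8, n)), error = function(e) NULL)
  if (!is.null(L)) {
    s <- drop(t(L) %*% stats::rnorm(n))
  } else {
    warning("covariance factorization failed; using sum-of-bumps field")
    area <- diff(range(coords[, 1])) * diff(range(coords[, 2]))
    m <- max(5L, ceiling(area / (pi * range_m^2)))
    cx <- stats::runif(m, min(coords[, 1]), max(coords[, 1]))
    cy <- stats::runif(m, min(coords[, 2]), max(coords[, 2]))
    eta <- stats::rnorm(m)
    s <- vapply(seq_len(n), function(i) {
      d2 <- (coords[i, 1] - cx)^2 + (coords[i, 2] - cy)^2
      sum(eta * exp(-d2 / (2 * range_m^2)))
    }, numeric(1))
  }
  .std(s)
}

#' Recovery metrics against the planted truth
#'
#' Compares a fitted pipeline bundle with the latent structure that
#' generated its cube: the absolute correlation between each retained
#' compromise axis and each applicable latent factor, whether the planted
#' pulse years are the most extreme dates on the axis best aligned with the
#' pulse, and (when a correlogram was run) whether the spatial structure was
#' detected.
#'
#' @param fit a `pta_result` from [run_analysis()] on a simulated cube.
#' @param truth the matching `latent_truth`.
#' @return a list of class `recovery_report`: `mode`, `cor` (matrix factors x
#'   axes of absolute correlations), `best` (named vector, max |cor| per
#'   factor), `pulse_rank_recovered`, `moran_significant`.
#' @export
recovery_metrics <- function(fit, truth) {
  stopifnot(inherits(fit, "pta_result"), inherits(truth, "latent_truth"))
  scores <- fit$compromise$row_scores
  m <- ncol(scores)
  if (fit$mode == "by_year") {
    if (nrow(scores) != length(truth$spatial_factor))
      stop("fit/truth dimension mismatch: ", nrow(scores), " trees vs ",
           length(truth$spatial_factor))
    fac <- list(spatial = truth$spatial_factor)
  } else {
    if (nrow(scores) != length(truth$temporal_pulse))
      stop("fit/truth dimension mismatch: ", nrow(scores), " dates vs ",
           length(truth$temporal_pulse))
    fac <- list(pulse = truth$temporal_pulse,
                trend = truth$temporal_trend)
  }
  cors <- matrix(NA_real_, length(fac), m,
                 dimnames = list(names(fac), colnames(scores)))
  for (i in seq_along(fac))
    for (j in seq_len(m))
      cors[i, j] <- if (stats::sd(fac[[i]]) == 0) NA_real_ else
        abs(stats::cor(fac[[i]], scores[, j]))
  best <- apply(cors, 1, max)
  pulse_ok <- NA
  if (fit$mode == "by_tree" && any(truth$temporal_pulse != 0)) {
    ax <- which.max(cors["pulse", ])
    k <- sum(truth$temporal_pulse != 0)
    sc <- scores[, ax]
    extreme <- order(abs(sc - stats::median(sc)), decreasing = TRUE)[seq_len(k)]
    pulse_ok <- setequal(rownames(scores)[extreme],
                         names(truth$temporal_pulse)[truth$temporal_pulse != 0])
  }
  structure(list(mode = fit$mode, cor = cors, best = best,
                 pulse_rank_recovered = pulse_ok,
                 moran_significant = if (!is.null(fit$correlogram))
                   fit$correlogram$globally_significant else NA),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("recovery_report (", x$mode, ")\n", sep = "")
  print(round(x$cor, 3))
  if (!is.na(x$pulse_rank_recovered))
    cat("pulse years most extreme: ", x$pulse_rank_recovered, "\n", sep = "")
  if (!is.na(x$moran_significant))
    cat("Moran correlogram globally significant: ", x$moran_significant,
        "\n", sep = "")
  invisible(x)
}
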