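#' Vectorial correlation between two same-shaped tables
#'
#' Scalar similarity in `[-1, 1]` between two standardized two-way tables.
#' `"mean_cor"` is the mean over descriptors of the per-column Pearson
#' correlations; `"rv"` is the normalized Frobenius inner product
#' `<Xk, Xl> / (||Xk|| ||Xl||)`. The two coincide when all columns are
#' standardized with a common denominator and the tables have equal
#' Frobenius norm.
#'
#' @param xk,xl numeric matrices of identical dimension, columns standardized.
#' @param method `"mean_cor"` (default) or `"rv"`.
#' @param check verify standardization (mean 0 columns) before computing.
#' @return a scalar in `[-1, 1]`.
#' @export
vectorial_correlation <- function(xk, xl, method = c("mean_cor", "rv"),
                                  check = TRUE) {
  method <- match.arg(method)
  if (!identical(dim(xk), dim(xl)))
    stop("tables must have identical dimensions")
  if (check) {
    mx <- max(abs(colMeans(xk)), abs(colMeans(xl)))
    if (mx > 1e-8)
      stop("tables do not look standardized (max |column mean| = ",
           format(mx), "); run standardize_stack() first")
  }
  if (method == "mean_cor") {
    p <- ncol(xk)
    r <- vapply(seq_len(p),
                function(j) stats::cor(xk[, j], xl[, j]), numeric(1))
    mean(r)
  } else {
    num <- sum(xk * xl)
    den <- sqrt(sum(xk^2)) * sqrt(sum(xl^2))
    if (den == 0) stop("zero-norm table in RV coefficient")
    num / den
  }
}

#' Inter-table correlation matrix (interstructure, step 1)
#'
#' Builds the K x K symmetric matrix of vectorial correlations between all
#' pairs of standardized tables in the stack: the inter-date matrix for the
#' by-year orientation, the inter-tree matrix for the by-tree orientation.
#'
#' @param stack a standardized `table_stack` with K >= 2 tables.
#' @param method inter-table coefficient, see [vectorial_correlation()].
#' @return an object of class `pta_interstructure` with `r_matrix` filled;
#'   complete it with [interstructure_eigen()], or use [interstructure()]
#'   for both steps.
#' @export
interstructure_matrix <- function(stack, method = c("mean_cor", "rv")) {
  method <- match.arg(method)
  stopifnot(inherits(stack, "table_stack"))
  if (!isTRUE(stack$standardized))
    stop("stack must be standardized")
  K <- length(stack$tables)
  if (K < 2L) stop("need at least 2 tables, got ", K)
  R <- diag(1, K)
  for (k in seq_len(K - 1))
    for (l in seq((k + 1), K)) {
      R[k, l] <- R[l, k] <- vectorial_correlation(
        stack$tables[[k]], stack$tables[[l]], method = method, check = FALSE)
    }
  if (method == "rv")  # self-RV is exactly 1; mean_cor diagonal already 1
    diag(R) <- 1
  dimnames(R) <- list(names(stack$tables), names(stack$tables))
  structure(list(r_matrix = R, method = method,
                 table_keys = stack$table_keys, mode = stack$mode,
                 eigenvalues = NULL, table_scores = NULL,
                 weights = NULL, inertia_pct = NULL),
            class = "pta_interstructure")
}

#' Eigen-analysis of the interstructure (typology and compromise weights)
#'
#' Non-centered principal component analysis of the inter-table matrix:
#' a symmetric eigendecomposition of `r_matrix` as is. Table scores on
#' component m are `sqrt(lambda_m) * eigenvector_m` (the typology plot).
#' Compromise weights are the entries of the leading eigenvector, sign-fixed
#' so the majority is positive, any residual negative entries floored at 0
#' with a warning, and renormalized to sum 1.
#'
#' @param inter a `pta_interstructure` from [interstructure_matrix()].
#' @param n_axes number of score axes to keep (default 2).
#' @return the completed `pta_interstructure`: `eigenvalues`, `inertia_pct`,
#'   `table_scores`, `weights`.
#' @export
interstructure_eigen <- function(inter, n_axes = 2L) {
  stopifnot(inherits(inter, "pta_interstructure"))
  R <- inter$r_matrix
  if (max(abs(R - t(R))) > 1e-8)
    stop("inter-table matrix is not symmetric")
  K <- nrow(R)
  eig <- eigen((R + t(R)) / 2, symmetric = TRUE)
  lam <- eig$values
  inter$eigenvalues <- lam
  inter$inertia_pct <- 100 * lam / sum(lam)
  n_axes <- min(n_axes, K)
  sc <- eig$vectors[, seq_len(n_axes), drop = FALSE] %*%
    diag(sqrt(pmax(lam[seq_len(n_axes)], 0)), n_axes)
  # sign convention: majority-positive per axis, tie broken on first table
  for (m in seq_len(n_axes)) {
    s <- sum(sign(sc[, m]))
    flip <- if (s != 0) s < 0 else sc[1, m] < 0
    if (flip) sc[, m] <- -sc[, m]
  }
  dimnames(sc) <- list(rownames(R), paste0("Axis", seq_len(n_axes)))
  inter$table_scores <- sc
  w <- eig$vectors[, 1]
  if (sum(sign(w)) < 0 || (sum(sign(w)) == 0 && w[1] < 0)) w <- -w
  if (any(w < 0)) {
    warning(sum(w < 0), " negative first-eigenvector entr(ies) floored at 0 ",
            "for the compromise weights")
    w[w < 0] <- 0
  }
  if (sum(w) == 0) stop("degenerate leading eigenvector; no usable weights")
  inter$weights <- stats::setNames(w / sum(w), rownames(R))
  inter
}

#' Interstructure analysis in one call
#'
#' [interstructure_matrix()] followed by [interstructure_eigen()].
#'
#' @inheritParams interstructure_matrix
#' @inheritParams interstructure_eigen
#' @return a completed `pta_interstructure`.
#' @export
interstructure <- function(stack, method = c("mean_cor", "rv"), n_axes = 2L) {
  interstructure_eigen(interstructure_matrix(stack, method), n_axes = n_axes)
}

#' @export
print.pta_interstructure <- function(x, ...) {
  cat("pta_interstructure (", x$mode, ", ", x$method, "): ",
      nrow(x$r_matrix), " tables\n", sep = "")
  if (!is.null(x$inertia_pct))
    cat("  inertia: ",
        paste(sprintf("%.1f%%", utils::head(x$inertia_pct, 4)),
              collapse = ", "), "\n", sep = "")
  invisible(x)
}
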