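#' Build the compromise table (step 2)
#'
#' The compromise is the weights-weighted sum of the standardized tables,
#' `sum_k alpha_k X_k` with `sum alpha_k = 1`: the two-way table expressing
#' the structure common to all tables (the stable spatial typology of trees
#' in the by-year orientation, the shared temporal trajectory in the by-tree
#' orientation).
#'
#' @param stack a standardized `table_stack`.
#' @param inter a completed `pta_interstructure` holding the weights, or a
#'   numeric weight vector of length K summing to 1.
#' @return an object of class `pta_compromise` with `table` filled; complete
#'   it with [compromise_pca()].
#' @export
build_compromise <- function(stack, inter) {
  stopifnot(inherits(stack, "table_stack"))
  if (!isTRUE(stack$standardized)) stop("stack must be standardized")
  w <- if (inherits(inter, "pta_interstructure")) inter$weights else inter
  if (is.null(w)) stop("interstructure has no weights; run interstructure_eigen()")
  K <- length(stack$tables)
  if (length(w) != K)
    stop("weight count (", length(w), ") does not match table count (", K, ")")
  if (any(w < 0)) stop("compromise weights must be nonnegative")
  M <- stack$tables[[1]] * w[1]
  for (k in seq_len(K)[-1]) M <- M + stack$tables[[k]] * w[k]
  dimnames(M) <- list(stack$row_keys, stack$var_names)
  structure(list(table = M, weights_used = w, mode = stack$mode,
                 pca_eigenvalues = NULL, inertia_pct = NULL,
                 variable_loadings = NULL, row_scores = NULL,
                 axes = NULL, svd = NULL),
            class = "pta_compromise")
}

#' PCA of the compromise table (step 2, decomposition)
#'
#' Singular value decomposition of the compromise. No re-centering is applied
#' by default: the weighted mean of column-centered tables is itself
#' column-centered, which is verified at run time (tolerance 1e-8). Axis
#' eigenvalues use uniform row weights 1/n; inertia percentages are the
#' squared-singular-value shares. Row scores are principal coordinates
#' (`U d`); variable loadings are the correlations between compromise columns
#' and the score axes (correlation-circle coordinates). Each axis is
#' sign-fixed so the descriptor with the largest-magnitude loading loads
#' positively.
#'
#' @param comp a `pta_compromise` from [build_compromise()].
#' @param n_axes number of axes to retain in scores/loadings (default 2).
#' @param center force re-centering of the compromise columns first.
#' @param rescale also re-scale compromise columns to unit (population) sd
#'   before decomposing (off by default; the compromise columns keep the
#'   relative strengths they inherited from the averaging).
#' @return the completed `pta_compromise`: `pca_eigenvalues`, `inertia_pct`,
#'   `row_scores`, `variable_loadings`, `axes` (unit variable axes used for
#'   intrastructure projection), `svd` (full decomposition).
#' @export
compromise_pca <- function(comp, n_axes = 2L, center = FALSE,
                           rescale = FALSE) {
  stopifnot(inherits(comp, "pta_compromise"))
  M <- comp$table
  n <- nrow(M)
  if (center) M <- sweep(M, 2, colMeans(M), "-")
  cm <- max(abs(colMeans(M)))
  if (cm > 1e-8)
    stop("compromise columns are not centered (max |mean| = ", format(cm),
         "); standardize the stack or set center = TRUE")
  if (rescale) {
    sds <- sqrt(colMeans(M^2))
    if (any(sds == 0)) stop("cannot rescale: zero-variance compromise column")
    M <- sweep(M, 2, sds, "/")
  }
  if (max(abs(M)) == 0) stop("degenerate all-zero compromise table")
  sv <- svd(M)
  lam <- sv$d^2 / n
  rank <- sum(sv$d > max(sv$d) * 1e-12)
  n_axes <- min(n_axes, rank)
  scores <- sv$u[, seq_len(n_axes), drop = FALSE] %*%
    diag(sv$d[seq_len(n_axes)], n_axes)
  load <- matrix(0, ncol(M), n_axes)
  for (m in seq_len(n_axes))
    load[, m] <- apply(M, 2, stats::cor, y = scores[, m])
  # sign rule: strongest descriptor on each axis loads positively
  for (m in seq_len(n_axes)) {
    top <- which.max(abs(load[, m]))
    if (load[top, m] < 0) {
      load[, m] <- -load[, m]
      scores[, m] <- -scores[, m]
      sv$u[, m] <- -sv$u[, m]
      sv$v[, m] <- -sv$v[, m]
    }
  }
  dimnames(scores) <- list(rownames(comp$table),
                           paste0("Axis", seq_len(n_axes)))
  dimnames(load) <- list(colnames(comp$table), paste0("Axis", seq_len(n_axes)))
  axes <- sv$v[, seq_len(n_axes), drop = FALSE]
  dimnames(axes) <- dimnames(load)
  comp$pca_eigenvalues <- lam
  comp$inertia_pct <- 100 * lam / sum(lam)
  comp$row_scores <- scores
  comp$variable_loadings <- load
  comp$axes <- axes
  comp$svd <- sv
  comp$rescaled <- rescale
  comp
}

#' @export
print.pta_compromise <- function(x, ...) {
  cat("pta_compromise (", x$mode, "): ", nrow(x$table), " rows x ",
      ncol(x$table), " descriptors\n", sep = "")
  if (!is.null(x$inertia_pct))
    cat("  PCA inertia: ",
        paste(sprintf("%.1f%%", utils::head(x$inertia_pct, 4)),
              collapse = ", "), "\n", sep = "")
  invisible(x)
}
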