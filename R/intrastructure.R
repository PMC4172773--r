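#' Project the original tables onto the compromise axes (step 3)
#'
#' Each standardized table is projected as a supplementary element onto the
#' PCA of the compromise: rows (trees or dates) onto the unit variable axes
#' (`X_k V`), and descriptors onto the score axes as correlations, so that a
#' table equal to the compromise reproduces the compromise's own row scores
#' and variable loadings exactly — the internal anchor that fixes the
#' normalization.
#'
#' @param stack the standardized `table_stack` the compromise was built from.
#' @param comp a completed [compromise_pca()] result.
#' @param n_axes number of axes (defaults to all retained in `comp`).
#' @return an object of class `pta_intrastructure` with `row_coords`
#'   (K x rows x m array) and `var_coords` (K x p x m array) filled;
#'   complete it with [envelope_outliers()].
#' @export
project_tables <- function(stack, comp, n_axes = NULL) {
  stopifnot(inherits(stack, "table_stack"), inherits(comp, "pta_compromise"))
  if (!isTRUE(stack$standardized)) stop("stack must be standardized")
  if (is.null(comp$axes)) stop("compromise PCA not computed; run compromise_pca()")
  m_avail <- ncol(comp$axes)
  if (is.null(n_axes)) n_axes <- m_avail
  if (n_axes > m_avail)
    stop("requested ", n_axes, " axes but only ", m_avail, " available")
  K <- length(stack$tables)
  nr <- length(stack$row_keys); p <- length(stack$var_names)
  V <- comp$axes[, seq_len(n_axes), drop = FALSE]
  U <- comp$svd$u[, seq_len(n_axes), drop = FALSE]
  row_coords <- array(NA_real_, c(K, nr, n_axes),
                      dimnames = list(names(stack$tables), stack$row_keys,
                                      paste0("Axis", seq_len(n_axes))))
  var_coords <- array(NA_real_, c(K, p, n_axes),
                      dimnames = list(names(stack$tables), stack$var_names,
                                      paste0("Axis", seq_len(n_axes))))
  for (k in seq_len(K)) {
    Xk <- stack$tables[[k]]
    row_coords[k, , ] <- Xk %*% V
    for (mm in seq_len(n_axes))
      var_coords[k, , mm] <- apply(Xk, 2, stats::cor, y = U[, mm])
  }
  structure(list(mode = stack$mode, row_coords = row_coords,
                 var_coords = var_coords, envelope = NULL,
                 outlier_flags = NULL, outlier_counts = NULL,
                 table_keys = stack$table_keys, row_keys = stack$row_keys),
            class = "pta_intrastructure")
}

#' Quantile-envelope outlier detection on projected coordinates
#'
#' Flags the projected coordinates that escape the central 95% envelope on a
#' compromise axis. The envelope bounds are empirical quantiles (linear
#' interpolation of order statistics, the type-7 rule) at `probs`;
#' "outside" means strictly below the lower or strictly above the upper
#' bound, so a degenerate all-equal set flags nothing.
#'
#' In the by-year orientation the envelope is computed per table (the trees
#' within each date): `across = "rows"`. In the by-tree orientation the
#' natural envelope is still over trees within each date, which are now
#' spread across tables at a fixed row: `across = "tables"`. In both cases
#' `outlier_counts` counts, per tree, the number of dates on which it fell
#' outside.
#'
#' @param intra a `pta_intrastructure` from [project_tables()].
#' @param probs lower/upper envelope probabilities, default `c(0.025, 0.975)`.
#' @param axis compromise axis to use (default 1).
#' @param across `"rows"` (quantiles within each table, over its rows) or
#'   `"tables"` (quantiles within each row, over tables).
#' @param quantile_type quantile convention passed to [stats::quantile()]
#'   (default 7, pinned; counts are sensitive to it).
#' @return the completed `pta_intrastructure`: `envelope` (data frame of
#'   key, lower, upper), `outlier_flags` (K x rows logical matrix),
#'   `outlier_counts` (named integer vector over the flagged units).
#' @export
envelope_outliers <- function(intra, probs = c(0.025, 0.975), axis = 1L,
                              across = c("rows", "tables"),
                              quantile_type = 7L) {
  stopifnot(inherits(intra, "pta_intrastructure"))
  across <- match.arg(across)
  if (is.null(intra$row_coords)) stop("row_coords not filled")
  if (length(probs) != 2L || probs[1] >= probs[2])
    stop("probs must be an increasing pair")
  if (axis > dim(intra$row_coords)[3])
    stop("axis ", axis, " not available")
  co <- intra$row_coords[, , axis, drop = FALSE]
  dim(co) <- dim(intra$row_coords)[1:2]   # K x rows
  dimnames(co) <- dimnames(intra$row_coords)[1:2]
  K <- nrow(co); nr <- ncol(co)
  flags <- matrix(FALSE, K, nr,
                  dimnames = dimnames(intra$row_coords)[1:2])
  if (across == "rows") {
    if (nr < 3L) stop("need at least 3 rows per table for quantiles")
    env <- t(apply(co, 1, stats::quantile, probs = probs,
                   type = quantile_type, names = FALSE))
    for (k in seq_len(K))
      flags[k, ] <- co[k, ] < env[k, 1] | co[k, ] > env[k, 2]
    keys <- rownames(co)
    counts <- colSums(flags)               # per row (tree in by-year)
  } else {
    if (K < 3L) stop("need at least 3 tables for quantiles across tables")
    env <- t(apply(co, 2, stats::quantile, probs = probs,
                   type = quantile_type, names = FALSE))
    for (r in seq_len(nr))
      flags[, r] <- co[, r] < env[r, 1] | co[, r] > env[r, 2]
    keys <- colnames(co)
    counts <- rowSums(flags)               # per table (tree in by-tree)
  }
  intra$envelope <- data.frame(key = keys, lower = env[, 1], upper = env[, 2],
                               row.names = NULL)
  intra$probs <- probs
  intra$axis <- axis
  intra$across <- across
  intra$outlier_flags <- flags
  intra$outlier_counts <- counts
  intra
}

#' @export
print.pta_intrastructure <- function(x, ...) {
  d <- dim(x$row_coords)
  cat("pta_intrastructure (", x$mode, "): ", d[1], " tables x ", d[2],
      " rows x ", d[3], " axes\n", sep = "")
  if (!is.null(x$outlier_counts))
    cat("  envelope [", paste(x$probs, collapse = ", "), "] on axis ",
        x$axis, ": ", sum(x$outlier_counts > 0), " unit(s) outside at least once\n",
        sep = "")
  invisible(x)
}
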