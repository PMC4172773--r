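#' Correlation circle of a compromise PCA
#'
#' Descriptor loadings (variable-axis correlations) on two compromise axes,
#' drawn inside the unit circle.
#'
#' @param comp a completed `pta_compromise`.
#' @param axes pair of axis indices.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the loading matrix plotted.
#' @export
plot_correlation_circle <- function(comp, axes = c(1, 2), ...) {
  stopifnot(inherits(comp, "pta_compromise"))
  L <- comp$variable_loadings
  if (max(axes) > ncol(L)) stop("axis not available")
  lab <- sprintf("Axis %d (%.1f%%)", axes, comp$inertia_pct[axes])
  graphics::plot(NA, xlim = c(-1, 1), ylim = c(-1, 1), asp = 1,
                 xlab = lab[1], ylab = lab[2],
                 main = "Compromise PCA: correlation circle", ...)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(cos(th), sin(th), col = "grey70")
  graphics::abline(h = 0, v = 0, col = "grey85", lty = 3)
  graphics::arrows(0, 0, L[, axes[1]], L[, axes[2]], length = 0.06,
                   col = "grey40")
  graphics::text(L[, axes[1]] * 1.08, L[, axes[2]] * 1.08, rownames(L),
                 cex = 0.8)
  invisible(L[, axes])
}

#' Map of per-tree values (scores or counts)
#'
#' Symbol area proportional to the absolute value; circles for positive
#' values, squares for negative.
#'
#' @param values named numeric vector, one per tree.
#' @param coords matching n x 2 coordinate matrix (m).
#' @param main plot title.
#' @param ... passed to [graphics::plot()].
#' @export
plot_score_map <- function(values, coords, main = "Tree scores (axis 1)",
                           ...) {
  if (length(values) != nrow(coords)) stop("values/coords mismatch")
  cex <- 0.4 + 2.2 * sqrt(abs(values) / max(abs(values), na.rm = TRUE))
  graphics::plot(coords[, 1], coords[, 2], asp = 1, xlab = "x (m)",
                 ylab = "y (m)", main = main, type = "n", ...)
  pos <- values >= 0
  graphics::points(coords[pos, 1], coords[pos, 2], pch = 21, cex = cex[pos],
                   bg = "grey80")
  graphics::points(coords[!pos, 1], coords[!pos, 2], pch = 22,
                   cex = cex[!pos], bg = "grey30")
  invisible(NULL)
}

#' Date coordinates along the years (by-tree compromise)
#'
#' Row scores of the by-tree compromise on the first two axes plotted as a
#' function of year: the pulse/zigzag signal on axis 1, the smooth trend on
#' axis 2.
#'
#' @param comp a completed by-tree `pta_compromise`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot_date_scores <- function(comp, ...) {
  stopifnot(inherits(comp, "pta_compromise"))
  yrs <- as.integer(rownames(comp$row_scores))
  graphics::matplot(yrs, comp$row_scores[, 1:min(2, ncol(comp$row_scores))],
                    type = "l", lty = c(1, 2), col = 1, xlab = "year",
                    ylab = "compromise score",
                    main = "Date coordinates on compromise axes", ...)
  graphics::abline(h = 0, col = "grey85", lty = 3)
  invisible(NULL)
}

#' @export
plot.moran_correlogram <- function(x, ...) {
  sig <- !is.na(x$holm_pvalues) & x$holm_pvalues <= x$alpha
  graphics::plot(x$class_centers, x$morans_i, type = "b",
                 xlab = "distance class center (m)", ylab = "Moran's I",
                 main = sprintf("Moran's I correlogram (%d permutations)",
                                x$n_permutations), ...)
  graphics::abline(h = x$expected_i, lty = 2, col = "grey50")
  graphics::points(x$class_centers[sig], x$morans_i[sig], pch = 16)
  invisible(x)
}
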