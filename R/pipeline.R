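#' Run the full partial triadic analysis on a datacube
#'
#' Orchestrates one orientation end to end: slice, per-table
#' standardization, interstructure (inter-table matrix + eigen), weighted
#' compromise and its PCA, intrastructure projection with quantile-envelope
#' outliers, and — for the by-year orientation with coordinates — the
#' Moran's I permutation correlogram of the compromise axis-1 tree scores.
#'
#' @param cube a [ring_cube()].
#' @param mode `"by_year"` (temporal evolution of spatial structures) or
#'   `"by_tree"` (spatial structure of temporal dynamics).
#' @param r_method inter-table coefficient, `"mean_cor"` or `"rv"`.
#' @param n_axes axes retained throughout (default 2).
#' @param denom standardization denominator, see [standardize_stack()].
#' @param missing missing-cell policy, see [slice_cube()].
#' @param rescale re-scale compromise columns before PCA, see
#'   [compromise_pca()].
#' @param probs envelope probabilities, see [envelope_outliers()].
#' @param quantile_type envelope quantile convention (default 7).
#' @param spatial run the correlogram stage (default: yes for `"by_year"`
#'   when coordinates exist). Requesting it without coordinates is an error.
#' @param n_perm,seed,alpha,breaks correlogram controls; `seed` also stamps
#'   the provenance record (default 1).
#' @return a `pta_result` bundle: `mode`, `interstructure`, `compromise`,
#'   `intrastructure`, `correlogram` (or `NULL`), `stack`, `provenance`.
#' @export
run_analysis <- function(cube, mode = c("by_year", "by_tree"),
                         r_method = c("mean_cor", "rv"), n_axes = 2L,
                         denom = c("population", "sample"),
                         missing = c("fail", "drop-tree", "drop-year"),
                         rescale = FALSE, probs = c(0.025, 0.975),
                         quantile_type = 7L, spatial = NULL,
                         n_perm = 1000L, seed = 1L, alpha = 0.05,
                         breaks = NULL) {
  mode <- match.arg(mode)
  r_method <- match.arg(r_method)
  denom <- match.arg(denom)
  missing <- match.arg(missing)
  seed <- as.integer(seed)
  n_perm <- as.integer(n_perm)
  if (is.null(spatial)) spatial <- mode == "by_year" && !is.null(cube$coords)
  if (spatial && is.null(cube$coords))
    stop("[spatial] correlogram requested but the cube has no coordinates")
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("[", what, "] ", conditionMessage(e), call. = FALSE))
  }
  stack <- stage("slice", slice_cube(cube, mode, missing = missing))
  stack <- stage("standardize", standardize_stack(stack, denom = denom))
  inter <- stage("interstructure",
                 interstructure(stack, method = r_method, n_axes = n_axes))
  comp <- stage("compromise", compromise_pca(
    build_compromise(stack, inter), n_axes = n_axes, rescale = rescale))
  intra <- stage("intrastructure", envelope_outliers(
    project_tables(stack, comp), probs = probs,
    across = if (mode == "by_year") "rows" else "tables",
    quantile_type = quantile_type))
  cg <- NULL
  if (spatial) {
    classes <- stage("correlogram",
                     distance_classes(stack$coords, breaks = breaks))
    cg <- stage("correlogram", correlogram(
      comp$row_scores[, 1], stack$coords, classes = classes,
      n_perm = n_perm, seed = seed, alpha = alpha))
  }
  structure(list(mode = mode, interstructure = inter, compromise = comp,
                 intrastructure = intra, correlogram = cg, stack = stack,
                 provenance = list(
                   mode = mode, r_method = r_method, n_axes = n_axes,
                   denom = denom, missing = missing, rescale = rescale,
                   probs = probs, quantile_type = quantile_type,
                   spatial = spatial, n_perm = n_perm, seed = seed,
                   alpha = alpha,
                   shape = dim(cube$values),
                   version = as.character(utils::packageVersion("ptacube")),
                   timestamp = format(Sys.time(), tz = "UTC"))),
            class = "pta_result")
}

#' @export
print.pta_result <- function(x, ...) {
  cat("pta_result (", x$mode, ")\n", sep = "")
  cat("  interstructure inertia: ",
      paste(sprintf("%.1f%%", utils::head(x$interstructure$inertia_pct, 2)),
            collapse = ", "), "\n", sep = "")
  cat("  compromise PCA inertia: ",
      paste(sprintf("%.1f%%", utils::head(x$compromise$inertia_pct, 2)),
            collapse = ", "), "\n", sep = "")
  oc <- x$intrastructure$outlier_counts
  cat("  envelope: ", sum(oc > 0), "/", length(oc),
      " units outside at least once\n", sep = "")
  if (!is.null(x$correlogram))
    cat("  Moran correlogram globally significant: ",
        x$correlogram$globally_significant, "\n", sep = "")
  invisible(x)
}

#' Export a result bundle to a directory
#'
#' Writes every matrix as a labeled TSV, a JSON summary (provenance without
#' the timestamp, so identical runs export byte-identical trees), optional
#' PDF plots, and a manifest listing every written file with its MD5
#' checksum.
#'
#' @param bundle a `pta_result`.
#' @param out_dir output directory (created).
#' @param plots also write PDF figures (correlation circle, score map or
#'   date trajectory, outlier map, correlogram). Off by default because PDF
#'   headers carry timestamps and defeat checksum-identical re-export.
#' @return invisibly, the manifest data frame (file, md5).
#' @export
export_bundle <- function(bundle, out_dir, plots = FALSE) {
  stopifnot(inherits(bundle, "pta_result"))
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  wtsv <- function(x, name, rowlab = "id") {
    df <- as.data.frame(x)
    if (!is.null(rowlab))
      df <- cbind(stats::setNames(data.frame(rownames(df),
                                             stringsAsFactors = FALSE),
                                  rowlab), df)
    data.table::fwrite(df, file.path(out_dir, name), sep = "\t")
    name
  }
  inter <- bundle$interstructure; comp <- bundle$compromise
  intra <- bundle$intrastructure
  files <- c(
    wtsv(inter$r_matrix, "interstructure_r_matrix.tsv", "table"),
    wtsv(data.frame(eigenvalue = inter$eigenvalues,
                    inertia_pct = inter$inertia_pct),
         "interstructure_eigen.tsv", "component"),
    wtsv(cbind(inter$table_scores, weight = inter$weights),
         "interstructure_scores.tsv", "table"),
    wtsv(comp$table, "compromise_table.tsv", "row"),
    wtsv(data.frame(eigenvalue = comp$pca_eigenvalues,
                    inertia_pct = comp$inertia_pct),
         "compromise_eigen.tsv", "component"),
    wtsv(comp$variable_loadings, "compromise_loadings.tsv", "descriptor"),
    wtsv(comp$row_scores, "compromise_scores.tsv", "row"),
    wtsv(intra$envelope, "intrastructure_envelope.tsv", NULL),
    wtsv(data.frame(unit = names(intra$outlier_counts),
                    n_outside = as.integer(intra$outlier_counts)),
         "intrastructure_outliers.tsv", NULL))
  # tidy long form of the per-table projections
  rc <- intra$row_coords
  long <- data.table::data.table(
    table = rep(dimnames(rc)[[1]], times = prod(dim(rc)[2:3])),
    row = rep(rep(dimnames(rc)[[2]], each = dim(rc)[1]), times = dim(rc)[3]),
    axis = rep(dimnames(rc)[[3]], each = prod(dim(rc)[1:2])),
    coord = as.vector(rc))
  data.table::fwrite(long, file.path(out_dir, "intrastructure_row_coords.tsv"),
                     sep = "\t")
  vc <- intra$var_coords
  vlong <- data.table::data.table(
    table = rep(dimnames(vc)[[1]], times = prod(dim(vc)[2:3])),
    descriptor = rep(rep(dimnames(vc)[[2]], each = dim(vc)[1]),
                     times = dim(vc)[3]),
    axis = rep(dimnames(vc)[[3]], each = prod(dim(vc)[1:2])),
    coord = as.vector(vc))
  data.table::fwrite(vlong, file.path(out_dir, "intrastructure_var_coords.tsv"),
                     sep = "\t")
  files <- c(files, "intrastructure_row_coords.tsv",
             "intrastructure_var_coords.tsv")
  if (!is.null(bundle$correlogram)) {
    cg <- bundle$correlogram
    data.table::fwrite(data.table::data.table(
      lower = cg$class_breaks[-length(cg$class_breaks)],
      upper = cg$class_breaks[-1], center = cg$class_centers,
      n_pairs = cg$n_pairs, reliable = cg$reliable, morans_i = cg$morans_i,
      p_perm = cg$perm_pvalues, p_holm = cg$holm_pvalues),
      file.path(out_dir, "correlogram.tsv"), sep = "\t")
    files <- c(files, "correlogram.tsv")
  }
  prov <- bundle$provenance
  prov$timestamp <- NULL
  summary <- list(
    mode = bundle$mode,
    interstructure_inertia_pct = inter$inertia_pct,
    compromise_inertia_pct = comp$inertia_pct,
    weights = as.list(inter$weights),
    n_outside_envelope = sum(intra$outlier_counts > 0),
    correlogram_globally_significant =
      if (!is.null(bundle$correlogram))
        bundle$correlogram$globally_significant else NULL,
    provenance = prov)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, "summary.json")
  if (plots) {
    pf <- file.path(out_dir, "figures.pdf")
    grDevices::pdf(pf, width = 7, height = 7)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot_correlation_circle(comp)
    if (bundle$mode == "by_year" && !is.null(bundle$stack$coords)) {
      plot_score_map(comp$row_scores[, 1], bundle$stack$coords)
      plot_score_map(intra$outlier_counts, bundle$stack$coords,
                     main = "Envelope departures per tree")
    }
    if (bundle$mode == "by_tree") plot_date_scores(comp)
    if (!is.null(bundle$correlogram)) plot(bundle$correlogram)
    files <- c(files, "figures.pdf")
  }
  md5 <- tools::md5sum(file.path(out_dir, files))
  manifest <- data.frame(file = files, md5 = unname(md5))
  data.table::fwrite(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t")
  invisible(manifest)
}
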