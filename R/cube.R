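#' Three-way ring datacube
#'
#' A `ring_cube` stores a trees x descriptors x years array of annual-ring
#' descriptors (typically the 11 microdensity codes RW, LW, RD, ED, LD, MID,
#' MAD, Co, RSD, ESD, LSD) together with per-tree planar coordinates in
#' meters and a missing-value mask. It is the entry point of the partial
#' triadic analysis pipeline: slice it with [slice_cube()] into a stack of
#' two-way tables, one per year or one per tree.
#'
#' @param values numeric array of dimension `(n trees, p descriptors, T years)`.
#' @param tree_ids character vector of unique tree identifiers, length `n`.
#' @param descriptors character vector of unique descriptor names, length `p`.
#' @param years integer vector of strictly increasing years, length `T`.
#' @param coords optional numeric matrix or data frame with `n` rows and
#'   columns `x`, `y` (planar meters), in the order of `tree_ids`.
#' @param missing_mask optional logical array, same dimension as `values`,
#'   `TRUE` where a cell is missing. Defaults to `is.na(values)`.
#'
#' @return an object of class `ring_cube`.
#' @seealso [read_long_table()], [slice_cube()], [simulate_cube()]
#' @export
ring_cube <- function(values, tree_ids, descriptors, years, coords = NULL,
                      missing_mask = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("'values' must be a 3-way array (trees x descriptors x years)")
  tree_ids <- as.character(tree_ids)
  descriptors <- as.character(descriptors)
  years <- as.integer(years)
  if (is.null(missing_mask)) missing_mask <- is.na(values)
  coords <- if (!is.null(coords)) {
    coords <- as.matrix(coords[, c("x", "y"), drop = FALSE])
    storage.mode(coords) <- "double"
    if (nrow(coords) == length(tree_ids)) rownames(coords) <- tree_ids
    coords
  }
  dimnames(values) <- dimnames(missing_mask) <-
    list(tree = tree_ids, descriptor = descriptors, year = as.character(years))
  obj <- structure(
    list(values = values, tree_ids = tree_ids, descriptors = descriptors,
         years = years, coords = coords, missing_mask = missing_mask),
    class = "ring_cube")
  validate_ring_cube(obj)
  obj
}

#' Validate a ring datacube
#'
#' Checks dimensional agreement, label uniqueness, strictly increasing years,
#' and mask alignment. Called by the constructor; exported so generated or
#' hand-built cubes can be re-checked.
#'
#' @param cube a [ring_cube()].
#' @return `cube`, invisibly, or an error.
#' @export
validate_ring_cube <- function(cube) {
  stopifnot(inherits(cube, "ring_cube"))
  d <- dim(cube$values)
  if (d[1] != length(cube$tree_ids) || d[2] != length(cube$descriptors) ||
      d[3] != length(cube$years))
    stop("cube dimensions ", paste(d, collapse = "x"),
         " do not match label lengths (",
         length(cube$tree_ids), ", ", length(cube$descriptors), ", ",
         length(cube$years), ")")
  if (anyDuplicated(cube$tree_ids)) stop("duplicated tree ids")
  if (anyDuplicated(cube$descriptors)) stop("duplicated descriptor names")
  if (length(cube$years) > 1 && any(diff(cube$years) <= 0))
    stop("years must be strictly increasing")
  if (!identical(dim(cube$missing_mask), d))
    stop("missing_mask dimension does not match values")
  if (!is.null(cube$coords)) {
    if (nrow(cube$coords) != d[1])
      stop("coords must have one row per tree")
    if (anyNA(cube$coords)) stop("coords contain NA")
  }
  # NA cells must be declared missing
  if (any(is.na(cube$values) & !cube$missing_mask))
    stop("NA values present that are not flagged in missing_mask")
  invisible(cube)
}

#' @export
print.ring_cube <- function(x, ...) {
  d <- dim(x$values)
  cat("ring_cube: ", d[1], " trees x ", d[2], " descriptors x ", d[3],
      " years (", x$years[1], "-", x$years[length(x$years)], ")\n", sep = "")
  cat("  descriptors: ", paste(x$descriptors, collapse = ", "), "\n", sep = "")
  cat("  coordinates: ", if (is.null(x$coords)) "none" else "x/y (m)",
      "; missing cells: ", sum(x$missing_mask), "\n", sep = "")
  invisible(x)
}

#' Default ring-descriptor codes
#'
#' The 11 standard microdensity descriptors: ring width (RW), latewood
#' percentage (LW), mean ring density (RD), earlywood density (ED), latewood
#' density (LD), minimum (MID) and maximum (MAD) ring density, density
#' contrast (Co = MAD - MID), and the standard deviations of the whole-ring,
#' earlywood and latewood parts of the density profile (RSD, ESD, LSD).
#'
#' @return character vector of length 11.
#' @export
ring_descriptor_codes <- function() {
  c("RW", "LW", "RD", "ED", "LD", "MID", "MAD", "Co", "RSD", "ESD", "LSD")
}

#' Column-mapping schema for long-format ring tables
#'
#' Maps the columns of a delimited file to the canonical roles used by
#' [read_long_table()]. Descriptor columns default to whatever of the 11
#' standard codes are present in the file; pass them explicitly for files
#' with other headers.
#'
#' @param tree,year names of the tree-id and year columns.
#' @param x,y names of the coordinate columns (may be absent from the file).
#' @param descriptors character vector of descriptor column names, or `NULL`
#'   to auto-detect (standard codes if present, otherwise every remaining
#'   column).
#' @param sep field separator; `"auto"` lets the reader sniff tab/comma/space.
#' @return a list of class `cube_schema`.
#' @export
cube_schema <- function(tree = "tree", year = "year", x = "x", y = "y",
                        descriptors = NULL, sep = "auto") {
  structure(list(tree = tree, year = year, x = x, y = y,
                 descriptors = descriptors, sep = sep),
            class = "cube_schema")
}

#' Read a long-format ring table into a datacube
#'
#' Expects one row per tree x year with one column per descriptor, plus a
#' tree-id and a year column; coordinates either embedded (x/y columns,
#' deduplicated per tree) or in a separate two-column file. Tree x year
#' combinations absent from the file become missing-mask entries.
#'
#' @param path delimited text file (TSV/CSV/whitespace).
#' @param schema a [cube_schema()] mapping file columns to roles.
#' @param coords_path optional separate coordinates file with tree, x, y
#'   columns (same tree column name as `schema$tree`).
#' @return a [ring_cube()].
#' @export
read_long_table <- function(path, schema = cube_schema(), coords_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (identical(schema$sep, "auto")) "auto" else schema$sep
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          colClasses = list(character = schema$tree))
  need <- c(schema$tree, schema$year)
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("required column(s) missing from ", path, ": ",
         paste(miss, collapse = ", "))
  desc_cols <- schema$descriptors
  if (is.null(desc_cols)) {
    std <- intersect(ring_descriptor_codes(), names(dt))
    desc_cols <- if (length(std)) std else
      setdiff(names(dt), c(schema$tree, schema$year, schema$x, schema$y))
  }
  miss <- setdiff(desc_cols, names(dt))
  if (length(miss))
    stop("descriptor column(s) missing: ", paste(miss, collapse = ", "))
  # non-numeric descriptor cells -> hard error with row number
  for (cn in desc_cols) {
    col <- dt[[cn]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(!is.na(col) & col != "" & is.na(num))
      if (length(bad))
        stop("non-numeric value in descriptor column '", cn, "' at data row ",
             bad[1], ": '", col[bad[1]], "'")
      data.table::set(dt, j = cn, value = num)
    }
  }
  keys <- paste(dt[[schema$tree]], dt[[schema$year]], sep = "\r")
  if (anyDuplicated(keys)) {
    d <- keys[duplicated(keys)][1]
    d <- strsplit(d, "\r", fixed = TRUE)[[1]]
    stop("duplicate (tree, year) entry: tree '", d[1], "', year ", d[2])
  }
  tree_ids <- unique(dt[[schema$tree]])
  years <- sort(unique(as.integer(dt[[schema$year]])))
  n <- length(tree_ids); p <- length(desc_cols); Tn <- length(years)
  values <- array(NA_real_, c(n, p, Tn))
  ii <- match(dt[[schema$tree]], tree_ids)
  tt <- match(as.integer(dt[[schema$year]]), years)
  for (j in seq_len(p))
    values[cbind(ii, j, tt)] <- dt[[desc_cols[j]]]

  coords <- NULL
  if (!is.null(coords_path)) {
    cdt <- data.table::fread(coords_path, header = TRUE,
                             colClasses = list(character = schema$tree))
    for (cn in c(schema$tree, schema$x, schema$y))
      if (!cn %in% names(cdt))
        stop("coordinate file lacks column '", cn, "'")
    m <- match(tree_ids, cdt[[schema$tree]])
    if (anyNA(m))
      warning("tree(s) without coordinates: ",
              paste(utils::head(tree_ids[is.na(m)], 5), collapse = ", "),
              "; spatial analyses will refuse this cube")
    else
      coords <- cbind(x = as.numeric(cdt[[schema$x]])[m],
                      y = as.numeric(cdt[[schema$y]])[m])
  } else if (all(c(schema$x, schema$y) %in% names(dt))) {
    cdt <- unique(dt[, c(schema$tree, schema$x, schema$y), with = FALSE])
    if (anyDuplicated(cdt[[schema$tree]]))
      stop("inconsistent embedded coordinates for tree '",
           cdt[[schema$tree]][duplicated(cdt[[schema$tree]])][1], "'")
    m <- match(tree_ids, cdt[[schema$tree]])
    coords <- cbind(x = as.numeric(cdt[[schema$x]])[m],
                    y = as.numeric(cdt[[schema$y]])[m])
  }
  ring_cube(values, tree_ids, desc_cols, years, coords = coords)
}

#' Write a datacube as a directory of TSVs plus a JSON manifest
#'
#' Inverse of [read_long_table()]: `rings.tsv` holds one row per tree x year
#' with descriptor columns; `coords.tsv` the per-tree coordinates; and
#' `manifest.json` the labels and shape. Round-trips exactly (up to float
#' printing, avoided by writing full precision).
#'
#' @param cube a [ring_cube()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_cube <- function(cube, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(cube$values)
  grid <- expand.grid(tree = seq_len(d[1]), year = seq_len(d[3]),
                      KEEP.OUT.ATTRS = FALSE)
  dt <- data.table::data.table(
    tree = cube$tree_ids[grid$tree],
    year = cube$years[grid$year])
  for (j in seq_len(d[2]))
    data.table::set(dt, j = cube$descriptors[j],
                    value = cube$values[cbind(grid$tree, j, grid$year)])
  # drop rows that are entirely missing so read_long_table re-masks them
  all_missing <- apply(cube$missing_mask, c(1, 3), all)
  dt <- dt[!all_missing[cbind(grid$tree, grid$year)]]
  data.table::fwrite(dt, file.path(dir, "rings.tsv"), sep = "\t")
  if (!is.null(cube$coords))
    data.table::fwrite(
      data.table::data.table(tree = cube$tree_ids,
                             x = cube$coords[, "x"], y = cube$coords[, "y"]),
      file.path(dir, "coords.tsv"), sep = "\t")
  jsonlite::write_json(
    list(shape = dim(cube$values), tree_ids = cube$tree_ids,
         descriptors = cube$descriptors, years = cube$years,
         has_coords = !is.null(cube$coords),
         n_missing = sum(cube$missing_mask)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Slice a datacube into a stack of two-way tables
#'
#' The two orientations of the partial triadic analysis: `"by_year"` yields
#' one trees x descriptors table per year (temporal evolution of spatial
#' structures); `"by_tree"` yields one years x descriptors table per tree
#' (spatial structure of temporal dynamics).
#'
#' @param cube a [ring_cube()].
#' @param mode `"by_year"` or `"by_tree"`.
#' @param missing what to do with missing cells: `"fail"` (default; the
#'   reference analysis assumes a complete cube), `"drop-tree"` or
#'   `"drop-year"` to remove every tree/year with any missing cell (logged
#'   with a warning).
#' @return a `table_stack`: list with `mode`, `tables` (named list of
#'   matrices), `table_keys`, `row_keys`, `var_names`, `standardized`,
#'   and `coords` (carried through for spatial analysis).
#' @export
slice_cube <- function(cube, mode = c("by_year", "by_tree"),
                       missing = c("fail", "drop-tree", "drop-year")) {
  mode <- match.arg(mode)
  missing <- match.arg(missing)
  validate_ring_cube(cube)
  v <- cube$values; mask <- cube$missing_mask
  tree_keep <- rep(TRUE, dim(v)[1]); year_keep <- rep(TRUE, dim(v)[3])
  if (any(mask)) {
    if (missing == "fail") {
      idx <- which(mask, arr.ind = TRUE)
      ex <- idx[seq_len(min(5, nrow(idx))), , drop = FALSE]
      stop(sum(mask), " missing cell(s), e.g. ",
           paste(sprintf("(%s, %s, %s)", cube$tree_ids[ex[, 1]],
                         cube$descriptors[ex[, 2]],
                         cube$years[ex[, 3]]), collapse = " "),
           "; set missing = 'drop-tree' or 'drop-year' to proceed")
    } else if (missing == "drop-tree") {
      tree_keep <- apply(mask, 1, function(m) !any(m))
      warning("dropping ", sum(!tree_keep), " tree(s) with missing cells")
    } else {
      year_keep <- apply(mask, 3, function(m) !any(m))
      warning("dropping ", sum(!year_keep), " year(s) with missing cells")
    }
    v <- v[tree_keep, , year_keep, drop = FALSE]
  }
  trees <- cube$tree_ids[tree_keep]; years <- cube$years[year_keep]
  coords <- if (!is.null(cube$coords))
    cube$coords[tree_keep, , drop = FALSE]
  if (mode == "by_year") {
    tables <- lapply(seq_along(years), function(t) {
      m <- v[, , t, drop = TRUE]
      dim(m) <- dim(v)[1:2]
      dimnames(m) <- list(trees, cube$descriptors)
      m
    })
    names(tables) <- as.character(years)
    keys <- years; rows <- trees
  } else {
    tables <- lapply(seq_along(trees), function(i) {
      m <- v[i, , , drop = TRUE]
      dim(m) <- dim(v)[2:3]
      m <- t(m)
      dimnames(m) <- list(as.character(years), cube$descriptors)
      m
    })
    names(tables) <- trees
    keys <- trees; rows <- as.character(years)
  }
  structure(list(mode = mode, tables = tables, table_keys = keys,
                 row_keys = rows, var_names = cube$descriptors,
                 standardized = FALSE, coords = coords),
            class = "table_stack")
}

#' Re-assemble a table stack into a datacube
#'
#' Exact inverse of [slice_cube()] on complete cubes; used by the lossless
#' round-trip checks.
#'
#' @param stack an unstandardized `table_stack`.
#' @return a [ring_cube()].
#' @export
unslice_stack <- function(stack) {
  stopifnot(inherits(stack, "table_stack"))
  if (isTRUE(stack$standardized))
    stop("cannot reassemble a standardized stack into raw values")
  p <- length(stack$var_names)
  if (stack$mode == "by_year") {
    n <- length(stack$row_keys); Tn <- length(stack$tables)
    v <- array(NA_real_, c(n, p, Tn))
    for (t in seq_len(Tn)) v[, , t] <- stack$tables[[t]]
    ring_cube(v, stack$row_keys, stack$var_names,
              as.integer(stack$table_keys), coords = stack$coords)
  } else {
    n <- length(stack$tables); Tn <- length(stack$row_keys)
    v <- array(NA_real_, c(n, p, Tn))
    for (i in seq_len(n)) v[i, , ] <- t(stack$tables[[i]])
    ring_cube(v, names(stack$tables), stack$var_names,
              as.integer(stack$row_keys), coords = stack$coords)
  }
}

#' @export
print.table_stack <- function(x, ...) {
  cat("table_stack (", x$mode, "): ", length(x$tables), " tables of ",
      nrow(x$tables[[1]]), " x ", ncol(x$tables[[1]]),
      if (isTRUE(x$standardized)) ", standardized" else ", raw", "\n", sep = "")
  invisible(x)
}
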