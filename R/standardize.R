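#' Standardize every table of a stack
#'
#' Centers and scales each column of each two-way table independently, so
#' that the subsequent inter-table comparison contrasts *structures* (the
#' correlation pattern among descriptors) rather than levels or units.
#' The default scale is the population standard deviation (1/n denominator),
#' the convention of the duality-diagram lineage of the method; under it a
#' standardized column x satisfies sum(x^2) = n, and the inter-table
#' coefficient reduces to a plain mean of column correlations.
#'
#' @param stack an unstandardized `table_stack` from [slice_cube()].
#' @param denom `"population"` (1/n, default) or `"sample"` (1/(n-1)).
#' @param constant policy for a zero-variance column within a table:
#'   `"fail"` (default) or `"drop"` to remove the descriptor stack-wide with
#'   a warning.
#' @return the stack with every column of every table at mean 0, sd 1, and
#'   `standardized = TRUE`.
#' @export
standardize_stack <- function(stack, denom = c("population", "sample"),
                              constant = c("fail", "drop")) {
  stopifnot(inherits(stack, "table_stack"))
  denom <- match.arg(denom)
  constant <- match.arg(constant)
  if (isTRUE(stack$standardized))
    stop("stack is already standardized")
  n <- nrow(stack$tables[[1]])
  if (n < 2L) stop("tables need at least 2 rows to standardize")
  fac <- if (denom == "population") (n - 1) / n else 1
  # first pass: find constant columns anywhere in the stack
  const_cols <- logical(length(stack$var_names))
  for (k in seq_along(stack$tables)) {
    sds <- sqrt(apply(stack$tables[[k]], 2, stats::var) * fac)
    bad <- sds == 0 | !is.finite(sds)
    if (any(bad)) {
      if (constant == "fail")
        stop("constant column '", stack$var_names[which(bad)[1]],
             "' in table '", names(stack$tables)[k],
             "' cannot be standardized (policy 'fail')")
      const_cols <- const_cols | bad
    }
  }
  if (any(const_cols)) {
    warning("dropping constant descriptor(s) stack-wide: ",
            paste(stack$var_names[const_cols], collapse = ", "))
    stack$tables <- lapply(stack$tables,
                           function(m) m[, !const_cols, drop = FALSE])
    stack$var_names <- stack$var_names[!const_cols]
    if (length(stack$var_names) == 0L)
      stop("all descriptors constant; nothing left to analyze")
  }
  stack$tables <- lapply(stack$tables, function(m) {
    mu <- colMeans(m)
    sds <- sqrt(apply(m, 2, stats::var) * fac)
    out <- sweep(sweep(m, 2, mu, "-"), 2, sds, "/")
    dimnames(out) <- dimnames(m)
    out
  })
  stack$standardized <- TRUE
  stack$denom <- denom
  stack
}
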