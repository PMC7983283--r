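#' Construct a cell-level cytometry dataset
#'
#' The common input container for both fitters: a cells-by-markers
#' expression matrix (on the transformed scale) together with a per-cell
#' donor identifier and a per-cell binary condition label.
#'
#' The condition may arrive as any two-level vector (factor, character,
#' logical or numeric); it is recoded to \{0, 1\} with the
#' lexicographically smaller level mapped to 0, and the mapping is stored
#' in the `condition_levels` attribute so the sign convention of fitted
#' coefficients is reproducible.
#'
#' @param expressions numeric matrix, one row per cell, one column per
#'   marker. No missing values.
#' @param donor per-cell donor identifier (any atomic type), same length as
#'   `nrow(expressions)`.
#' @param condition per-cell condition label with at most two distinct
#'   values, same length as `nrow(expressions)`.
#' @param marker_names optional marker names; defaults to
#'   `colnames(expressions)` or `M1..MP`.
#' @return an object of class `cytometry_dataset`: a list with elements
#'   `expressions` (matrix), `donor` (factor), `condition` (integer 0/1),
#'   plus attributes `condition_levels` and `paired`.
#' @seealso [load_table()], [transform_expressions()]
#' @export
cytometry_dataset <- function(expressions, donor, condition,
                              marker_names = NULL) {
  expressions <- as.matrix(expressions)
  storage.mode(expressions) <- "double"
  n <- nrow(expressions)
  if (n < 1L || ncol(expressions) < 1L)
    stop("expressions must have at least one cell and one marker")
  if (length(donor) != n || length(condition) != n)
    stop("donor and condition must have one entry per cell (", n, ")")
  if (anyNA(expressions)) {
    bad <- which(rowSums(is.na(expressions)) > 0)
    stop("missing expression values in rows: ",
         paste(head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) ", ..." else "")
  }
  if (anyNA(donor) || anyNA(condition))
    stop("donor and condition must not contain missing values")
  if (is.null(marker_names)) marker_names <- colnames(expressions)
  if (is.null(marker_names))
    marker_names <- paste0("M", seq_len(ncol(expressions)))
  if (length(marker_names) != ncol(expressions))
    stop("marker_names length does not match the number of marker columns")
  colnames(expressions) <- marker_names

  lev <- sort(unique(as.character(condition)))
  if (length(lev) > 2L)
    stop("more than two conditions (", paste(lev, collapse = ", "),
         "); run a separate two-group analysis per pair and combine with ",
         "summarize_analyses()")
  cond <- as.integer(match(as.character(condition), lev) - 1L)

  donor <- factor(donor)
  paired <- length(lev) == 2L &&
    all(vapply(split(cond, donor), function(y) length(unique(y)) == 2L,
               logical(1)))
  structure(
    list(expressions = expressions, donor = donor, condition = cond),
    condition_levels = lev, paired = paired, class = "cytometry_dataset")
}

#' @export
print.cytometry_dataset <- function(x, ...) {
  lev <- attr(x, "condition_levels")
  cat("<cytometry_dataset> ", nrow(x$expressions), " cells, ",
      ncol(x$expressions), " markers, ", nlevels(x$donor), " donors\n",
      sep = "")
  cat("  condition: ", paste(lev, collapse = " vs "),
      " (coded ", paste(seq_along(lev) - 1L, collapse = "/"), "); ",
      if (attr(x, "paired")) "paired" else "unpaired", " design\n", sep = "")
  invisible(x)
}

#' Number of markers in a dataset
#' @param dataset a [cytometry_dataset()]
#' @return integer marker count
#' @export
n_markers <- function(dataset) ncol(dataset$expressions)

#' Read a cell-level cytometry table from delimited text
#'
#' Expects one row per cell and a header naming a donor column, a condition
#' column and one numeric column per marker.
#'
#' @param path CSV (or TSV, by `sep`) file path.
#' @param donor_col,condition_col names of the donor and condition columns.
#' @param marker_cols names of the marker columns; default: every other
#'   column.
#' @param sep field separator; `","` by default, use `"\t"` for TSV.
#' @param transform optional [transform_spec()] applied to the marker
#'   columns after reading (e.g. raw counts on disk, asinh scale in memory).
#' @return a [cytometry_dataset()]
#' @export
load_table <- function(path, donor_col = "donor",
                       condition_col = "condition", marker_cols = NULL,
                       sep = ",", transform = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE)
  for (col in c(donor_col, condition_col))
    if (!col %in% names(df)) stop("missing column: ", col)
  if (is.null(marker_cols))
    marker_cols <- setdiff(names(df), c(donor_col, condition_col))
  missing_markers <- setdiff(marker_cols, names(df))
  if (length(missing_markers))
    stop("missing column: ", paste(missing_markers, collapse = ", "))
  expr <- as.matrix(df[marker_cols])
  if (!is.numeric(expr)) stop("marker columns must be numeric")
  if (!is.null(transform)) expr <- transform_expressions(expr, transform)
  cytometry_dataset(expr, df[[donor_col]], df[[condition_col]],
                    marker_names = marker_cols)
}

#' Write a cytometry dataset to delimited text
#'
#' Inverse of [load_table()]: one row per cell with `donor`, `condition`
#' (original labels) and one column per marker.
#'
#' @param dataset a [cytometry_dataset()]
#' @param path output file path
#' @param sep field separator
#' @return `path`, invisibly
#' @export
write_table <- function(dataset, path, sep = ",") {
  lev <- attr(dataset, "condition_levels")
  df <- data.frame(donor = as.character(dataset$donor),
                   condition = lev[dataset$condition + 1L],
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(dataset$expressions))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Specify a variance-stabilizing transform
#'
#' Cytometry counts are heteroskedastic; the inverse hyperbolic sine with a
#' technology-specific cofactor (5 for mass cytometry, 150 for flow
#' cytometry) is the standard variance-stabilizing choice. A log transform
#' with a pseudo-count and the identity are also available.
#'
#' @param method one of `"asinh"`, `"log"`, `"identity"`.
#' @param cofactor positive scale divisor for `asinh`; default 5 (mass
#'   cytometry). Use 150 for flow cytometry.
#' @param pseudo_count added before `log`; default 1 so zero counts map
#'   to zero.
#' @return an object of class `transform_spec`
#' @export
transform_spec <- function(method = c("asinh", "log", "identity"),
                           cofactor = 5, pseudo_count = 1) {
  method <- match.arg(method)
  if (method == "asinh" && (!is.numeric(cofactor) || cofactor <= 0))
    stop("cofactor must be a positive number")
  structure(list(method = method, cofactor = cofactor,
                 pseudo_count = pseudo_count), class = "transform_spec")
}

#' Apply a variance-stabilizing transform to an expression matrix
#'
#' `asinh`: `y = asinh(x / cofactor)`; `log`: `y = log(x + pseudo_count)`;
#' `identity`: unchanged. All are elementwise and monotone increasing.
#'
#' @param raw numeric matrix or vector of raw intensities/counts.
#'   Nonnegative values are required for `log`.
#' @param spec a [transform_spec()]
#' @return transformed matrix with the same shape and dimnames
#' @export
transform_expressions <- function(raw, spec = transform_spec()) {
  stopifnot(inherits(spec, "transform_spec"))
  switch(spec$method,
         asinh = asinh(raw / spec$cofactor),
         log = {
           if (any(raw < 0))
             stop("log transform requires nonnegative values")
           log(raw + spec$pseudo_count)
         },
         identity = raw)
}

# Center and scale each marker to unit variance so coefficients are
# comparable across markers. Constant markers are left centered only.
standardize_markers <- function(dataset) {
  x <- dataset$expressions
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s == 0 | !is.finite(s)] <- 1
  dataset$expressions <- sweep(sweep(x, 2, mu, "-"), 2, s, "/")
  attr(dataset, "standardized") <- TRUE
  dataset
}

# Shared pre-fit validation: both conditions present, enough cells.
check_fit_ready <- function(dataset) {
  stopifnot(inherits(dataset, "cytometry_dataset"))
  if (length(unique(dataset$condition)) < 2L)
    stop("both conditions must be present to fit")
  if (nrow(dataset$expressions) < n_markers(dataset) + 1L)
    stop("need at least P + 1 cells to fit P marker coefficients")
  invisible(dataset)
}
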