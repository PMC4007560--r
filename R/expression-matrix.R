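#' Expression matrix with declared space, platform and unit
#'
#' A light container (in the spirit of limma's `EList`) holding a numeric
#' features x samples matrix together with the scale it lives on
#' (`linear` or `log2`), the platform that produced it, and its unit.
#' Row names are feature identifiers (probe or gene ids), column names are
#' sample identifiers; both must be unique.
#'
#' @param values numeric matrix, features in rows, samples in columns, with
#'   unique row and column names.
#' @param space `"linear"` or `"log2"`. Linear-space matrices must be
#'   non-negative.
#' @param platform `"microarray"` or `"rnaseq"`.
#' @param unit `"intensity"`, `"TPM"`, `"counts"` or `"SSMI"`. `counts`
#'   must be non-negative integers.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `space`, `platform`, `unit`.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' em <- ExpressionMatrix(m, "linear", "rnaseq", "TPM")
#' dim(em)
#' @export
ExpressionMatrix <- function(values,
                             space = c("linear", "log2"),
                             platform = c("microarray", "rnaseq"),
                             unit = c("intensity", "TPM", "counts", "SSMI")) {
  space <- match.arg(space)
  platform <- match.arg(platform)
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  x <- structure(list(values = values, space = space,
                      platform = platform, unit = unit),
                 class = "ExpressionMatrix")
  validate_expression_matrix(x)
  x
}

validate_expression_matrix <- function(x) {
  v <- x$values
  fid <- rownames(v); sid <- colnames(v)
  if (is.null(fid) || is.null(sid))
    stop("ExpressionMatrix requires feature (row) and sample (column) names")
  if (anyDuplicated(fid))
    stop("duplicate feature ids: ",
         paste(utils::head(unique(fid[duplicated(fid)]), 3), collapse = ", "))
  if (anyDuplicated(sid))
    stop("duplicate sample ids: ",
         paste(utils::head(unique(sid[duplicated(sid)]), 3), collapse = ", "))
  if (anyNA(v))
    stop("missing values are not supported in ExpressionMatrix")
  if (x$space == "linear" && any(v < 0))
    stop("linear-space values must be non-negative")
  if (x$unit == "counts" && any(v != round(v)))
    stop("counts must be integers")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
dimnames.ExpressionMatrix <- function(x) dimnames(x$values)

#' @export
as.matrix.ExpressionMatrix <- function(x, ...) x$values

#' Subset an ExpressionMatrix by features and/or samples
#' @param x an `ExpressionMatrix`.
#' @param i,j feature and sample indices (any form `[` accepts).
#' @param ... ignored.
#' @return An `ExpressionMatrix` with the same space/platform/unit.
#' @export
`[.ExpressionMatrix` <- function(x, i, j, ...) {
  v <- x$values[i, j, drop = FALSE]
  structure(list(values = v, space = x$space, platform = x$platform,
                 unit = x$unit), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d features x %d samples [%s %s, %s space]\n",
              nrow(x$values), ncol(x$values), x$platform, x$unit, x$space))
  if (nrow(x$values) > 0 && ncol(x$values) > 0) {
    print(utils::head(x$values[, utils::head(seq_len(ncol(x$values)), 4),
                               drop = FALSE], 4))
  }
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' The file must be tab-delimited with a header row of sample ids and feature
#' ids in a first column named `feature_id`. Lines starting with `#` are
#' treated as comments. Cells must parse as finite numbers; the first
#' offending cell is reported with its row and column.
#'
#' @param path file path.
#' @inheritParams ExpressionMatrix
#' @return An [ExpressionMatrix].
#' @export
read_expression_matrix <- function(path, space, platform, unit) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE,
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("expression TSV needs a feature_id column plus >=1 sample column: ",
         path)
  fid <- df[[1]]
  if (anyDuplicated(fid))
    stop("duplicate feature ids in ", path, ": ",
         paste(utils::head(unique(fid[duplicated(fid)]), 3), collapse = ", "))
  vals <- matrix(NA_real_, nrow(df), ncol(df) - 1L,
                 dimnames = list(fid, colnames(df)[-1]))
  for (j in seq_len(ncol(df) - 1L)) {
    col <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.finite(num))
    if (length(bad) > 0)
      stop(sprintf("malformed numeric cell '%s' at row %d (feature %s), column '%s' in %s",
                   col[bad[1]], bad[1], fid[bad[1]], colnames(df)[j + 1L], path))
    vals[, j] <- num
  }
  ExpressionMatrix(vals, space = space, platform = platform, unit = unit)
}

#' Write an expression matrix to TSV
#'
#' Writes the dialect [read_expression_matrix()] reads: a `feature_id`
#' column, tab-delimited, 15 significant digits. Optional comment lines
#' (prefixed `# `) are placed before the header.
#'
#' @param x an `ExpressionMatrix`.
#' @param path output path.
#' @param comments character vector of comment lines (without the `# `).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, comments = character()) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments))
    writeLines(paste0("# ", comments), con)
  writeLines(paste(c("feature_id", colnames(x$values)), collapse = "\t"), con)
  body <- apply(x$values, 1L, function(r)
    paste(sprintf("%.15g", r), collapse = "\t"))
  writeLines(paste(rownames(x$values), body, sep = "\t"), con)
  invisible(path)
}

#' Log2-transform a linear-space matrix
#'
#' Computes `log2(x + epsilon)`. log2 is the working space for probe scoring,
#' scaling, batch adjustment and all reproducibility metrics; the default
#' offset 2^-10 is small enough not to distort values at TPM >= 1 (it shifts
#' log2(1) by under 0.0015) while keeping zeros finite.
#'
#' @param mat an `ExpressionMatrix` in linear space.
#' @param epsilon non-negative offset added before taking logs. `epsilon = 0`
#'   with any zero value is an error.
#' @return An `ExpressionMatrix` in log2 space (same platform and unit).
#' @export
log_transform <- function(mat, epsilon = 2^-10) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (mat$space != "linear")
    stop("log_transform expects a linear-space matrix")
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (epsilon == 0 && any(mat$values == 0))
    stop("epsilon = 0 with zero values: log of zero")
  out <- mat
  out$values <- log2(mat$values + epsilon)
  out$space <- "log2"
  out
}

#' Invert [log_transform()]
#'
#' Computes `2^y - epsilon`, clipped at zero to absorb rounding just below
#' the offset.
#'
#' @param mat an `ExpressionMatrix` in log2 space.
#' @param epsilon the offset used in the forward transform.
#' @return An `ExpressionMatrix` in linear space.
#' @export
unlog_transform <- function(mat, epsilon = 2^-10) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (mat$space != "log2")
    stop("unlog_transform expects a log2-space matrix")
  out <- mat
  out$values <- pmax(2^mat$values - epsilon, 0)
  out$space <- "linear"
  out
}
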