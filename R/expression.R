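#' Construct an expression matrix object
#'
#' Bundles a genes x samples matrix of non-negative abundance values
#' (FPKM-like units) with an optional aligned matrix of raw read counts.
#' Gene and sample identifiers are taken from the dimnames and must be
#' unique; identifiers are treated as opaque strings.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   unique rownames (gene ids) and colnames (sample ids); finite and >= 0.
#' @param raw_counts optional integer-valued matrix of the same shape and
#'   dimnames, used by the raw-count expression filter.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, raw_counts = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values))) {
    if (nrow(values) > 0) stop("'values' must have gene rownames")
    rownames(values) <- character(0)
  }
  if (is.null(colnames(values))) {
    if (ncol(values) > 0) stop("'values' must have sample colnames")
    colnames(values) <- character(0)
  }
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  if (any(values < 0))
    stop("expression values must be non-negative")
  if (!is.null(raw_counts)) {
    if (!is.matrix(raw_counts) || !identical(dim(raw_counts), dim(values)))
      stop("'raw_counts' must be a matrix with the same shape as 'values'")
    if (nrow(values) > 0 &&
        (!identical(rownames(raw_counts), rownames(values)) ||
         !identical(colnames(raw_counts), colnames(values))))
      stop("'raw_counts' dimnames must match 'values'")
    if (any(!is.finite(raw_counts)) || any(raw_counts < 0))
      stop("raw counts must be finite and non-negative")
  }
  structure(list(values = values, raw_counts = raw_counts),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$raw_counts)) "" else " (with raw counts)"))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Gene identifiers of an expression matrix
#' @param expr an `ExpressionMatrix`.
#' @return Character vector of gene ids in row order.
#' @export
gene_ids <- function(expr) rownames(expr$values)

#' Sample identifiers of an expression matrix
#' @param expr an `ExpressionMatrix`.
#' @return Character vector of sample ids in column order.
#' @export
sample_ids <- function(expr) colnames(expr$values)

#' Subset an expression matrix by genes and/or samples
#'
#' @param expr an `ExpressionMatrix`.
#' @param genes,samples character vectors of identifiers to keep (default:
#'   all). Unknown identifiers raise an error.
#' @return A new `ExpressionMatrix` restricted to the requested rows/columns.
#' @export
subset_expression <- function(expr, genes = NULL, samples = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  g <- if (is.null(genes)) gene_ids(expr) else genes
  s <- if (is.null(samples)) sample_ids(expr) else samples
  missing_g <- setdiff(g, gene_ids(expr))
  if (length(missing_g))
    stop("unknown gene ids: ", paste(utils::head(missing_g, 5), collapse = ", "))
  missing_s <- setdiff(s, sample_ids(expr))
  if (length(missing_s))
    stop("unknown sample ids: ", paste(utils::head(missing_s, 5), collapse = ", "))
  expression_matrix(expr$values[g, s, drop = FALSE],
                    if (is.null(expr$raw_counts)) NULL
                    else expr$raw_counts[g, s, drop = FALSE])
}

#' Read an expression matrix from a tab-separated file
#'
#' Expected layout: a header row of sample ids, then one row per gene with
#' the gene id in the first column followed by numeric abundances.
#'
#' @param path path to a TSV file.
#' @param raw_counts_path optional path to a raw-count TSV with identical
#'   gene/sample layout.
#' @return An `ExpressionMatrix`.
#' @export
read_expression <- function(path, raw_counts_path = NULL) {
  vals <- .read_numeric_tsv(path)
  counts <- if (!is.null(raw_counts_path)) .read_numeric_tsv(raw_counts_path)
  expression_matrix(vals, counts)
}

.read_numeric_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("cannot parse '", path, "': file is empty")
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0 || ncol(df) < 2)
    stop("cannot parse '", path, "': need a header row and >= 1 gene row with >= 1 sample column")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate gene identifiers in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf("malformed numeric cell in '%s' at gene '%s', sample '%s': '%s'",
                 path, ids[bad[1]], colnames(body)[bad[2]], body[bad[1], bad[2]]))
  }
  dimnames(num) <- list(ids, colnames(body))
  num
}

#' Write an expression matrix to TSV
#'
#' @param expr an `ExpressionMatrix`.
#' @param path output file; the first column (`gene`) holds gene ids.
#' @param what write the abundance `"values"` (default) or the `"raw_counts"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, what = c("values", "raw_counts")) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  what <- match.arg(what)
  m <- expr[[what]]
  if (is.null(m)) stop("expression matrix has no ", what)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
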