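#' Construct phenotype labels
#'
#' Maps sample ids to categorical phenotype classes and fixes the binary
#' contrast (control, case) used by the fitness function. Data sets may
#' carry more than two classes (e.g. a normal / pre-invasive / invasive
#' design); only the two comparison classes enter the mutual-information
#' fitness.
#'
#' @param classes named character vector: names are sample ids, values are
#'   class labels.
#' @param comparison length-2 character vector `c(control, case)`; both must
#'   occur among `classes`. Defaults to the first two classes in order of
#'   appearance.
#' @return An object of class `PhenotypeLabels`.
#' @export
phenotype_labels <- function(classes, comparison = NULL) {
  if (is.null(names(classes)) || anyDuplicated(names(classes)))
    stop("'classes' must be named by unique sample ids")
  classes <- vapply(classes, as.character, character(1))
  if (is.null(comparison)) comparison <- unique(unname(classes))[1:2]
  comparison <- as.character(comparison)
  if (length(comparison) != 2 || anyNA(comparison) || comparison[1] == comparison[2])
    stop("'comparison' must name two distinct classes")
  for (cl in comparison) {
    if (sum(classes == cl) < 2)
      stop("comparison class '", cl, "' has fewer than 2 samples")
  }
  structure(list(classes = classes, comparison = comparison),
            class = "PhenotypeLabels")
}

#' @export
print.PhenotypeLabels <- function(x, ...) {
  tab <- table(x$classes)
  cat(sprintf("PhenotypeLabels: %d samples, classes {%s}; comparison %s vs %s\n",
              length(x$classes),
              paste(sprintf("%s:%d", names(tab), tab), collapse = ", "),
              x$comparison[1], x$comparison[2]))
  invisible(x)
}

#' Read phenotype labels from a two-column TSV (sample, class)
#'
#' @param path path to a TSV file with a header row.
#' @param comparison optional `c(control, case)` pair; see
#'   [phenotype_labels()].
#' @return A `PhenotypeLabels` object.
#' @export
read_labels <- function(path, comparison = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = "character")
  if (ncol(df) < 2) stop("label file needs two columns: sample, class")
  phenotype_labels(stats::setNames(df[[2]], df[[1]]), comparison)
}

#' Write phenotype labels to TSV
#' @param labels a `PhenotypeLabels` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "PhenotypeLabels"))
  utils::write.table(
    data.frame(sample = names(labels$classes), class = unname(labels$classes)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Restrict labels to the two comparison classes, ordered as in `expr`;
# returns list(samples, y) with y a factor (control first). Errors when a
# labeled sample is missing from the matrix.
.comparison_samples <- function(expr, labels) {
  stopifnot(inherits(labels, "PhenotypeLabels"))
  missing <- setdiff(names(labels$classes), sample_ids(expr))
  if (length(missing))
    stop("labeled samples absent from expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  keep <- names(labels$classes)[labels$classes %in% labels$comparison]
  keep <- sample_ids(expr)[sample_ids(expr) %in% keep]
  y <- factor(labels$classes[keep], levels = labels$comparison)
  if (any(table(y) < 2)) stop("each comparison class needs >= 2 samples")
  list(samples = keep, y = y)
}
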