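#' Construct a driver-score table
#'
#' Per-gene functional-impact scores in the style of CHASM: a score in
#' [0, 1] (0 = likely passenger, 1 = likely driver) and an empirical
#' p-value in (0, 1] for the probability that a passenger is misclassified
#' as a driver.
#'
#' @param gene character vector of gene ids (unique).
#' @param score numeric in [0, 1].
#' @param p_value numeric in (0, 1].
#' @return A data.frame of class `DriverTable` with columns
#'   `gene`, `score`, `p_value`.
#' @export
driver_table <- function(gene, score, p_value) {
  gene <- as.character(gene)
  if (anyDuplicated(gene))
    stop("duplicate gene ids in driver table")
  if (length(score) != length(gene) || length(p_value) != length(gene))
    stop("gene, score and p_value must have equal length")
  if (any(!is.finite(score)) || any(score < 0 | score > 1))
    stop("driver scores must lie in [0, 1]")
  if (any(!is.finite(p_value)) || any(p_value <= 0 | p_value > 1))
    stop("driver p-values must lie in (0, 1]")
  structure(data.frame(gene = gene, score = score, p_value = p_value,
                       stringsAsFactors = FALSE),
            class = c("DriverTable", "data.frame"))
}

#' Read a driver-score table from a 3-column TSV (gene, score, p_value)
#' @param path path to the TSV (with header).
#' @return A `DriverTable`.
#' @export
read_drivers <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#")
  if (ncol(df) < 3) stop("driver table needs columns: gene, score, p_value")
  driver_table(df[[1]], as.numeric(df[[2]]), as.numeric(df[[3]]))
}

#' Write a driver-score table to TSV
#' @param drivers a `DriverTable`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_drivers <- function(drivers, path) {
  utils::write.table(as.data.frame(drivers), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select putative driver genes from a score table
#'
#' A gene is called a putative driver when its score strictly exceeds
#' `score_threshold` and its p-value is strictly below `p_threshold`
#' (defaults 0.8 and 0.05). The score boundary is exclusive by default;
#' set `inclusive_score = TRUE` for a `>=` boundary.
#'
#' @param drivers a `DriverTable`.
#' @param score_threshold minimum score (exclusive by default).
#' @param p_threshold maximum p-value (exclusive).
#' @param inclusive_score if `TRUE`, use `score >= score_threshold`.
#' @return Sorted character vector of putative driver gene ids.
#' @export
filter_drivers <- function(drivers, score_threshold = 0.8, p_threshold = 0.05,
                           inclusive_score = FALSE) {
  stopifnot(inherits(drivers, "DriverTable"))
  ok_score <- if (inclusive_score) drivers$score >= score_threshold
              else drivers$score > score_threshold
  sort(drivers$gene[ok_score & drivers$p_value < p_threshold])
}
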