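#' Remove unexpressed genes by median raw count
#'
#' Retains genes whose median raw read count across all samples is greater
#' than zero; genes with median raw count equal to zero are treated as
#' unexpressed and dropped.
#'
#' @param expr an `ExpressionMatrix` carrying `raw_counts`.
#' @return An `ExpressionMatrix` restricted to expressed genes.
#' @export
filter_unexpressed_by_count <- function(expr) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (is.null(expr$raw_counts))
    stop("expression matrix has no raw counts; use the FPKM filter ",
         "(filter_unexpressed_by_fpkm) instead")
  med <- apply(expr$raw_counts, 1, stats::median)
  keep <- gene_ids(expr)[med > 0]
  if (!length(keep)) {
    warning("all genes have median raw count 0; returning empty matrix")
    return(expression_matrix(expr$values[keep, , drop = FALSE],
                             expr$raw_counts[keep, , drop = FALSE]))
  }
  subset_expression(expr, genes = keep)
}

#' Expressed genes by median abundance
#'
#' Returns the genes whose median abundance (FPKM-like) across samples is
#' at least `threshold`; genes with median below the threshold are
#' considered unexpressed. The default threshold of 1 implements the
#' standard "median FPKM < 1 is unexpressed" rule, so a gene with median
#' exactly 1 is retained.
#'
#' @param expr an `ExpressionMatrix`.
#' @param threshold minimum median abundance (default 1.0).
#' @return Character vector of expressed gene ids (row order preserved).
#' @export
filter_unexpressed_by_fpkm <- function(expr, threshold = 1.0) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  med <- apply(expr$values, 1, stats::median)
  gene_ids(expr)[med >= threshold]
}

#' Two-group differential expression (pluggable test stage)
#'
#' A deterministic substitute for a count-based DE fit: per gene,
#' `log2_fc = log2((mean_case + eps) / (mean_control + eps))` on the
#' abundance scale, a two-sided Welch t-test on `log2(x + 1)` transformed
#' values, and Benjamini-Hochberg FDR across all tested genes. The output
#' contract (gene, log2_fc, p_value, fdr) is the interface: an externally
#' computed DE table (e.g. from a negative-binomial fit) can be dropped in
#' at this stage via [read_de_table()].
#'
#' @param expr an `ExpressionMatrix` (genes pre-filtered for expression).
#' @param labels a `PhenotypeLabels`; the comparison pair selects the two
#'   groups (control first).
#' @param method test method; currently `"log_t_test"`.
#' @param eps pseudocount for fold changes (default 1).
#' @return data.frame with columns `gene`, `log2_fc`, `p_value`, `fdr`.
#' @export
differential_expression <- function(expr, labels, method = "log_t_test",
                                    eps = 1) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  method <- match.arg(method, "log_t_test")
  cs <- .comparison_samples(expr, labels)
  x <- expr$values[, cs$samples, drop = FALSE]
  is_case <- cs$y == labels$comparison[2]
  mean_case <- rowMeans(x[, is_case, drop = FALSE])
  mean_ctrl <- rowMeans(x[, !is_case, drop = FALSE])
  log2_fc <- log2((mean_case + eps) / (mean_ctrl + eps))
  lx <- log2(x + 1)
  p <- .welch_t_rows(lx[, is_case, drop = FALSE], lx[, !is_case, drop = FALSE])
  data.frame(gene = gene_ids(expr), log2_fc = log2_fc, p_value = p,
             fdr = stats::p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Row-wise Welch two-sample t-test, two-sided. Zero-variance degenerate
# rows: equal means -> p 1, unequal means -> p 0.
.welch_t_rows <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  p <- numeric(length(m1))
  zero <- se2 == 0
  p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
  if (any(!zero)) {
    tstat <- (m1[!zero] - m2[!zero]) / sqrt(se2[!zero])
    df <- se2[!zero]^2 /
      ((v1[!zero] / n1)^2 / (n1 - 1) + (v2[!zero] / n2)^2 / (n2 - 1))
    p[!zero] <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  }
  p
}

#' Read / write DE result tables (gene, log2_fc, p_value, fdr)
#'
#' @param path TSV path.
#' @return `read_de_table`: data.frame with the DE contract columns.
#' @export
read_de_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#")
  need <- c("gene", "log2_fc", "p_value", "fdr")
  if (!all(need %in% names(df)))
    stop("DE table must have columns: ", paste(need, collapse = ", "))
  df$gene <- as.character(df$gene)
  if (any(df$p_value < 0 | df$p_value > 1, na.rm = TRUE) ||
      any(df$fdr < 0 | df$fdr > 1, na.rm = TRUE))
    stop("p_value and fdr must lie in [0, 1]")
  df[, need]
}

#' @rdname read_de_table
#' @param de DE data.frame to write.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Case-specific gene selection by double DE intersection
#'
#' Selects genes differentially expressed in BOTH the case-vs-intermediate
#' and the case-vs-control comparison (|FC| > `fc_threshold` and
#' FDR < `fdr_threshold` in each), i.e. genes specific to the case
#' phenotype rather than shared with the intermediate state. Genes
#' significant in both comparisons but with opposite fold-change signs are
#' dropped with a warning. Direction (`up`/`down`) is taken from the sign
#' of the case-vs-control log2 fold change.
#'
#' @param de_case_vs_intermediate,de_case_vs_control DE data.frames over
#'   the same gene universe (see [differential_expression()]).
#' @param fc_threshold fold-change cutoff on the linear scale (default 2,
#'   i.e. |log2FC| > 1).
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @return data.frame with columns `gene`, `direction`, sorted by gene.
#' @export
select_invasive_specific <- function(de_case_vs_intermediate,
                                     de_case_vs_control,
                                     fc_threshold = 2,
                                     fdr_threshold = 0.05) {
  a <- de_case_vs_intermediate; b <- de_case_vs_control
  if (!setequal(a$gene, b$gene))
    stop("the two DE tables cover different gene universes")
  b <- b[match(a$gene, b$gene), ]
  lfc_cut <- log2(fc_threshold)
  pass <- abs(a$log2_fc) > lfc_cut & a$fdr < fdr_threshold &
          abs(b$log2_fc) > lfc_cut & b$fdr < fdr_threshold
  pass[is.na(pass)] <- FALSE
  conflict <- pass & sign(a$log2_fc) != sign(b$log2_fc)
  if (any(conflict)) {
    warning(sum(conflict), " gene(s) significant with opposite fold-change ",
            "signs dropped: ", paste(utils::head(a$gene[conflict], 5), collapse = ", "))
    pass <- pass & !conflict
  }
  out <- data.frame(gene = a$gene[pass],
                    direction = ifelse(b$log2_fc[pass] > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
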