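#' Write core subnetworks to a directory
#'
#' Emits one induced edge-list file per core
#' (`core_<seed>_edges.tsv`), a human-readable summary table
#' (`core_summary.tsv`: seed, size, n_drivers, fitness, both p-values,
#' driver genes) and a machine-readable JSON dump (`cores.json`) that
#' round-trips losslessly through [read_subnetworks()].
#'
#' @param cores nonempty list of `CoreSubnetwork` objects.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_subnetworks <- function(cores, out_dir) {
  if (!length(cores)) stop("'cores' must be a nonempty list")
  stopifnot(all(vapply(cores, inherits, logical(1), "CoreSubnetwork")))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  for (core in cores) {
    ef <- file.path(out_dir, paste0("core_", .safe_name(core$seed), "_edges.tsv"))
    utils::write.table(core$edges, ef, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  summary <- data.frame(
    seed = vapply(cores, `[[`, character(1), "seed"),
    size = vapply(cores, function(x) length(x$members), integer(1)),
    n_drivers = vapply(cores, function(x) length(x$drivers), integer(1)),
    fitness = vapply(cores, `[[`, numeric(1), "fitness"),
    p_label_perm = vapply(cores, `[[`, numeric(1), "p_label_perm"),
    p_random_members = vapply(cores, `[[`, numeric(1), "p_random_members"),
    drivers = vapply(cores, function(x) paste(x$drivers, collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(summary, file.path(out_dir, "core_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dump <- lapply(cores, function(x) list(
    seed = x$seed, members = as.list(x$members), drivers = as.list(x$drivers),
    fitness = x$fitness, p_label_perm = x$p_label_perm,
    p_random_members = x$p_random_members,
    edges = list(u = as.list(x$edges$u), v = as.list(x$edges$v),
                 kind = as.list(x$edges$kind))))
  jsonlite::write_json(dump, file.path(out_dir, "cores.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

.safe_name <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)

#' Read core subnetworks back from a dump directory
#'
#' @param out_dir directory written by [write_subnetworks()].
#' @return List of `CoreSubnetwork` objects identical to the ones written.
#' @export
read_subnetworks <- function(out_dir) {
  path <- file.path(out_dir, "cores.json")
  if (!file.exists(path)) stop("no cores.json in ", out_dir)
  dump <- jsonlite::read_json(path)
  lapply(dump, function(x) {
    edges <- if (is.null(x$edges$u) || !length(x$edges$u))
      data.frame(u = character(0), v = character(0),
                 kind = character(0), stringsAsFactors = FALSE)
    else
      data.frame(u = unlist(x$edges$u), v = unlist(x$edges$v),
                 kind = unlist(x$edges$kind), stringsAsFactors = FALSE)
    structure(list(seed = x$seed,
                   members = as.character(unlist(x$members)),
                   drivers = as.character(unlist(x$drivers)),
                   fitness = as.numeric(x$fitness),
                   p_label_perm = as.numeric(x$p_label_perm),
                   p_random_members = as.numeric(x$p_random_members),
                   edges = edges),
              class = "CoreSubnetwork")
  })
}
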