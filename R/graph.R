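#' Construct a typed molecular interaction graph
#'
#' Holds a heterogeneous interaction network: undirected protein-protein
#' interaction (`ppi`) edges, directed transcription-factor to target
#' (`tf_target`) edges and directed lncRNA to target (`lnc_target`) edges.
#' Node kinds (`coding`, `tf`, `lncrna`) are inferred from edge roles when
#' not supplied: sources of `lnc_target` edges are `lncrna`, sources of
#' `tf_target` edges are `tf`, everything else is `coding`.
#'
#' Self-loops are dropped with a warning; duplicate (u, v, kind) triples —
#' including reversed duplicates of undirected ppi edges — collapse to one
#' edge. For neighborhood expansion all edge kinds are traversable in both
#' directions, so candidate recall is maximized.
#'
#' @param edges data.frame with columns `u`, `v`, `kind`
#'   (kind in `ppi`, `tf_target`, `lnc_target`).
#' @param node_kinds optional named character vector gene id -> kind
#'   (`coding`, `tf`, `lncrna`) overriding the inference; must be consistent
#'   with edge roles.
#' @return An object of class `InteractionGraph` with elements `nodes`
#'   (data.frame gene, kind) and `edges` (data.frame u, v, kind).
#' @export
interaction_graph <- function(edges, node_kinds = NULL) {
  edge_kinds <- c("ppi", "tf_target", "lnc_target")
  if (!all(c("u", "v", "kind") %in% names(edges)))
    stop("'edges' needs columns u, v, kind")
  edges <- data.frame(u = as.character(edges$u), v = as.character(edges$v),
                      kind = as.character(edges$kind),
                      stringsAsFactors = FALSE)
  bad <- setdiff(unique(edges$kind), edge_kinds)
  if (length(bad))
    stop("unknown edge kind(s): ", paste(bad, collapse = ", "))
  loops <- edges$u == edges$v
  if (any(loops)) {
    warning(sum(loops), " self-loop edge(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  # canonical order for undirected ppi edges so A-B and B-A dedupe together
  swap <- edges$kind == "ppi" & edges$u > edges$v
  tmp <- edges$u[swap]; edges$u[swap] <- edges$v[swap]; edges$v[swap] <- tmp
  edges <- unique(edges)
  edges <- edges[order(edges$kind, edges$u, edges$v), , drop = FALSE]
  rownames(edges) <- NULL

  genes <- sort(unique(c(edges$u, edges$v, names(node_kinds))))
  kind <- stats::setNames(rep("coding", length(genes)), genes)
  kind[unique(edges$u[edges$kind == "tf_target"])] <- "tf"
  kind[unique(edges$u[edges$kind == "lnc_target"])] <- "lncrna"
  if (!is.null(node_kinds)) {
    bad_kind <- setdiff(unique(node_kinds), c("coding", "tf", "lncrna"))
    if (length(bad_kind))
      stop("unknown node kind(s): ", paste(bad_kind, collapse = ", "))
    kind[names(node_kinds)] <- node_kinds
    tf_src <- unique(edges$u[edges$kind == "tf_target"])
    if (any(kind[tf_src] != "tf"))
      stop("tf_target source(s) not marked as tf: ",
           paste(tf_src[kind[tf_src] != "tf"], collapse = ", "))
  }
  structure(list(nodes = data.frame(gene = genes, kind = unname(kind),
                                    stringsAsFactors = FALSE),
                 edges = edges),
            class = "InteractionGraph")
}

#' @export
print.InteractionGraph <- function(x, ...) {
  nk <- table(x$nodes$kind)
  ek <- table(x$edges$kind)
  cat(sprintf("InteractionGraph: %d nodes (%s), %d edges (%s)\n",
              nrow(x$nodes), paste(sprintf("%s:%d", names(nk), nk), collapse = ", "),
              nrow(x$edges), paste(sprintf("%s:%d", names(ek), ek), collapse = ", ")))
  invisible(x)
}

#' Read a typed edge list
#'
#' Parses a whitespace- or tab-separated 3-column edge list
#' (`u v kind`); lines starting with `#` are comments. The parsed graph is
#' independent of line order.
#'
#' @param path path to the edge-list file.
#' @return An `InteractionGraph`.
#' @export
read_graph <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("edge list '", path, "' contains no edges")
  parts <- strsplit(lines, "[ \t]+")
  n <- lengths(parts)
  if (any(n != 3))
    stop("malformed edge line(s) in '", path, "' (need 3 fields): line ",
         which(n != 3)[1])
  m <- do.call(rbind, parts)
  interaction_graph(data.frame(u = m[, 1], v = m[, 2], kind = m[, 3],
                               stringsAsFactors = FALSE))
}

#' Write an interaction graph as a 3-column edge list
#' @param graph an `InteractionGraph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graph_edges <- function(graph, path) {
  stopifnot(inherits(graph, "InteractionGraph"))
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Node kinds of an interaction graph
#' @param graph an `InteractionGraph`.
#' @return Named character vector gene id -> kind.
#' @export
node_kinds <- function(graph) {
  stopifnot(inherits(graph, "InteractionGraph"))
  stats::setNames(graph$nodes$kind, graph$nodes$gene)
}

# Undirected igraph view used for neighborhood traversal (all edge kinds
# traversable both ways).
.as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges[, c("u", "v")], directed = FALSE,
    vertices = graph$nodes$gene)
}

#' Edges induced by a gene set
#'
#' @param graph an `InteractionGraph`.
#' @param genes character vector of gene ids.
#' @return The rows of `graph$edges` with both endpoints in `genes`.
#' @export
induced_edges <- function(graph, genes) {
  stopifnot(inherits(graph, "InteractionGraph"))
  keep <- graph$edges$u %in% genes & graph$edges$v %in% genes
  e <- graph$edges[keep, , drop = FALSE]
  rownames(e) <- NULL
  e
}

#' Export an interaction graph to GraphML
#'
#' Writes a GraphML file with a `kind` attribute on nodes and edges, for
#' use in network viewers. Directionality of regulatory edges is recorded
#' in the edge attribute; the exported graph itself is undirected to match
#' the traversal semantics.
#'
#' @param graph an `InteractionGraph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "InteractionGraph"))
  g <- igraph::graph_from_data_frame(
    graph$edges, directed = FALSE,
    vertices = graph$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
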