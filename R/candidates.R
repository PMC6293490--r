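#' Genes within a bounded graph distance of a seed
#'
#' Breadth-first ball of the given radius around the seed gene, with every
#' edge kind (ppi, tf_target, lnc_target) traversable in both directions.
#' The seed itself is excluded from the result. A seed absent from the
#' graph, or present without incident edges, yields an empty set.
#'
#' @param graph an `InteractionGraph`.
#' @param seed gene id.
#' @param radius maximum number of edges from the seed (default 3).
#' @return Sorted character vector of gene ids, possibly with a
#'   `distance` attribute via [bounded_neighborhood_distances()].
#' @export
bounded_neighborhood <- function(graph, seed, radius = 3) {
  names(bounded_neighborhood_distances(graph, seed, radius))
}

#' @rdname bounded_neighborhood
#' @return `bounded_neighborhood_distances`: named integer vector of BFS
#'   distances (1..radius), names sorted within each distance.
#' @export
bounded_neighborhood_distances <- function(graph, seed, radius = 3) {
  stopifnot(inherits(graph, "InteractionGraph"))
  if (!is.numeric(radius) || radius < 1)
    stop("'radius' must be >= 1")
  if (!seed %in% graph$nodes$gene)
    return(stats::setNames(integer(0), character(0)))
  g <- .as_igraph(graph)
  d <- igraph::distances(g, v = seed, mode = "all")[1, ]
  d <- d[is.finite(d) & d >= 1 & d <= radius]
  d <- d[order(d, names(d))]
  stats::setNames(as.integer(d), names(d))
}

#' Rank candidate lncRNA targets by tree-ensemble importance
#'
#' For lncRNA seeds no curated interaction edges are typically available,
#' so putative targets are ranked from expression alone: each candidate
#' target is regressed on the lncRNA plus a random set of co-regulator
#' genes with a random-forest regression, and the lncRNA's share of the
#' forest's variable importance is the target's score. Targets are
#' returned in descending importance (ties broken lexicographically by
#' gene id), truncated to `top_k`.
#'
#' @param expr an `ExpressionMatrix`.
#' @param lncrna gene id of the lncRNA (must have non-constant expression).
#' @param candidate_regulatees character vector of candidate target genes.
#' @param top_k number of top targets to return (default 200).
#' @param rng_seed integer seed; the ranking is deterministic given it.
#' @param n_coregulators number of random co-regulator genes per target
#'   regression (default 50).
#' @param num_trees trees per forest (default 100).
#' @return Character vector of the top-ranked targets with a
#'   `importance` attribute (named numeric, same order).
#' @export
rank_lncrna_targets <- function(expr, lncrna, candidate_regulatees,
                                top_k = 200, rng_seed = 1,
                                n_coregulators = 50, num_trees = 100) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (!lncrna %in% gene_ids(expr)) stop("lncRNA '", lncrna, "' not in expression matrix")
  targets <- sort(setdiff(unique(candidate_regulatees), lncrna))
  targets <- intersect(targets, gene_ids(expr))
  if (!length(targets)) stop("no candidate regulatees present in expression matrix")
  xl <- expr$values[lncrna, ]
  if (stats::sd(xl) == 0)
    stop("lncRNA '", lncrna, "' has constant expression; cannot rank targets")
  pool <- setdiff(gene_ids(expr), lncrna)
  imp <- numeric(length(targets))
  names(imp) <- targets
  for (i in seq_along(targets)) {
    tg <- targets[i]
    others <- setdiff(pool, tg)
    set.seed(rng_seed + i)
    coreg <- if (length(others) > n_coregulators)
      sample(others, n_coregulators) else others
    preds <- c(lncrna, sort(coreg))
    dat <- data.frame(t(expr$values[preds, , drop = FALSE]), check.names = FALSE)
    names(dat) <- paste0("p", seq_along(preds))  # opaque ids can be non-syntactic
    dat$.y <- expr$values[tg, ]
    fit <- ranger::ranger(dependent.variable.name = ".y", data = dat,
                          num.trees = num_trees, importance = "impurity",
                          seed = rng_seed + i, num.threads = 1)
    vi <- fit$variable.importance
    tot <- sum(vi)
    imp[i] <- if (tot > 0) unname(vi["p1"]) / tot else 0
  }
  ord <- order(-imp, names(imp))
  imp <- imp[ord]
  out <- utils::head(names(imp), min(top_k, length(imp)))
  attr(out, "importance") <- imp[seq_along(out)]
  out
}

#' Build the candidate gene set for one seed
#'
#' Coding/TF seeds: the bounded-radius neighborhood of the seed,
#' intersected with expressed genes. lncRNA seeds: the top-ranked putative
#' targets (by [rank_lncrna_targets()]) form the radius-1 shell, and
#' expansion over the interaction graph continues from those targets for
#' the remaining radius. Expression filtering is applied after traversal,
#' so unexpressed genes are removed from the candidate set but do not
#' block paths. The result is deduplicated and lexicographically ordered
#' for reproducible chromosome indexing.
#'
#' @param graph an `InteractionGraph`.
#' @param expr an `ExpressionMatrix`.
#' @param seed seed gene id (must be expressed).
#' @param radius maximum expansion radius (default 3).
#' @param fpkm_threshold median-abundance expression threshold (default 1).
#' @param top_k_lnc top target count for lncRNA seeds (default 200).
#' @param rng_seed seed for the lncRNA target ranking.
#' @param expand_lnc_targets continue graph expansion beyond the ranked
#'   targets of a lncRNA seed (default TRUE).
#' @return An object of class `CandidateSet`: list(seed, genes, radius_used,
#'   distances).
#' @export
build_candidate_set <- function(graph, expr, seed, radius = 3,
                                fpkm_threshold = 1.0, top_k_lnc = 200,
                                rng_seed = 1, expand_lnc_targets = TRUE) {
  stopifnot(inherits(graph, "InteractionGraph"), inherits(expr, "ExpressionMatrix"))
  expressed <- filter_unexpressed_by_fpkm(expr, fpkm_threshold)
  if (!seed %in% expressed)
    stop("seed '", seed, "' is not expressed (median abundance below ",
         fpkm_threshold, "); it would be removed by the FPKM filter")
  kind <- node_kinds(graph)
  seed_kind <- if (seed %in% names(kind)) kind[[seed]] else "coding"
  if (seed_kind == "lncrna") {
    shell1 <- rank_lncrna_targets(expr, seed, setdiff(expressed, seed),
                                  top_k = top_k_lnc, rng_seed = rng_seed)
    dist <- stats::setNames(rep(1L, length(shell1)), shell1)
    if (expand_lnc_targets && radius > 1) {
      for (tg in intersect(shell1, graph$nodes$gene)) {
        sub <- bounded_neighborhood_distances(graph, tg, radius - 1)
        sub <- sub + 1L
        new <- setdiff(names(sub), c(names(dist), seed))
        upd <- intersect(names(sub), names(dist))
        dist[upd] <- pmin(dist[upd], sub[upd])
        dist <- c(dist, sub[new])
      }
    }
  } else {
    dist <- bounded_neighborhood_distances(graph, seed, radius)
  }
  dist <- dist[names(dist) %in% setdiff(expressed, seed)]
  dist <- dist[order(names(dist))]
  structure(list(seed = seed, genes = names(dist),
                 radius_used = as.integer(radius),
                 distances = dist),
            class = "CandidateSet")
}

#' @export
print.CandidateSet <- function(x, ...) {
  cat(sprintf("CandidateSet: seed %s, %d candidate genes (radius %d)\n",
              x$seed, length(x$genes), x$radius_used))
  invisible(x)
}

#' Cache candidate sets to TSV (seed, gene, distance)
#'
#' @param candidate_sets list of `CandidateSet` objects.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_candidate_sets <- function(candidate_sets, path) {
  rows <- do.call(rbind, lapply(candidate_sets, function(cs) {
    if (!length(cs$genes))
      return(data.frame(seed = character(0), gene = character(0),
                        distance = integer(0)))
    data.frame(seed = cs$seed, gene = cs$genes,
               distance = unname(cs$distances[cs$genes]),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read cached candidate sets
#' @param path TSV written by [write_candidate_sets()].
#' @param seeds optional seed ids to reconstruct even if empty.
#' @return Named list of `CandidateSet` objects.
#' @export
read_candidate_sets <- function(path, seeds = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = c("character", "character", "integer"))
  all_seeds <- union(if (is.null(seeds)) character(0) else seeds,
                     unique(df$seed))
  out <- lapply(all_seeds, function(s) {
    sub <- df[df$seed == s, , drop = FALSE]
    sub <- sub[order(sub$gene), , drop = FALSE]
    structure(list(seed = s, genes = sub$gene,
                   radius_used = if (nrow(sub)) max(sub$distance) else 0L,
                   distances = stats::setNames(sub$distance, sub$gene)),
              class = "CandidateSet")
  })
  stats::setNames(out, all_seeds)
}
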