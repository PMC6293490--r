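#' Keep only subnetworks that contain a putative driver gene
#'
#' @param subnetworks list of member-gene character vectors.
#' @param drivers character vector of putative driver gene ids.
#' @return The subnetworks intersecting the driver set (possibly empty).
#' @export
require_driver <- function(subnetworks, drivers) {
  Filter(function(s) any(s %in% drivers), subnetworks)
}

#' Per-gene frequency across subnetworks
#'
#' @param subnetworks nonempty list of member-gene character vectors.
#' @return Named numeric vector: fraction of subnetworks containing each
#'   gene, in [0, 1], sorted by gene id.
#' @export
gene_frequency <- function(subnetworks) {
  if (!length(subnetworks)) stop("'subnetworks' must be nonempty")
  tab <- table(unlist(lapply(subnetworks, unique)))
  freq <- as.numeric(tab) / length(subnetworks)
  stats::setNames(freq, names(tab))[order(names(tab))]
}

#' Build the core subnetwork of a seed by frequency vote
#'
#' Members are the genes appearing in at least `cutoff` (default 50%,
#' boundary inclusive: low-frequency genes are filtered OUT) of the seed's
#' driver-containing optimal subnetworks, plus the seed itself. Returns
#' `NULL` when the resulting members contain no putative driver gene.
#'
#' @param frequencies named frequency vector from [gene_frequency()],
#'   computed over driver-filtered subnetworks.
#' @param seed seed gene id.
#' @param graph an `InteractionGraph` (for the induced edge list).
#' @param drivers character vector of putative driver gene ids.
#' @param cutoff frequency cutoff in (0, 1] (default 0.5).
#' @return A `CoreSubnetwork` (list: seed, members, drivers, fitness,
#'   p_label_perm, p_random_members, edges) or `NULL`.
#' @export
build_core <- function(frequencies, seed, graph, drivers, cutoff = 0.5) {
  members <- sort(union(names(frequencies)[frequencies >= cutoff], seed))
  core_drivers <- sort(intersect(members, drivers))
  if (!length(core_drivers)) return(NULL)
  structure(list(seed = seed, members = members, drivers = core_drivers,
                 fitness = NA_real_, p_label_perm = NA_real_,
                 p_random_members = NA_real_,
                 edges = induced_edges(graph, members)),
            class = "CoreSubnetwork")
}

#' @export
print.CoreSubnetwork <- function(x, ...) {
  cat(sprintf(
    "CoreSubnetwork: seed %s, %d members (%d driver%s), fitness %s, p(label)=%s p(members)=%s\n",
    x$seed, length(x$members), length(x$drivers),
    if (length(x$drivers) == 1) "" else "s",
    format(x$fitness, digits = 4),
    format(x$p_label_perm, digits = 4),
    format(x$p_random_members, digits = 4)))
  invisible(x)
}

# add-one empirical p-value for a minimized statistic
.empirical_p <- function(null_stats, observed) {
  (1 + sum(null_stats <= observed)) / (length(null_stats) + 1)
}

#' Label-permutation significance of a core subnetwork
#'
#' Null distribution: the fitness of the FIXED core members recomputed
#' under random permutations of the phenotype labels. The p-value uses the
#' add-one estimator `(1 + #{null <= observed}) / (n_perm + 1)` (smaller
#' fitness is better, so the null is counted at or below the observed
#' value); it can never be 0 and is bounded below by 1/(n_perm + 1). When
#' fewer distinct label assignments than `n_perm` exist, all of them are
#' enumerated instead (with a message).
#'
#' @param core a `CoreSubnetwork`.
#' @param expr an `ExpressionMatrix`.
#' @param labels a `PhenotypeLabels`.
#' @param n_perm number of permutations (default 1000).
#' @param rng_seed integer seed.
#' @param n_bins fitness discretization bins (default `"auto"`).
#' @return Empirical p-value in [1/(n_perm + 1), 1].
#' @export
label_permutation_test <- function(core, expr, labels, n_perm = 1000,
                                   rng_seed = 1, n_bins = "auto") {
  stopifnot(inherits(core, "CoreSubnetwork"))
  if (n_perm < 1) stop("'n_perm' must be >= 1")
  cs <- .comparison_samples(expr, labels)
  sub <- subset_expression(expr, genes = core$members, samples = cs$samples)
  act <- subnetwork_activity(sub, core$members)
  B <- .resolve_bins(n_bins, length(act))
  bins <- discretize(act, B)
  y <- as.integer(cs$y) - 1L
  observed <- -.mi_bins_binary(bins, y, B)
  n <- length(y); k <- sum(y == 1L)
  n_distinct <- choose(n, k)
  set.seed(rng_seed)
  if (n_distinct <= n_perm) {
    message("only ", n_distinct, " distinct label assignments; enumerating ",
            "exhaustively instead of ", n_perm, " permutations")
    case_sets <- utils::combn(n, k, simplify = FALSE)
    null_stats <- vapply(case_sets, function(idx) {
      yy <- integer(n); yy[idx] <- 1L
      -.mi_bins_binary(bins, yy, B)
    }, numeric(1))
  } else {
    null_stats <- vapply(seq_len(n_perm), function(i)
      -.mi_bins_binary(bins, sample(y), B), numeric(1))
  }
  .empirical_p(null_stats, observed)
}

#' Random-membership significance of a core subnetwork
#'
#' Null distribution: the fitness of uniformly drawn gene sets of the same
#' size as the core, sampled from the expressed-gene universe (genomic
#' background), with the true labels fixed. The p-value uses the same
#' add-one estimator as [label_permutation_test()].
#'
#' @param core a `CoreSubnetwork`.
#' @param expr an `ExpressionMatrix`.
#' @param labels a `PhenotypeLabels`.
#' @param gene_universe character vector of expressed genes to draw from;
#'   must be larger than the core.
#' @param n_perm number of random member sets (default 1000).
#' @param rng_seed integer seed.
#' @param n_bins fitness discretization bins (default `"auto"`).
#' @return Empirical p-value in [1/(n_perm + 1), 1].
#' @export
random_members_test <- function(core, expr, labels, gene_universe,
                                n_perm = 1000, rng_seed = 1,
                                n_bins = "auto") {
  stopifnot(inherits(core, "CoreSubnetwork"))
  if (n_perm < 1) stop("'n_perm' must be >= 1")
  gene_universe <- intersect(unique(gene_universe), gene_ids(expr))
  k <- length(core$members)
  if (length(gene_universe) <= k)
    stop("gene universe (", length(gene_universe),
         ") must be larger than the core (", k, " members)")
  cs <- .comparison_samples(expr, labels)
  sub <- subset_expression(expr, samples = cs$samples)
  z <- .zscore_rows(sub$values)
  B <- .resolve_bins(n_bins, length(cs$samples))
  y <- as.integer(cs$y) - 1L
  fit_of <- function(members) {
    a <- colMeans(z[members, , drop = FALSE])
    lo <- min(a); hi <- max(a)
    b <- if (hi == lo) rep(0L, length(a))
         else as.integer(pmin(floor((a - lo) / (hi - lo) * B), B - 1L))
    -.mi_bins_binary(b, y, B)
  }
  observed <- fit_of(core$members)
  set.seed(rng_seed)
  null_stats <- vapply(seq_len(n_perm), function(i)
    fit_of(sample(gene_universe, k)), numeric(1))
  .empirical_p(null_stats, observed)
}

#' Extract and test the core subnetwork for one seed
#'
#' Convenience wrapper chaining [require_driver()], [gene_frequency()],
#' [build_core()] and both significance tests, filling the core's
#' `fitness`, `p_label_perm` and `p_random_members` fields.
#'
#' @param optima list of optimal member sets from [collect_optima()].
#' @param seed seed gene id.
#' @param expr an `ExpressionMatrix`.
#' @param labels a `PhenotypeLabels`.
#' @param graph an `InteractionGraph`.
#' @param drivers character vector of putative driver genes.
#' @param gene_universe expressed-gene universe for the random-members null.
#' @param cutoff frequency cutoff (default 0.5).
#' @param n_perm permutations per test (default 1000).
#' @param rng_seed integer seed.
#' @param n_bins fitness discretization bins (default `"auto"`).
#' @return A tested `CoreSubnetwork`, or `NULL` when no driver-containing
#'   subnetwork survives.
#' @export
extract_core <- function(optima, seed, expr, labels, graph, drivers,
                         gene_universe, cutoff = 0.5, n_perm = 1000,
                         rng_seed = 1, n_bins = "auto") {
  kept <- require_driver(optima, drivers)
  if (!length(kept)) return(NULL)
  core <- build_core(gene_frequency(kept), seed, graph, drivers, cutoff)
  if (is.null(core)) return(NULL)
  cfg <- ga_config(n_bins = n_bins, rng_seed = rng_seed)
  core$fitness <- fitness(core$members, expr, labels, cfg)
  core$p_label_perm <- suppressMessages(
    label_permutation_test(core, expr, labels, n_perm, rng_seed, n_bins))
  core$p_random_members <- random_members_test(
    core, expr, labels, gene_universe, n_perm, rng_seed + 1L, n_bins)
  core
}
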