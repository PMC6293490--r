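# Small in-code fixtures shared across test files.

# genes x samples matrix with G*/S* dimnames
make_values <- function(nrow, ncol, data) {
  matrix(data, nrow, ncol,
         dimnames = list(sprintf("G%d", seq_len(nrow)),
                         sprintf("S%d", seq_len(ncol))))
}

make_expr <- function(nrow, ncol, data, counts = NULL) {
  v <- make_values(nrow, ncol, data)
  cm <- if (!is.null(counts)) make_values(nrow, ncol, counts)
  expression_matrix(v, cm)
}

make_balanced_labels <- function(n_per_class, classes = c("ctl", "case"),
                                 samples = NULL) {
  cl <- rep(classes, each = n_per_class)
  if (is.null(samples)) samples <- sprintf("S%d", seq_along(cl))
  phenotype_labels(stats::setNames(cl, samples), classes[c(1, length(classes))])
}

# star interaction graph: seed joined to each candidate by a ppi edge
star_graph <- function(seed, leaves) {
  interaction_graph(data.frame(u = seed, v = leaves, kind = "ppi",
                               stringsAsFactors = FALSE))
}

# path graph a-b-c-... as ppi edges
path_graph <- function(nodes) {
  interaction_graph(data.frame(u = nodes[-length(nodes)], v = nodes[-1],
                               kind = "ppi", stringsAsFactors = FALSE))
}

# Random small GA instance with a planted discriminative gene subset:
# lognormal background, k_sig genes shifted up in the case class.
# Returns everything needed to evolve and to brute-force.
make_planted_instance <- function(seed_int, L = NULL, n = 20, shift = 2) {
  set.seed(seed_int)
  if (is.null(L)) L <- sample(8:12, 1)
  genes <- sprintf("C%02d", seq_len(L))
  logx <- matrix(stats::rnorm((L + 1) * n, 3, 1), L + 1, n)
  y <- rep(0:1, each = n / 2)
  k_sig <- sample(2:3, 1)
  sig <- sample(seq_len(L), k_sig) + 1
  logx[sig, y == 1] <- logx[sig, y == 1] + shift
  vals <- 2^logx
  dimnames(vals) <- list(c("SEED", genes), sprintf("S%02d", seq_len(n)))
  labels <- phenotype_labels(
    stats::setNames(ifelse(y == 0, "ctl", "case"), colnames(vals)),
    c("ctl", "case"))
  expr <- expression_matrix(vals)
  graph <- star_graph("SEED", genes)
  cs <- build_candidate_set(graph, expr, "SEED", radius = 1,
                            fpkm_threshold = 0)
  list(expr = expr, labels = labels, graph = graph, candidate_set = cs,
       y = y, vals = vals, signal = rownames(vals)[sig])
}

# Random GA instance at the benchmark's study conditions: planted
# discriminative genes at effect size 3 (log2 scale), 50 samples/class.
make_study_instance <- function(seed_int) {
  set.seed(seed_int)
  L <- sample(8:14, 1)
  n <- 100
  genes <- sprintf("C%02d", seq_len(L))
  logx <- matrix(stats::rnorm((L + 1) * n, 3, 1), L + 1, n)
  y <- rep(0:1, each = n / 2)
  k_sig <- sample(2:4, 1)
  sig <- sample(seq_len(L), k_sig) + 1
  logx[sig, y == 1] <- logx[sig, y == 1] + 3
  vals <- 2^logx
  dimnames(vals) <- list(c("SEED", genes), sprintf("S%03d", seq_len(n)))
  labels <- phenotype_labels(
    stats::setNames(ifelse(y == 0, "ctl", "case"), colnames(vals)),
    c("ctl", "case"))
  expr <- expression_matrix(vals)
  cs <- build_candidate_set(star_graph("SEED", genes), expr, "SEED",
                            radius = 1, fpkm_threshold = 0)
  list(expr = expr, labels = labels, candidate_set = cs, y = y, vals = vals,
       signal = rownames(vals)[sig])
}

# Precision/recall of a core subnetwork against the planted module.
core_recovery <- function(core, module_genes) {
  tp <- length(intersect(core$members, module_genes))
  c(precision = tp / length(core$members), recall = tp / length(module_genes))
}

# Independent oracle: exhaustive enumeration of all subsets of the
# candidate genes (seed always included), evaluating the documented
# fitness definition directly (z-score mean activity, equal-width bins,
# plug-in MI in bits). Returns the minimum fitness.
brute_force_min_fitness <- function(vals, y, n_bins) {
  zs <- t(apply(vals, 1, function(r) {
    s <- stats::sd(r)
    if (s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
  L <- nrow(zs) - 1
  best <- Inf
  for (m in 0:(2^L - 1)) {
    sel <- which(bitwAnd(m, 2^(0:(L - 1))) > 0)
    a <- colMeans(zs[c(1, sel + 1), , drop = FALSE])
    lo <- min(a); hi <- max(a)
    b <- if (hi == lo) rep(0L, length(a))
         else pmin(floor((a - lo) / (hi - lo) * n_bins), n_bins - 1)
    f <- -mi_oracle(b, y)
    if (f < best) best <- f
  }
  best
}

# Independent plug-in MI oracle (bits): explicit double sum over the
# joint table.
mi_oracle <- function(x, y) {
  xs <- unique(x); ys <- unique(y)
  n <- length(x)
  mi <- 0
  for (a in xs) for (b in ys) {
    pxy <- sum(x == a & y == b) / n
    if (pxy > 0) {
      px <- sum(x == a) / n
      py <- sum(y == b) / n
      mi <- mi + pxy * log2(pxy / (px * py))
    }
  }
  max(mi, 0)
}

# Independent Benjamini-Hochberg oracle: direct sort-and-cummin.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}
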