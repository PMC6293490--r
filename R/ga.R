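#' GA configuration
#'
#' Parameters of the elitist binary genetic algorithm. Defaults follow the
#' sparse-subnetwork setting: mutation rate 5%, zero-to-one rate 19 (a bit
#' set during initialization or mutation becomes 1 with probability
#' 1/(zero_to_one_rate + 1) = 5%, so subnetworks stay small), elite
#' fraction 5% (the chromosomes with the smallest fitness pass unchanged
#' to the next generation), 500 generations, population 200.
#'
#' @param population_size number of chromosomes per generation.
#' @param generations number of generations to evolve.
#' @param mutation_rate per-bit mutation probability.
#' @param zero_to_one_rate sparsity control; mutated/initialized bits are 1
#'   with probability 1/(rate + 1).
#' @param elite_fraction fraction of the population kept unchanged each
#'   generation (smallest fitness first).
#' @param n_bins number of discretization bins for the fitness, or
#'   `"auto"` for the Sturges rule ceil(log2(n_samples)) + 1.
#' @param local_search if `TRUE` (default), the incumbent best chromosome
#'   is refined by single-bit-flip hill climbing each generation (memetic
#'   step). The sparse mutation kernel biases the population toward small
#'   subnetworks; the deterministic climb restores the ability to reach
#'   optima that are not sparse. Costs one extra evaluation of
#'   chromosome-length many neighbors per improvement step; disable for
#'   very long chromosomes.
#' @param rng_seed integer seed controlling all GA randomness.
#' @return A list of class `GAConfig`.
#' @export
ga_config <- function(population_size = 200, generations = 500,
                      mutation_rate = 0.05, zero_to_one_rate = 19,
                      elite_fraction = 0.05, n_bins = "auto",
                      local_search = TRUE, rng_seed = 1) {
  if (elite_fraction <= 0 || elite_fraction >= 1)
    stop("'elite_fraction' must lie strictly between 0 and 1")
  if (population_size < 2 / elite_fraction)
    stop("'population_size' must be >= 2/elite_fraction so the elite has >= 2 members")
  if (zero_to_one_rate < 1) stop("'zero_to_one_rate' must be >= 1")
  if (mutation_rate < 0 || mutation_rate > 1)
    stop("'mutation_rate' must lie in [0, 1]")
  if (generations < 0) stop("'generations' must be >= 0")
  if (!identical(n_bins, "auto") && (!is.numeric(n_bins) || n_bins < 1))
    stop("'n_bins' must be \"auto\" or an integer >= 1")
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 mutation_rate = mutation_rate,
                 zero_to_one_rate = zero_to_one_rate,
                 elite_fraction = elite_fraction,
                 n_bins = n_bins,
                 local_search = isTRUE(local_search),
                 rng_seed = as.integer(rng_seed)),
            class = "GAConfig")
}

#' Subnetwork activity profile
#'
#' Summarizes the expression of a gene set into one value per sample:
#' each member gene is z-scored across the samples of `expr`
#' (zero-variance genes map to an all-zero profile), and the per-sample
#' mean over members is returned.
#'
#' @param expr an `ExpressionMatrix` (typically restricted to the samples
#'   under comparison).
#' @param members nonempty character vector of member gene ids.
#' @return Numeric vector with one activity value per sample.
#' @export
subnetwork_activity <- function(expr, members) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  members <- unique(as.character(members))
  if (!length(members)) stop("'members' must be nonempty")
  missing <- setdiff(members, gene_ids(expr))
  if (length(missing))
    stop("member gene(s) not in expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  z <- .zscore_rows(expr$values[members, , drop = FALSE])
  colMeans(z)
}

# row-wise z-score; rows with zero variance become all zero
.zscore_rows <- function(m) {
  mu <- rowMeans(m)
  s <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  z <- (m - mu) / ifelse(s == 0, 1, s)
  z[s == 0, ] <- 0
  z
}

#' Equal-width discretization
#'
#' Bins a numeric vector into `n_bins` equal-width bins over its observed
#' [min, max]; `"auto"` uses the Sturges rule ceil(log2(n)) + 1. A
#' constant vector maps to a single bin with label 0.
#'
#' @param values finite numeric vector.
#' @param n_bins integer >= 1 or `"auto"`.
#' @return Integer vector of 0-based bin labels.
#' @export
discretize <- function(values, n_bins = "auto") {
  if (any(!is.finite(values))) stop("'values' must be finite")
  n_bins <- .resolve_bins(n_bins, length(values))
  lo <- min(values); hi <- max(values)
  if (hi == lo) return(rep(0L, length(values)))
  idx <- floor((values - lo) / (hi - lo) * n_bins)
  as.integer(pmin(idx, n_bins - 1L))
}

.resolve_bins <- function(n_bins, n) {
  if (identical(n_bins, "auto")) {
    if (n < 1) stop("cannot auto-select bins for empty input")
    return(as.integer(ceiling(log2(n)) + 1))
  }
  if (!is.numeric(n_bins) || n_bins < 1) stop("'n_bins' must be >= 1")
  as.integer(n_bins)
}

#' Mutual information between discrete variables (bits)
#'
#' Plug-in mutual information of the joint empirical distribution,
#' in bits (log base 2). Non-negative; zero when either marginal is
#' constant.
#'
#' @param bins_x integer (or factor-like) labels.
#' @param labels_y class labels of the same length.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(bins_x, labels_y) {
  if (length(bins_x) != length(labels_y))
    stop("'bins_x' and 'labels_y' must have equal length")
  if (length(bins_x) < 2) stop("need at least 2 observations")
  joint <- table(bins_x, labels_y)
  n <- sum(joint)
  pxy <- joint / n
  px <- rowSums(pxy); py <- colSums(pxy)
  terms <- pxy * log2(pxy / outer(px, py))
  mi <- sum(terms[pxy > 0])
  max(mi, 0)
}

#' Construct a subnetwork chromosome
#'
#' A binary vector over a seed's candidate gene list; bit i = 1 selects
#' `candidate_set$genes[i]` into the subnetwork. The seed gene is an
#' implicit, unconditional member and has no bit.
#'
#' @param candidate_set a `CandidateSet`.
#' @param bits 0/1 vector of length `length(candidate_set$genes)`.
#' @return An object of class `SubnetworkChromosome`.
#' @export
chromosome <- function(candidate_set, bits) {
  stopifnot(inherits(candidate_set, "CandidateSet"))
  bits <- as.integer(bits)
  if (length(bits) != length(candidate_set$genes))
    stop("'bits' length must equal the candidate gene count")
  if (!all(bits %in% c(0L, 1L))) stop("'bits' must be 0/1")
  structure(list(candidate_set = candidate_set, bits = bits),
            class = "SubnetworkChromosome")
}

#' Member genes implied by a chromosome
#' @param chrom a `SubnetworkChromosome`.
#' @return Sorted character vector: the seed plus all selected genes.
#' @export
chromosome_members <- function(chrom) {
  stopifnot(inherits(chrom, "SubnetworkChromosome"))
  sort(c(chrom$candidate_set$seed,
         chrom$candidate_set$genes[chrom$bits == 1L]))
}

#' GA fitness of a subnetwork
#'
#' Fitness is the negated mutual information between the discretized
#' subnetwork activity and the binary phenotype contrast; the GA
#' minimizes it, so more discriminative subnetworks have smaller
#' (more negative) fitness. Deterministic given its inputs.
#'
#' @param chrom a `SubnetworkChromosome`, or a character vector of member
#'   genes.
#' @param expr an `ExpressionMatrix`.
#' @param labels a `PhenotypeLabels`.
#' @param config a `GAConfig` (only `n_bins` is used).
#' @return Negated mutual information in bits (<= 0).
#' @export
fitness <- function(chrom, expr, labels, config = ga_config()) {
  members <- if (inherits(chrom, "SubnetworkChromosome"))
    chromosome_members(chrom) else as.character(chrom)
  cs <- .comparison_samples(expr, labels)
  sub <- subset_expression(expr, samples = cs$samples)
  act <- subnetwork_activity(sub, members)
  -mutual_information(discretize(act, config$n_bins), cs$y)
}

#' Initialize a GA population
#'
#' Draws `population_size` chromosomes with each bit independently 1 with
#' probability 1/(zero_to_one_rate + 1); reproducible under
#' `config$rng_seed`.
#'
#' @param candidate_set a `CandidateSet` with at least one candidate gene.
#' @param config a `GAConfig`.
#' @return Integer 0/1 matrix, `population_size` rows, one column per
#'   candidate gene.
#' @export
init_population <- function(candidate_set, config = ga_config()) {
  stopifnot(inherits(candidate_set, "CandidateSet"))
  L <- length(candidate_set$genes)
  if (L == 0)
    stop("candidate set is empty; the seed-only subnetwork needs no GA ",
         "(evolve() handles this case directly)")
  set.seed(config$rng_seed)
  p1 <- 1 / (config$zero_to_one_rate + 1)
  matrix(as.integer(stats::runif(config$population_size * L) < p1),
         nrow = config$population_size, ncol = L)
}

# Precompute everything fitness evaluation needs for a candidate set:
# z-scored expression of seed + candidates on the comparison samples,
# binary labels, bin count.
.ga_problem <- function(candidate_set, expr, labels, n_bins = "auto") {
  cs <- .comparison_samples(expr, labels)
  genes <- c(candidate_set$seed, candidate_set$genes)
  missing <- setdiff(genes, gene_ids(expr))
  if (length(missing))
    stop("candidate gene(s) missing from expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  z <- .zscore_rows(expr$values[genes, cs$samples, drop = FALSE])
  list(z_seed = z[1, ], z_genes = z[-1, , drop = FALSE],
       y = as.integer(cs$y) - 1L, n_bins = .resolve_bins(n_bins, length(cs$y)),
       n_samples = length(cs$y))
}

# fast MI for 0-based integer bins vs 0/1 labels, in bits
.mi_bins_binary <- function(bins, y01, n_bins) {
  counts <- tabulate(bins * 2L + y01 + 1L, nbins = 2L * n_bins)
  n <- length(bins)
  p <- counts / n
  px <- p[c(TRUE, FALSE)] + p[c(FALSE, TRUE)]
  py0 <- sum(p[c(TRUE, FALSE)]); py1 <- 1 - py0
  pxy_prod <- c(rbind(px * py0, px * py1))
  nz <- p > 0
  mi <- sum(p[nz] * log2(p[nz] / pxy_prod[nz]))
  max(mi, 0)
}

# Evaluate a 0/1 population matrix against a .ga_problem; returns the
# fitness vector (negated MI). Fully vectorized over the population:
# one matrix product for the activities, then row-wise equal-width
# binning and joint-count tabulation in matrix form.
.eval_population <- function(bits, problem) {
  nsel <- rowSums(bits)
  act <- (bits %*% problem$z_genes +
            matrix(problem$z_seed, nrow(bits), problem$n_samples, byrow = TRUE)) /
         (nsel + 1)
  n_pop <- nrow(act); n <- ncol(act); B <- problem$n_bins
  lo <- act[cbind(seq_len(n_pop), max.col(-act, "first"))]
  hi <- act[cbind(seq_len(n_pop), max.col(act, "first"))]
  rng <- hi - lo
  const <- rng == 0
  rng[const] <- 1
  binm <- floor((act - lo) / rng * B)
  binm[binm > B - 1] <- B - 1
  binm[const, ] <- 0
  # joint cell index (bin, label) per observation, offset per row
  code <- binm * 2 + matrix(problem$y, n_pop, n, byrow = TRUE) + 1
  code <- code + (seq_len(n_pop) - 1) * 2 * B
  counts <- matrix(tabulate(code, nbins = n_pop * 2 * B),
                   nrow = n_pop, byrow = TRUE)
  P <- counts / n
  odd <- seq(1, 2 * B, by = 2)
  px <- P[, odd, drop = FALSE] + P[, odd + 1, drop = FALSE]
  py0 <- rowSums(P[, odd, drop = FALSE])
  prod0 <- px * py0
  prod1 <- px * (1 - py0)
  Q <- P
  Q[, odd] <- prod0
  Q[, odd + 1] <- prod1
  term <- P * log2(P / Q)
  term[P == 0] <- 0
  mi <- pmax(rowSums(term), 0)
  -mi
}

#' Evolve a population of subnetwork chromosomes
#'
#' Elitist generational loop: every generation the chromosomes with the
#' smallest fitness (ties broken by fewer selected genes, then
#' lexicographically on the bit string) are copied unchanged, and the rest
#' of the population is refilled by uniform crossover of two parents drawn
#' by rank-weighted sampling followed by per-bit mutation (a mutated bit
#' becomes 1 with probability 1/(zero_to_one_rate + 1), else 0). An empty
#' candidate set degenerates to the seed-only subnetwork without any GA.
#'
#' @param candidate_set a `CandidateSet`.
#' @param expr an `ExpressionMatrix` containing seed and candidates.
#' @param labels a `PhenotypeLabels`.
#' @param config a `GAConfig`.
#' @return An object of class `ga_result`: list with `population` (0/1
#'   matrix), `fitness` (per-chromosome), `best_fitness`, `trajectory`
#'   (data.frame generation, best_fitness, mean_fitness, elite_size),
#'   `candidate_set`, `config`.
#' @export
evolve <- function(candidate_set, expr, labels, config = ga_config()) {
  stopifnot(inherits(candidate_set, "CandidateSet"), inherits(config, "GAConfig"))
  L <- length(candidate_set$genes)
  if (L == 0) {
    f <- fitness(candidate_set$seed, expr, labels, config)
    return(structure(list(population = matrix(integer(0), nrow = 1, ncol = 0),
                          fitness = f, best_fitness = f,
                          trajectory = data.frame(generation = 0L,
                                                  best_fitness = f,
                                                  mean_fitness = f,
                                                  elite_size = 1L),
                          candidate_set = candidate_set, config = config),
                     class = "ga_result"))
  }
  problem <- .ga_problem(candidate_set, expr, labels, config$n_bins)
  pop <- init_population(candidate_set, config)  # seeds the RNG stream
  n_pop <- config$population_size
  elite_n <- max(1L, floor(config$elite_fraction * n_pop))
  p1 <- 1 / (config$zero_to_one_rate + 1)
  fit <- .eval_population(pop, problem)
  traj <- vector("list", config$generations + 1L)
  ord <- .ga_order(fit, pop)
  if (config$local_search) {
    up <- .memetic_step(pop, fit, ord, problem)
    pop <- up$pop; fit <- up$fit; ord <- up$ord
  }
  traj[[1]] <- data.frame(generation = 0L, best_fitness = fit[ord[1]],
                          mean_fitness = mean(fit), elite_size = elite_n)
  gen <- 0L
  while (gen < config$generations) {
    gen <- gen + 1L
    # elite slots go to DISTINCT chromosomes first, so equally optimal
    # subnetworks survive side by side for the downstream frequency vote
    keys <- apply(pop[ord, , drop = FALSE], 1, paste0, collapse = "")
    elite_idx <- c(ord[!duplicated(keys)], ord[duplicated(keys)])[seq_len(elite_n)]
    elite <- pop[elite_idx, , drop = FALSE]
    elite_fit <- fit[elite_idx]
    n_child <- n_pop - elite_n
    # rank-weighted parent sampling: best rank gets weight n_pop
    w <- rev(seq_len(n_pop))
    pa <- sample.int(n_pop, n_child, replace = TRUE, prob = w)
    pb <- sample.int(n_pop, n_child, replace = TRUE, prob = w)
    P1 <- pop[ord[pa], , drop = FALSE]
    P2 <- pop[ord[pb], , drop = FALSE]
    mask <- matrix(stats::runif(n_child * L) < 0.5, n_child, L)
    children <- ifelse(mask, P1, P2)
    mut <- matrix(stats::runif(n_child * L) < config$mutation_rate, n_child, L)
    newbit <- matrix(as.integer(stats::runif(n_child * L) < p1), n_child, L)
    children[mut] <- newbit[mut]
    storage.mode(children) <- "integer"
    child_fit <- .eval_population(children, problem)
    pop <- rbind(elite, children)
    fit <- c(elite_fit, child_fit)
    ord <- .ga_order(fit, pop)
    if (config$local_search) {
      up <- .memetic_step(pop, fit, ord, problem)
      pop <- up$pop; fit <- up$fit; ord <- up$ord
    }
    traj[[gen + 1L]] <- data.frame(generation = gen, best_fitness = fit[ord[1]],
                                   mean_fitness = mean(fit),
                                   elite_size = elite_n)
  }
  structure(list(population = pop, fitness = fit,
                 best_fitness = min(fit),
                 trajectory = do.call(rbind, traj[seq_len(gen + 1L)]),
                 candidate_set = candidate_set, config = config),
            class = "ga_result")
}

# Memetic refinement: hill-climb the incumbent best chromosome
# (exploitation) and one uniformly random chromosome (unbiased
# multistart, since the sparse mutation kernel alone rarely visits dense
# regions); improvements overwrite the worst chromosome so elitism
# retains them.
.memetic_step <- function(pop, fit, ord, problem) {
  n_pop <- nrow(pop); L <- ncol(pop)
  rand_start <- as.integer(stats::runif(L) < 0.5)
  starts <- list(list(bits = pop[ord[1], ], fit = fit[ord[1]]),
                 list(bits = rand_start,
                      fit = .eval_population(matrix(rand_start, 1), problem)[1]))
  for (s in starts) {
    ls <- .hill_climb(s$bits, s$fit, problem)
    if (ls$fit < fit[ord[n_pop]]) {
      worst <- ord[n_pop]
      pop[worst, ] <- ls$bits
      fit[worst] <- ls$fit
      ord <- .ga_order(fit, pop)
    }
  }
  list(pop = pop, fit = fit, ord = ord)
}

# Deterministic single-bit-flip hill climbing: repeatedly move to the
# best strictly improving Hamming-1 neighbor. Strict decrease guarantees
# termination.
.hill_climb <- function(bits, fit_val, problem) {
  L <- length(bits)
  repeat {
    nb <- matrix(bits, L, L, byrow = TRUE)
    flip <- cbind(seq_len(L), seq_len(L))
    nb[flip] <- 1L - nb[flip]
    f <- .eval_population(nb, problem)
    i <- which.min(f)
    if (f[i] < fit_val) {
      bits[i] <- 1L - bits[i]
      fit_val <- f[i]
    } else break
  }
  list(bits = as.integer(bits), fit = fit_val)
}

# ascending fitness; ties -> fewer selected genes -> lexicographic bits
.ga_order <- function(fit, pop) {
  keys <- apply(pop, 1, paste0, collapse = "")
  order(fit, rowSums(pop), keys)
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("ga_result: seed %s, best fitness %.6f over %d generations (pop %d)\n",
              x$candidate_set$seed, x$best_fitness,
              max(x$trajectory$generation), nrow(x$population)))
  invisible(x)
}

#' Collect all equally optimal subnetworks from a final population
#'
#' Returns the distinct member sets (seed included) whose fitness equals
#' the population minimum within an absolute tolerance. Bit-distinct
#' chromosomes implying the same member set are deduplicated.
#'
#' @param ga_result result of [evolve()].
#' @param tol absolute fitness tolerance (default 1e-12).
#' @return List of sorted character vectors (member sets).
#' @export
collect_optima <- function(ga_result, tol = 1e-12) {
  stopifnot(inherits(ga_result, "ga_result"))
  cs <- ga_result$candidate_set
  if (length(cs$genes) == 0) return(list(cs$seed))
  best <- min(ga_result$fitness)
  rows <- which(ga_result$fitness <= best + tol)
  sets <- lapply(rows, function(i)
    sort(c(cs$seed, cs$genes[ga_result$population[i, ] == 1L])))
  unique(sets)
}

#' Write a GA run log
#'
#' Per-generation TSV (generation, best_fitness, mean_fitness, elite_size)
#' with the configuration echoed in `#`-prefixed header lines.
#'
#' @param ga_result result of [evolve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ga_log <- function(ga_result, path) {
  stopifnot(inherits(ga_result, "ga_result"))
  cfg <- ga_result$config
  hdr <- sprintf("# %s=%s", names(cfg), vapply(cfg, format, character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, sprintf("# seed_gene=%s", ga_result$candidate_set$seed)), con)
  utils::write.table(ga_result$trajectory, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
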