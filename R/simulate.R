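#' Simulation configuration for the synthetic benchmark
#'
#' Describes a two- or three-class expression study with planted
#' phenotype-discriminative modules embedded in a random interaction
#' graph, plus designated driver genes, emulating the statistical
#' structure the pipeline assumes: lognormal FPKM-like abundance, a case
#' vs control contrast (optionally with an intermediate pre-invasive-like
#' class shifted by half the effect), and a driver-score table where only
#' a controlled fraction of drivers falls inside the planted modules.
#'
#' @param n_genes total number of genes (coding + tf + lncrna).
#' @param n_tfs number of transcription-factor nodes.
#' @param n_lncrnas number of lncRNA nodes.
#' @param n_samples_per_class samples per phenotype class.
#' @param mean_degree target mean degree of the random interaction graph.
#' @param planted_modules list of modules, each
#'   `list(size =, effect_size =)`; effect sizes are in units of the
#'   log-scale noise SD, so with `noise_sd = 1` an effect of 3 is a
#'   log2 fold change of 3.
#' @param noise_sd SD of log2 expression noise.
#' @param n_driver_genes number of genes given driver-grade scores.
#' @param driver_overlap_with_module fraction of driver genes placed
#'   inside planted modules.
#' @param three_class add an intermediate class shifted by half the
#'   module effect (mirrors a normal / pre-invasive / invasive design).
#' @param baseline_log_mean,baseline_log_sd distribution of per-gene
#'   baseline log2 abundance.
#' @param rng_seed integer seed; every generated artifact is a pure
#'   function of the config including this seed.
#' @return A list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_genes = 500, n_tfs = 20, n_lncrnas = 10,
                              n_samples_per_class = 50, mean_degree = 4,
                              planted_modules = list(list(size = 5, effect_size = 3)),
                              noise_sd = 1, n_driver_genes = 10,
                              driver_overlap_with_module = 0.1,
                              three_class = TRUE,
                              baseline_log_mean = 3, baseline_log_sd = 1.5,
                              rng_seed = 1) {
  stopifnot(n_genes > 0, n_tfs >= 0, n_lncrnas >= 0,
            n_samples_per_class >= 2, mean_degree > 0, noise_sd > 0,
            n_driver_genes >= 0,
            driver_overlap_with_module >= 0, driver_overlap_with_module <= 1)
  if (n_tfs + n_lncrnas >= n_genes)
    stop("n_tfs + n_lncrnas must be smaller than n_genes")
  for (m in planted_modules) {
    if (is.null(m$size) || is.null(m$effect_size))
      stop("each planted module needs 'size' and 'effect_size'")
    if (m$size > n_genes) stop("planted module size exceeds n_genes")
  }
  structure(list(n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
                 n_lncrnas = as.integer(n_lncrnas),
                 n_samples_per_class = as.integer(n_samples_per_class),
                 mean_degree = mean_degree,
                 planted_modules = planted_modules, noise_sd = noise_sd,
                 n_driver_genes = as.integer(n_driver_genes),
                 driver_overlap_with_module = driver_overlap_with_module,
                 three_class = isTRUE(three_class),
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "SimulationConfig")
}

.sim_gene_names <- function(config) {
  n_cod <- config$n_genes - config$n_tfs - config$n_lncrnas
  c(sprintf("G%04d", seq_len(n_cod)),
    if (config$n_tfs) sprintf("TF%03d", seq_len(config$n_tfs)),
    if (config$n_lncrnas) sprintf("LNC%03d", seq_len(config$n_lncrnas)))
}

# module gene assignment is deterministic given the config: module m gets
# the coding genes right after the seed blocks, seeds first
.sim_modules <- function(config) {
  genes <- .sim_gene_names(config)
  coding <- genes[!startsWith(genes, "TF") & !startsWith(genes, "LNC")]
  out <- list(); used <- 0
  for (i in seq_along(config$planted_modules)) {
    size <- config$planted_modules[[i]]$size
    if (used + size > length(coding))
      stop("planted modules exceed the available coding genes")
    members <- coding[(used + 1):(used + size)]
    out[[i]] <- list(id = i, seed_gene = members[1], members = members,
                     effect_size = config$planted_modules[[i]]$effect_size)
    used <- used + size
  }
  out
}

#' Generate a random typed interaction graph with planted modules
#'
#' Draws an Erdos-Renyi-style random graph at the requested mean degree
#' over all genes, types the nodes (coding / tf / lncrna), assigns edge
#' kinds by their source node (tf -> `tf_target`, lncrna -> `lnc_target`,
#' otherwise `ppi`), and wires every planted module as a star around its
#' seed gene so all module members lie within radius 1 of the seed (hence
#' within the radius-3 search ball).
#'
#' @param config a `SimulationConfig`.
#' @return An `InteractionGraph`.
#' @export
generate_graph <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$rng_seed)
  genes <- .sim_gene_names(config)
  n <- length(genes)
  m <- round(n * config$mean_degree / 2)
  g <- igraph::sample_gnm(n, m)
  el <- igraph::as_edgelist(g)
  u <- genes[el[, 1]]; v <- genes[el[, 2]]
  kinds <- rep("coding", n); names(kinds) <- genes
  kinds[startsWith(genes, "TF")] <- "tf"
  kinds[startsWith(genes, "LNC")] <- "lncrna"
  edge_kind <- function(a, b) {
    ifelse(kinds[a] == "lncrna", "lnc_target",
           ifelse(kinds[a] == "tf", "tf_target",
                  ifelse(kinds[b] == "lncrna", "lnc_target",
                         ifelse(kinds[b] == "tf", "tf_target", "ppi"))))
  }
  # regulatory edges point out of the regulator
  swap <- kinds[v] %in% c("tf", "lncrna") & !kinds[u] %in% c("tf", "lncrna")
  tmp <- u[swap]; u[swap] <- v[swap]; v[swap] <- tmp
  edges <- data.frame(u = u, v = v, kind = edge_kind(u, v),
                      stringsAsFactors = FALSE)
  for (mod in .sim_modules(config)) {
    others <- setdiff(mod$members, mod$seed_gene)
    if (length(others))
      edges <- rbind(edges, data.frame(u = mod$seed_gene, v = others,
                                       kind = "ppi", stringsAsFactors = FALSE))
  }
  interaction_graph(edges, node_kinds = kinds)
}

#' Generate a synthetic expression study
#'
#' Background genes get class-independent lognormal abundance
#' (`log2 x ~ N(baseline, noise_sd)`); planted-module genes are shifted in
#' the case class by `effect_size * noise_sd` on the log2 scale (and by
#' half of that in the optional intermediate class). Raw counts are drawn
#' as Poisson reads proportional to abundance. The truth record lists
#' module memberships for downstream recovery scoring.
#'
#' @param graph the `InteractionGraph` from [generate_graph()] (used for
#'   consistency checks; expression is generated per gene).
#' @param config a `SimulationConfig`.
#' @return List with `expr` (an `ExpressionMatrix` with raw counts),
#'   `labels` (a `PhenotypeLabels`, comparison control vs case) and
#'   `truth` (data.frame gene, module_id, seed_gene).
#' @export
generate_expression <- function(graph, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$rng_seed + 1L)
  genes <- .sim_gene_names(config)
  stopifnot(all(genes %in% graph$nodes$gene))
  classes <- c("control", if (config$three_class) "intermediate", "case")
  n_per <- config$n_samples_per_class
  sample_class <- rep(classes, each = n_per)
  samples <- sprintf("S%03d_%s", seq_along(sample_class), sample_class)
  baseline <- stats::rnorm(length(genes), config$baseline_log_mean,
                           config$baseline_log_sd)
  names(baseline) <- genes
  shift <- matrix(0, length(genes), length(sample_class),
                  dimnames = list(genes, samples))
  mods <- .sim_modules(config)
  for (mod in mods) {
    delta <- mod$effect_size * config$noise_sd
    shift[mod$members, sample_class == "case"] <- delta
    if (config$three_class)
      shift[mod$members, sample_class == "intermediate"] <- delta / 2
  }
  logx <- baseline + shift +
    matrix(stats::rnorm(length(genes) * length(samples), 0, config$noise_sd),
           length(genes), length(samples))
  values <- 2^logx
  dimnames(values) <- list(genes, samples)
  counts <- matrix(stats::rpois(length(values), lambda = pmin(values * 10, 1e7)),
                   nrow(values), ncol(values), dimnames = dimnames(values))
  truth_rows <- do.call(rbind, lapply(mods, function(mod)
    data.frame(gene = mod$members, module_id = mod$id,
               seed_gene = mod$seed_gene, stringsAsFactors = FALSE)))
  if (is.null(truth_rows))
    truth_rows <- data.frame(gene = character(0), module_id = integer(0),
                             seed_gene = character(0))
  list(expr = expression_matrix(values, counts),
       labels = phenotype_labels(stats::setNames(sample_class, samples),
                                 comparison = c("control", "case")),
       truth = truth_rows)
}

#' Generate a synthetic driver-score table
#'
#' `n_driver_genes` genes receive driver-grade scores (score > 0.8,
#' p < 0.05); the fraction `driver_overlap_with_module` of them is placed
#' inside planted modules (seed genes excluded so driver status is not
#' trivially tied to the seed), the rest on background genes. All other
#' genes receive sub-threshold scores. This reproduces the typical
#' situation where most putative drivers are not differentially
#' expressed.
#'
#' @param graph the `InteractionGraph` (gene universe).
#' @param config a `SimulationConfig`.
#' @param truth truth record from [generate_expression()].
#' @return A `DriverTable` covering every gene.
#' @export
generate_drivers <- function(graph, config, truth) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$rng_seed + 2L)
  genes <- .sim_gene_names(config)
  n_drv <- config$n_driver_genes
  k_in <- round(config$driver_overlap_with_module * n_drv)
  module_pool <- setdiff(truth$gene, unique(truth$seed_gene))
  if (k_in > length(module_pool))
    stop("requested module-driver overlap (", k_in,
         ") exceeds available non-seed module genes (", length(module_pool), ")")
  bg_pool <- setdiff(genes, truth$gene)
  if (n_drv - k_in > length(bg_pool))
    stop("requested driver count exceeds available background genes")
  inside <- if (k_in) sample(module_pool, k_in) else character(0)
  outside <- if (n_drv - k_in) sample(bg_pool, n_drv - k_in) else character(0)
  driver_genes <- c(inside, outside)
  score <- stats::runif(length(genes), 0, 0.8)
  p <- stats::runif(length(genes), 0.01, 1)
  names(score) <- names(p) <- genes
  score[driver_genes] <- stats::runif(length(driver_genes), 0.81, 0.99)
  p[driver_genes] <- stats::runif(length(driver_genes), 0.001, 0.049)
  driver_table(genes, unname(score), unname(p))
}

#' Generate a complete synthetic data set
#'
#' Chains [generate_graph()], [generate_expression()] and
#' [generate_drivers()]. Fully reproducible: the same config (including
#' `rng_seed`) always yields identical artifacts.
#'
#' @param config a `SimulationConfig`.
#' @return List with `graph`, `expr`, `labels`, `drivers`, `truth`,
#'   `config`.
#' @export
generate_dataset <- function(config = simulation_config()) {
  graph <- generate_graph(config)
  ex <- generate_expression(graph, config)
  drivers <- generate_drivers(graph, config, ex$truth)
  list(graph = graph, expr = ex$expr, labels = ex$labels,
       drivers = drivers, truth = ex$truth, config = config)
}

#' Write the truth record to TSV (gene, module_id, seed_gene, is_driver)
#'
#' @param truth truth data.frame from [generate_expression()].
#' @param drivers a `DriverTable` (used to flag driver genes).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, drivers, path) {
  driver_set <- filter_drivers(drivers)
  truth$is_driver <- truth$gene %in% driver_set
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
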