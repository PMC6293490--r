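#' Pipeline configuration
#'
#' Collects every tunable parameter of the end-to-end analysis with its
#' standard default: fold-change 2, FDR 0.05, median-FPKM expression
#' threshold 1.0, expansion radius 3, top 200 lncRNA targets, driver
#' score > 0.8 at p < 0.05, GA mutation rate 5% with zero-to-one rate 19,
#' 500 generations with 5% elitism, 50% core frequency cutoff, and 1000
#' permutations per significance test.
#'
#' @param fc_threshold DE fold-change cutoff (linear scale).
#' @param fdr_threshold DE FDR cutoff.
#' @param fpkm_threshold median-abundance expression threshold.
#' @param radius candidate expansion radius.
#' @param top_k_lnc top lncRNA targets kept.
#' @param score_threshold,p_threshold driver-score filter.
#' @param cutoff core frequency cutoff.
#' @param n_perm permutations per significance test.
#' @param ga list of [ga_config()] overrides.
#' @param sim list of [simulation_config()] overrides for the simulate
#'   stage.
#' @return A list of class `PipelineConfig`.
#' @export
pipeline_config <- function(fc_threshold = 2, fdr_threshold = 0.05,
                            fpkm_threshold = 1.0, radius = 3,
                            top_k_lnc = 200, score_threshold = 0.8,
                            p_threshold = 0.05, cutoff = 0.5,
                            n_perm = 1000, ga = list(), sim = list()) {
  structure(list(fc_threshold = fc_threshold, fdr_threshold = fdr_threshold,
                 fpkm_threshold = fpkm_threshold, radius = radius,
                 top_k_lnc = top_k_lnc, score_threshold = score_threshold,
                 p_threshold = p_threshold, cutoff = cutoff,
                 n_perm = n_perm, ga = ga, sim = sim),
            class = "PipelineConfig")
}

.config_header <- function(stage, config, seed) {
  flat <- config[!names(config) %in% c("ga", "sim")]
  extra <- c(
    if (length(config$ga)) sprintf("ga.%s=%s", names(config$ga),
                                   vapply(config$ga, format, character(1))),
    if (length(config$sim)) sprintf("sim.%s=%s", names(config$sim),
                                    vapply(config$sim, format, character(1))))
  sprintf("# subnetGA stage=%s seed=%d %s", stage, seed,
          paste(c(sprintf("%s=%s", names(flat),
                          vapply(flat, format, character(1))), extra),
                collapse = " "))
}

.write_stage_tsv <- function(df, path, header_line) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_line, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.need_artifact <- function(path, stage) {
  if (!file.exists(path))
    stop("missing artifact '", basename(path), "'; run stage '", stage,
         "' first")
  path
}

#' Find seed genes (in-memory gene-selection stage)
#'
#' Expression filtering by raw count (when counts are present), then
#' differential expression and selection of case-specific genes. With a
#' three-class design (an `intermediate` class present) seeds must pass
#' |FC| and FDR thresholds in both the case-vs-intermediate and the
#' case-vs-control comparison; with two classes a single comparison is
#' used.
#'
#' @param expr an `ExpressionMatrix`.
#' @param labels a `PhenotypeLabels`.
#' @param config a `PipelineConfig`.
#' @return List: `seeds` (data.frame gene, direction), `de` (named list of
#'   DE tables).
#' @export
find_seed_genes <- function(expr, labels, config = pipeline_config()) {
  if (!is.null(expr$raw_counts)) expr <- filter_unexpressed_by_count(expr)
  ctrl <- labels$comparison[1]; case <- labels$comparison[2]
  other <- setdiff(unique(labels$classes), c(ctrl, case))
  if (length(other) >= 1) {
    mid <- other[1]
    de_mid <- differential_expression(
      expr, phenotype_labels(labels$classes, c(mid, case)))
    de_ctrl <- differential_expression(expr, labels)
    seeds <- select_invasive_specific(de_mid, de_ctrl,
                                      config$fc_threshold, config$fdr_threshold)
    de <- list(case_vs_intermediate = de_mid, case_vs_control = de_ctrl)
  } else {
    de_ctrl <- differential_expression(expr, labels)
    lfc <- log2(config$fc_threshold)
    pass <- abs(de_ctrl$log2_fc) > lfc & de_ctrl$fdr < config$fdr_threshold
    seeds <- data.frame(gene = de_ctrl$gene[pass],
                        direction = ifelse(de_ctrl$log2_fc[pass] > 0,
                                           "up", "down"),
                        stringsAsFactors = FALSE)
    seeds <- seeds[order(seeds$gene), , drop = FALSE]
    rownames(seeds) <- NULL
    de <- list(case_vs_control = de_ctrl)
  }
  list(seeds = seeds, de = de)
}

#' Search optimal subnetworks for a set of seed genes
#'
#' For every seed: build the candidate set by bounded-radius expansion,
#' run the elitist GA, and collect all equally optimal member sets from
#' the final population. Seeds with no interaction partners yield the
#' seed-only subnetwork directly.
#'
#' @param seeds character vector of seed gene ids.
#' @param graph an `InteractionGraph`.
#' @param expr an `ExpressionMatrix`.
#' @param labels a `PhenotypeLabels`.
#' @param config a `PipelineConfig`.
#' @param seed integer seed; each seed gene's GA run gets a derived seed.
#' @return Named list per seed gene: list(candidate_set, ga, optima).
#' @export
search_subnetworks <- function(seeds, graph, expr, labels,
                               config = pipeline_config(), seed = 1) {
  expressed <- filter_unexpressed_by_fpkm(expr, config$fpkm_threshold)
  drop <- setdiff(seeds, expressed)
  if (length(drop)) {
    warning(length(drop), " seed(s) below the expression threshold skipped: ",
            paste(utils::head(drop, 5), collapse = ", "))
    seeds <- intersect(seeds, expressed)
  }
  out <- lapply(seq_along(seeds), function(i) {
    sg <- seeds[i]
    cs <- build_candidate_set(graph, expr, sg, radius = config$radius,
                              fpkm_threshold = config$fpkm_threshold,
                              top_k_lnc = config$top_k_lnc,
                              rng_seed = seed + 7L * i)
    ga_cfg <- do.call(ga_config,
                      utils::modifyList(list(rng_seed = seed + 7L * i + 1L),
                                        config$ga))
    res <- evolve(cs, expr, labels, ga_cfg)
    list(candidate_set = cs, ga = res, optima = collect_optima(res))
  })
  stats::setNames(out, seeds)
}

#' Extract and test core subnetworks for all seeds
#'
#' Applies the driver filter, the frequency vote and both permutation
#' tests to each seed's optimal subnetworks; seeds whose subnetworks
#' contain no putative driver produce no core.
#'
#' @param searches result of [search_subnetworks()].
#' @param expr an `ExpressionMatrix`.
#' @param labels a `PhenotypeLabels`.
#' @param graph an `InteractionGraph`.
#' @param driver_genes character vector from [filter_drivers()].
#' @param config a `PipelineConfig`.
#' @param seed integer seed for the permutation tests.
#' @return List of tested `CoreSubnetwork` objects (seeds without a core
#'   are dropped).
#' @export
extract_cores <- function(searches, expr, labels, graph, driver_genes,
                          config = pipeline_config(), seed = 1) {
  universe <- filter_unexpressed_by_fpkm(expr, config$fpkm_threshold)
  cores <- lapply(seq_along(searches), function(i) {
    extract_core(searches[[i]]$optima, names(searches)[i], expr, labels,
                 graph, driver_genes, gene_universe = universe,
                 cutoff = config$cutoff, n_perm = config$n_perm,
                 rng_seed = seed + 13L * i)
  })
  Filter(Negate(is.null), cores)
}

#' Run one pipeline stage (file-based orchestration)
#'
#' Stages communicate through TSV artifacts in `out_dir`, so externally
#' produced tables (e.g. a DE table from a count-based fit, or a
#' driver-score table from a mutation annotator) can be dropped in at the
#' documented interfaces. Every artifact carries a `#` header echoing the
#' stage, configuration and seed. `run-all` chains
#' simulate, select-genes, candidates, ga, core, significance.
#'
#' @param command one of `simulate`, `select-genes`, `candidates`, `ga`,
#'   `core`, `significance`, `run-all`.
#' @param out_dir artifact directory (created if missing).
#' @param config a `PipelineConfig`.
#' @param seed integer master seed for all randomness.
#' @return Invisibly, the stage's main result object.
#' @export
run_stage <- function(command = c("run-all", "simulate", "select-genes",
                                  "candidates", "ga", "core", "significance"),
                      out_dir, config = pipeline_config(), seed = 1) {
  command <- match.arg(command)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  t0 <- Sys.time()
  res <- switch(command,
    "simulate" = .stage_simulate(out_dir, config, seed),
    "select-genes" = .stage_select_genes(out_dir, config, seed),
    "candidates" = .stage_candidates(out_dir, config, seed),
    "ga" = .stage_ga(out_dir, config, seed),
    "core" = .stage_core(out_dir, config, seed),
    "significance" = .stage_significance(out_dir, config, seed),
    "run-all" = {
      for (st in c("simulate", "select-genes", "candidates", "ga", "core"))
        run_stage(st, out_dir, config, seed)
      run_stage("significance", out_dir, config, seed)
    })
  message(sprintf("[subnetGA] stage %s finished in %.1fs", command,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(res)
}

.stage_simulate <- function(out_dir, config, seed) {
  sim_cfg <- do.call(simulation_config,
                     utils::modifyList(list(rng_seed = seed), config$sim))
  ds <- generate_dataset(sim_cfg)
  write_expression(ds$expr, file.path(out_dir, "expression.tsv"))
  write_expression(ds$expr, file.path(out_dir, "raw_counts.tsv"), "raw_counts")
  write_labels(ds$labels, file.path(out_dir, "labels.tsv"))
  write_graph_edges(ds$graph, file.path(out_dir, "graph.tsv"))
  write_drivers(ds$drivers, file.path(out_dir, "drivers.tsv"))
  write_truth(ds$truth, ds$drivers, file.path(out_dir, "truth.tsv"))
  ds
}

.read_inputs <- function(out_dir) {
  list(expr = read_expression(
         .need_artifact(file.path(out_dir, "expression.tsv"), "simulate"),
         if (file.exists(file.path(out_dir, "raw_counts.tsv")))
           file.path(out_dir, "raw_counts.tsv")),
       labels = read_labels(
         .need_artifact(file.path(out_dir, "labels.tsv"), "simulate"),
         comparison = c("control", "case")),
       graph = read_graph(
         .need_artifact(file.path(out_dir, "graph.tsv"), "simulate")),
       drivers = read_drivers(
         .need_artifact(file.path(out_dir, "drivers.tsv"), "simulate")))
}

.stage_select_genes <- function(out_dir, config, seed) {
  inp <- .read_inputs(out_dir)
  sel <- find_seed_genes(inp$expr, inp$labels, config)
  hdr <- .config_header("select-genes", config, seed)
  for (nm in names(sel$de))
    .write_stage_tsv(sel$de[[nm]], file.path(out_dir, paste0("de_", nm, ".tsv")), hdr)
  .write_stage_tsv(sel$seeds, file.path(out_dir, "seeds.tsv"), hdr)
  sel
}

.read_seeds <- function(out_dir) {
  path <- .need_artifact(file.path(out_dir, "seeds.tsv"), "select-genes")
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = "character")
  df$gene
}

.stage_candidates <- function(out_dir, config, seed) {
  inp <- .read_inputs(out_dir)
  seeds <- .read_seeds(out_dir)
  sets <- lapply(seq_along(seeds), function(i)
    build_candidate_set(inp$graph, inp$expr, seeds[i], radius = config$radius,
                        fpkm_threshold = config$fpkm_threshold,
                        top_k_lnc = config$top_k_lnc,
                        rng_seed = seed + 7L * i))
  con <- file(file.path(out_dir, "candidates.tsv"), "w")
  writeLines(.config_header("candidates", config, seed), con)
  close(con)
  tmp <- tempfile(); on.exit(unlink(tmp))
  write_candidate_sets(sets, tmp)
  file.append(file.path(out_dir, "candidates.tsv"), tmp)
  stats::setNames(sets, seeds)
}

.stage_ga <- function(out_dir, config, seed) {
  inp <- .read_inputs(out_dir)
  seeds <- .read_seeds(out_dir)
  sets <- read_candidate_sets(
    .need_artifact(file.path(out_dir, "candidates.tsv"), "candidates"),
    seeds = seeds)
  rows <- list()
  for (i in seq_along(seeds)) {
    sg <- seeds[i]
    ga_cfg <- do.call(ga_config,
                      utils::modifyList(list(rng_seed = seed + 7L * i + 1L),
                                        config$ga))
    res <- evolve(sets[[sg]], inp$expr, inp$labels, ga_cfg)
    write_ga_log(res, file.path(out_dir, paste0("ga_log_", .safe_name(sg), ".tsv")))
    optima <- collect_optima(res)
    rows[[i]] <- do.call(rbind, lapply(seq_along(optima), function(j)
      data.frame(seed = sg, optimum_id = j, gene = optima[[j]],
                 fitness = min(res$fitness), stringsAsFactors = FALSE)))
  }
  df <- do.call(rbind, rows)
  .write_stage_tsv(df, file.path(out_dir, "ga_optima.tsv"),
                   .config_header("ga", config, seed))
  df
}

.read_optima <- function(out_dir) {
  path <- .need_artifact(file.path(out_dir, "ga_optima.tsv"), "ga")
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#")
  df$seed <- as.character(df$seed); df$gene <- as.character(df$gene)
  lapply(split(df, df$seed), function(sub)
    unname(lapply(split(sub$gene, sub$optimum_id), sort)))
}

.stage_core <- function(out_dir, config, seed) {
  inp <- .read_inputs(out_dir)
  optima_by_seed <- .read_optima(out_dir)
  driver_genes <- filter_drivers(inp$drivers, config$score_threshold,
                                 config$p_threshold)
  rows <- list()
  for (sg in names(optima_by_seed)) {
    kept <- require_driver(optima_by_seed[[sg]], driver_genes)
    if (!length(kept)) next
    core <- build_core(gene_frequency(kept), sg, inp$graph, driver_genes,
                       config$cutoff)
    if (is.null(core)) next
    rows[[sg]] <- data.frame(seed = sg, gene = core$members,
                             is_driver = core$members %in% driver_genes,
                             stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(seed = character(0), gene = character(0),
                        is_driver = logical(0))
  .write_stage_tsv(df, file.path(out_dir, "core_members.tsv"),
                   .config_header("core", config, seed))
  df
}

.stage_significance <- function(out_dir, config, seed) {
  inp <- .read_inputs(out_dir)
  path <- .need_artifact(file.path(out_dir, "core_members.tsv"), "core")
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = c("character", "character", "logical"))
  driver_genes <- filter_drivers(inp$drivers, config$score_threshold,
                                 config$p_threshold)
  universe <- filter_unexpressed_by_fpkm(inp$expr, config$fpkm_threshold)
  optima_by_seed <- .read_optima(out_dir)
  cores <- list()
  i <- 0L
  for (sg in unique(df$seed)) {
    i <- i + 1L
    members <- sort(df$gene[df$seed == sg])
    core <- structure(list(seed = sg, members = members,
                           drivers = sort(intersect(members, driver_genes)),
                           fitness = NA_real_, p_label_perm = NA_real_,
                           p_random_members = NA_real_,
                           edges = induced_edges(inp$graph, members)),
                      class = "CoreSubnetwork")
    cfg <- ga_config(rng_seed = seed)
    core$fitness <- fitness(members, inp$expr, inp$labels, cfg)
    core$p_label_perm <- suppressMessages(label_permutation_test(
      core, inp$expr, inp$labels, config$n_perm, seed + 13L * i))
    core$p_random_members <- random_members_test(
      core, inp$expr, inp$labels, universe, config$n_perm, seed + 13L * i + 1L)
    core$n_optima <- length(optima_by_seed[[sg]])
    cores[[sg]] <- core
  }
  if (length(cores)) write_subnetworks(unname(cores), out_dir)
  report <- if (length(cores)) data.frame(
    seed = vapply(cores, `[[`, character(1), "seed"),
    core_size = vapply(cores, function(x) length(x$members), integer(1)),
    n_optima = vapply(cores, function(x) x$n_optima, integer(1)),
    fitness = vapply(cores, `[[`, numeric(1), "fitness"),
    p_label_perm = vapply(cores, `[[`, numeric(1), "p_label_perm"),
    p_random_members = vapply(cores, `[[`, numeric(1), "p_random_members"),
    drivers = vapply(cores, function(x) paste(x$drivers, collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE)
  else data.frame(seed = character(0), core_size = integer(0),
                  n_optima = integer(0), fitness = numeric(0),
                  p_label_perm = numeric(0), p_random_members = numeric(0),
                  drivers = character(0))
  rownames(report) <- NULL
  .write_stage_tsv(report, file.path(out_dir, "significance_report.tsv"),
                   .config_header("significance", config, seed))
  list(cores = unname(cores), report = report)
}

#' Run the complete analysis in memory
#'
#' Convenience wrapper over the in-memory stage functions for a dataset
#' already loaded (or generated): gene selection, candidate expansion, GA
#' search, core extraction and significance testing, without file
#' handoff.
#'
#' @param dataset list with `expr`, `labels`, `graph`, `drivers` (as from
#'   [generate_dataset()]).
#' @param config a `PipelineConfig`.
#' @param seed integer master seed.
#' @return List: `seeds`, `searches`, `cores`.
#' @export
analyze_dataset <- function(dataset, config = pipeline_config(), seed = 1) {
  sel <- find_seed_genes(dataset$expr, dataset$labels, config)
  searches <- search_subnetworks(sel$seeds$gene, dataset$graph, dataset$expr,
                                 dataset$labels, config, seed)
  driver_genes <- filter_drivers(dataset$drivers, config$score_threshold,
                                 config$p_threshold)
  cores <- extract_cores(searches, dataset$expr, dataset$labels,
                         dataset$graph, driver_genes, config, seed)
  list(seeds = sel$seeds, searches = searches, cores = cores)
}
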