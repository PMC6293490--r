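test_that("subnetwork activity is the mean of per-gene z-scores", {
  expr <- make_expr(3, 5, c(1, 10, 7,  2, 20, 7,  3, 30, 7,  4, 40, 7,  5, 50, 7))
  # single gene: activity equals its z-scored profile
  a1 <- subnetwork_activity(expr, "G1")
  expect_equal(a1, (expr$values["G1", ] - 3) / sd(expr$values["G1", ]))
  # two genes with identical (z-scored) profiles: same as either alone
  a12 <- subnetwork_activity(expr, c("G1", "G2"))
  expect_equal(a12, a1, tolerance = 1e-12)
  # constant gene contributes zeros and scales the mean: direct oracle
  a13 <- subnetwork_activity(expr, c("G1", "G3"))
  z1 <- (expr$values["G1", ] - mean(expr$values["G1", ])) / sd(expr$values["G1", ])
  expect_equal(a13, (z1 + 0) / 2, tolerance = 1e-12)
  expect_error(subnetwork_activity(expr, character(0)), "nonempty")
  expect_error(subnetwork_activity(expr, "nope"), "not in expression")
})

test_that("discretization uses equal-width bins and the Sturges auto rule", {
  expect_equal(discretize(1:8, 2), rep(0:1, each = 4))
  expect_equal(discretize(rep(3.7, 5), 4), rep(0L, 5))
  # n = 18, auto -> ceil(log2 18) + 1 = 6 bins
  b <- discretize(seq_len(18), "auto")
  expect_equal(length(unique(b)), 6L)
  expect_equal(max(b), 5L)
  expect_error(discretize(1:4, 0), ">= 1")
  expect_error(discretize(c(1, NA), 2), "finite")
})

test_that("mutual information matches the plug-in oracle", {
  # perfectly matched balanced binary variables: exactly 1 bit
  expect_identical(mutual_information(rep(0:1, each = 4),
                                      rep(c("A", "B"), each = 4)), 1)
  # constant bins: 0 bits
  expect_identical(mutual_information(rep(0L, 6), rep(c("A", "B"), 3)), 0)
  # hand-specified joint counts {(0,A):2,(0,B):1,(1,A):1,(1,B):2}
  x <- c(0, 0, 0, 1, 1, 1)
  y <- c("A", "A", "B", "A", "B", "B")
  expect_equal(mutual_information(x, y), mi_oracle(x, y), tolerance = 1e-15)
  expect_equal(mutual_information(x, y),
               2 * (2 / 6) * log2((2 / 6) / (1 / 4)) +
               2 * (1 / 6) * log2((1 / 6) / (1 / 4)),
               tolerance = 1e-15)
  expect_error(mutual_information(1:3, 1:4), "equal length")
})

test_that("fitness equals the negated composition of its parts", {
  inst <- make_planted_instance(71, L = 6, n = 16)
  cfg <- ga_config(rng_seed = 3)
  bits <- c(1L, 0L, 1L, 0L, 0L, 1L)
  chrom <- chromosome(inst$candidate_set, bits)
  members <- chromosome_members(chrom)
  expect_true(inst$candidate_set$seed %in% members)
  act <- subnetwork_activity(inst$expr, members)
  manual <- -mutual_information(discretize(act, "auto"),
                                inst$labels$classes[sample_ids(inst$expr)])
  expect_equal(fitness(chrom, inst$expr, inst$labels, cfg), manual,
               tolerance = 1e-12)
  # bounds: fitness in [-log2(min(bins, classes)), 0]
  expect_gte(fitness(chrom, inst$expr, inst$labels, cfg), -1)
  expect_lte(fitness(chrom, inst$expr, inst$labels, cfg), 0)
})

test_that("vectorized population evaluation matches the public fitness", {
  inst <- make_planted_instance(72, L = 8, n = 20)
  prob <- subnetGA:::.ga_problem(inst$candidate_set, inst$expr, inst$labels,
                                 "auto")
  set.seed(4)
  bits <- matrix(as.integer(runif(10 * 8) < 0.4), 10, 8)
  fast <- subnetGA:::.eval_population(bits, prob)
  slow <- vapply(seq_len(10), function(i)
    fitness(chromosome(inst$candidate_set, bits[i, ]), inst$expr,
            inst$labels, ga_config()), numeric(1))
  expect_equal(fast, slow, tolerance = 1e-12)
})

test_that("population initialization respects the zero-to-one rate", {
  inst <- make_planted_instance(73, L = 10, n = 12)
  cs <- inst$candidate_set
  # synthetic long chromosome for the binomial check
  long <- structure(list(seed = "SEED", genes = sprintf("X%04d", 1:1000),
                         radius_used = 1L,
                         distances = stats::setNames(rep(1L, 1000),
                                                     sprintf("X%04d", 1:1000))),
                    class = "CandidateSet")
  cfg <- ga_config(population_size = 200, zero_to_one_rate = 19, rng_seed = 8)
  pop <- init_population(long, cfg)
  ones <- sum(pop)
  n_bits <- length(pop)
  # binomial 99% bounds around p = 0.05
  bounds <- qbinom(c(0.005, 0.995), n_bits, 0.05)
  expect_gte(ones, bounds[1])
  expect_lte(ones, bounds[2])
  # determinism
  expect_identical(pop, init_population(long, cfg))
  # zero_to_one_rate -> infinity limit: all-zero chromosomes
  pop0 <- init_population(long, ga_config(zero_to_one_rate = 1e12, rng_seed = 8))
  expect_equal(sum(pop0), 0L)
  expect_error(init_population(
    structure(list(seed = "s", genes = character(0), radius_used = 1L,
                   distances = integer(0)), class = "CandidateSet"), cfg),
    "empty")
})

test_that("evolution is elitist: best fitness never increases", {
  inst <- make_planted_instance(74)
  res <- evolve(inst$candidate_set, inst$expr, inst$labels,
                ga_config(population_size = 60, generations = 40,
                          elite_fraction = 0.1, rng_seed = 9))
  expect_true(all(diff(res$trajectory$best_fitness) <= 0))
  expect_equal(min(res$fitness), res$best_fitness)
  expect_equal(utils::tail(res$trajectory$best_fitness, 1), res$best_fitness)
})

test_that("seeded runs are bit-reproducible", {
  inst <- make_planted_instance(75)
  cfg <- ga_config(population_size = 50, generations = 20, rng_seed = 77)
  r1 <- evolve(inst$candidate_set, inst$expr, inst$labels, cfg)
  r2 <- evolve(inst$candidate_set, inst$expr, inst$labels, cfg)
  expect_identical(r1$population, r2$population)
  expect_identical(r1$trajectory, r2$trajectory)
})

test_that("a population of identical chromosomes is invariant without mutation", {
  inst <- make_planted_instance(76, L = 6)
  cfg <- ga_config(population_size = 40, generations = 10, mutation_rate = 0,
                   zero_to_one_rate = 1e12, local_search = FALSE, rng_seed = 1)
  # zero_to_one_rate -> infinity gives an all-zero initial population;
  # crossover of identical parents is the identity and mutation is off
  res <- evolve(inst$candidate_set, inst$expr, inst$labels, cfg)
  expect_true(all(res$population == 0L))
})

test_that("empty candidate sets degenerate to the seed-only subnetwork", {
  inst <- make_planted_instance(77, L = 5)
  lonely <- structure(list(seed = "SEED", genes = character(0),
                           radius_used = 3L, distances = integer(0)),
                      class = "CandidateSet")
  res <- evolve(lonely, inst$expr, inst$labels, ga_config(rng_seed = 2))
  expect_equal(nrow(res$population), 1L)
  expect_equal(res$best_fitness,
               fitness("SEED", inst$expr, inst$labels, ga_config()))
  expect_equal(collect_optima(res), list("SEED"))
})

test_that("collect_optima deduplicates member sets at the minimum", {
  inst <- make_planted_instance(78, L = 4)
  cs <- inst$candidate_set
  fake <- structure(list(
    population = rbind(c(1L, 0L, 0L, 0L), c(1L, 0L, 0L, 0L),
                       c(0L, 1L, 0L, 0L), c(0L, 0L, 1L, 1L)),
    fitness = c(-0.9, -0.9, -0.9, -0.2),
    best_fitness = -0.9, candidate_set = cs, config = ga_config()),
    class = "ga_result")
  opt <- collect_optima(fake)
  expect_length(opt, 2L)  # duplicate bit rows collapse, -0.2 excluded
  expect_true(all(vapply(opt, function(s) "SEED" %in% s, logical(1))))
})

test_that("the GA recovers a planted module's genes across restarts", {
  # one strongly discriminative pair among noise candidates
  hits <- 0
  n_restarts <- 10
  inst <- make_planted_instance(79, L = 10, n = 40, shift = 3)
  for (r in seq_len(n_restarts)) {
    res <- evolve(inst$candidate_set, inst$expr, inst$labels,
                  ga_config(population_size = 60, generations = 60,
                            rng_seed = 500 + r))
    best_members <- collect_optima(res)[[1]]
    if (all(inst$signal %in% best_members)) hits <- hits + 1
  }
  expect_gte(hits / n_restarts, 0.9)
})

test_that("GA run logs carry the configuration header", {
  inst <- make_planted_instance(80, L = 5)
  res <- evolve(inst$candidate_set, inst$expr, inst$labels,
                ga_config(population_size = 40, generations = 5, rng_seed = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ga_log(res, path)
  lines <- readLines(path)
  expect_true(any(grepl("zero_to_one_rate=19", lines)))
  log <- read.delim(path, comment.char = "#")
  expect_equal(nrow(log), 6L)  # generations 0..5
  expect_named(log, c("generation", "best_fitness", "mean_fitness",
                      "elite_size"))
})

test_that("GA config invariants are enforced", {
  expect_error(ga_config(elite_fraction = 0), "strictly between")
  expect_error(ga_config(population_size = 10, elite_fraction = 0.05),
               "2/elite_fraction")
  expect_error(ga_config(zero_to_one_rate = 0), ">= 1")
})
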