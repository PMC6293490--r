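test_that("driver filter on subnetworks keeps only driver-containing sets", {
  subs <- list(c("s", "a", "b"), c("s", "c"), c("s", "d", "e"))
  expect_equal(require_driver(subs, "d"), list(c("s", "d", "e")))
  expect_equal(require_driver(subs, character(0)), list())
  expect_equal(require_driver(subs, c("a", "c", "d")), subs)
})

test_that("gene frequencies are fractions of subnetworks", {
  subs <- list(c("s", "a"), c("s", "a", "b"), c("s", "b"), c("s", "c"))
  freq <- gene_frequency(subs)
  expect_equal(unname(freq["a"]), 0.5)
  expect_equal(unname(freq["s"]), 1.0)
  expect_equal(unname(freq["c"]), 0.25)
  expect_equal(gene_frequency(list(c("x", "y"))), c(x = 1, y = 1))
  expect_error(gene_frequency(list()), "nonempty")
})

test_that("core building applies an inclusive frequency cutoff", {
  g <- star_graph("s", c("A", "B", "C"))
  freq <- c(A = 1.0, B = 0.5, C = 0.25)
  core <- build_core(freq, seed = "s", graph = g, drivers = "A")
  expect_equal(core$members, c("A", "B", "s"))  # C below, B at boundary kept
  expect_equal(core$drivers, "A")
  # no driver among members -> no core
  expect_null(build_core(freq, seed = "s", graph = g, drivers = "C"))
  # monotone in cutoff: raising it never adds members
  sizes <- vapply(c(0.2, 0.5, 0.8, 1.0), function(ct) {
    core <- build_core(freq, seed = "s", graph = g, drivers = "A",
                       cutoff = ct)
    if (is.null(core)) 0L else length(core$members)
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("label permutation p-value hits the floor on a planted core", {
  inst <- make_planted_instance(91, L = 8, n = 20, shift = 4)
  g <- inst$graph
  members <- sort(c("SEED", inst$signal))
  core <- build_core(stats::setNames(rep(1, length(members)), members),
                     seed = "SEED", graph = g, drivers = inst$signal[1])
  p <- label_permutation_test(core, inst$expr, inst$labels, n_perm = 200,
                              rng_seed = 4)
  expect_equal(p, 1 / 201)
  expect_error(label_permutation_test(core, inst$expr, inst$labels,
                                      n_perm = 0), ">= 1")
})

test_that("permutation tests are deterministic and never return 0", {
  inst <- make_planted_instance(92, L = 8, n = 16, shift = 0)
  members <- c("SEED", inst$candidate_set$genes[1:3])
  core <- build_core(stats::setNames(rep(1, 4), members), seed = "SEED",
                     graph = inst$graph, drivers = members)
  p1 <- label_permutation_test(core, inst$expr, inst$labels, 99, rng_seed = 5)
  p2 <- label_permutation_test(core, inst$expr, inst$labels, 99, rng_seed = 5)
  expect_identical(p1, p2)
  expect_gte(p1, 1 / 100)
  q1 <- random_members_test(core, inst$expr, inst$labels,
                            gene_ids(inst$expr), 99, rng_seed = 5)
  q2 <- random_members_test(core, inst$expr, inst$labels,
                            gene_ids(inst$expr), 99, rng_seed = 5)
  expect_identical(q1, q2)
  expect_gte(q1, 1 / 100)
  expect_lte(q1, 1)
})

test_that("tiny designs fall back to exhaustive label enumeration", {
  inst <- make_planted_instance(93, L = 5, n = 8, shift = 2)
  members <- c("SEED", inst$candidate_set$genes[1])
  core <- build_core(stats::setNames(c(1, 1), members), seed = "SEED",
                     graph = inst$graph, drivers = members)
  # choose(8, 4) = 70 < 1000 -> exhaustive, message emitted
  expect_message(
    p <- label_permutation_test(core, inst$expr, inst$labels, n_perm = 1000,
                                rng_seed = 1),
    "enumerating")
  expect_gte(p, 1 / 71)
})

test_that("random-members null rejects a universe smaller than the core", {
  inst <- make_planted_instance(94, L = 5)
  members <- c("SEED", inst$candidate_set$genes)
  core <- build_core(stats::setNames(rep(1, 6), members), seed = "SEED",
                     graph = inst$graph, drivers = members)
  expect_error(random_members_test(core, inst$expr, inst$labels,
                                   members, 99), "larger than the core")
})

test_that("a strongly discriminative set scores near the p-value floor", {
  inst <- make_planted_instance(95, L = 40, n = 40, shift = 4)
  members <- sort(c("SEED", inst$signal))
  core <- build_core(stats::setNames(rep(1, length(members)), members),
                     seed = "SEED", graph = inst$graph, drivers = inst$signal)
  # random same-size sets from the 41-gene noise universe only rarely tie
  # the planted set's perfect separation
  p <- random_members_test(core, inst$expr, inst$labels,
                           gene_ids(inst$expr), n_perm = 200, rng_seed = 6)
  expect_lte(p, 0.05)
})

test_that("extract_core chains filter, vote and both tests", {
  inst <- make_planted_instance(96, L = 8, n = 20, shift = 3)
  filler <- setdiff(inst$candidate_set$genes, inst$signal)[1:2]
  optima <- list(sort(c("SEED", inst$signal)),
                 sort(c("SEED", inst$signal, filler[2])),
                 sort(c("SEED", inst$signal, filler[1])))
  core <- extract_core(optima, "SEED", inst$expr, inst$labels, inst$graph,
                       drivers = inst$signal[1],
                       gene_universe = gene_ids(inst$expr),
                       n_perm = 99, rng_seed = 3)
  expect_s3_class(core, "CoreSubnetwork")
  expect_true(all(inst$signal %in% core$members))
  expect_false(filler[1] %in% core$members)  # frequency 1/3 below cutoff
  expect_true(is.finite(core$fitness))
  expect_gte(core$p_label_perm, 1 / 100)
  expect_gte(core$p_random_members, 1 / 100)
  # driver-free optima produce no core
  expect_null(extract_core(optima, "SEED", inst$expr, inst$labels,
                           inst$graph, drivers = "ZZZ",
                           gene_universe = gene_ids(inst$expr), n_perm = 9,
                           rng_seed = 3))
})
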