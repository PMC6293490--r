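test_that("bounded neighborhood on a path graph respects the radius", {
  g <- path_graph(c("a", "b", "c", "d", "e"))
  expect_equal(bounded_neighborhood(g, "a", 3), c("b", "c", "d"))
  expect_equal(bounded_neighborhood(g, "a", 1), "b")
  d <- bounded_neighborhood_distances(g, "a", 3)
  expect_equal(unname(d), c(1L, 2L, 3L))
})

test_that("isolated or absent seeds give an empty neighborhood", {
  g <- interaction_graph(data.frame(u = "a", v = "b", kind = "ppi"),
                         node_kinds = c(a = "coding", b = "coding",
                                        lonely = "coding"))
  expect_length(bounded_neighborhood(g, "lonely", 3), 0L)
  expect_length(bounded_neighborhood(g, "not_in_graph", 3), 0L)
  expect_error(bounded_neighborhood(g, "a", 0), "radius")
})

test_that("star center reaches all leaves at radius 1 and edges traverse both ways", {
  leaves <- sprintf("L%d", 1:5)
  g <- star_graph("hub", leaves)
  expect_equal(bounded_neighborhood(g, "hub", 1), leaves)
  # directed tf_target edges are traversable against their direction
  g2 <- interaction_graph(data.frame(u = c("T", "T"), v = c("x", "y"),
                                     kind = "tf_target"))
  expect_equal(bounded_neighborhood(g2, "x", 2), c("T", "y"))
})

test_that("neighborhoods nest with radius and shrink when edges are removed", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 30
    nodes <- sprintf("N%02d", 1:n)
    edges <- data.frame(u = sample(nodes, 60, TRUE),
                        v = sample(nodes, 60, TRUE), kind = "ppi")
    edges <- edges[edges$u != edges$v, ]
    g <- interaction_graph(edges)
    seed_gene <- g$nodes$gene[1]
    prev <- character(0)
    for (r in 1:4) {
      cur <- bounded_neighborhood(g, seed_gene, r)
      expect_true(all(prev %in% cur))
      prev <- cur
    }
    # dropping an edge never enlarges the ball
    g_small <- interaction_graph(g$edges[-1, , drop = FALSE])
    if (seed_gene %in% g_small$nodes$gene) {
      cur_small <- bounded_neighborhood(g_small, seed_gene, 3)
      expect_true(all(cur_small %in% bounded_neighborhood(g, seed_gene, 3)))
    }
  }
})

test_that("candidate sets exclude the seed, filter expression, sort genes", {
  chain <- sprintf("g%d", 1:6)
  g <- path_graph(chain)
  vals <- make_values(6, 3, rep(5, 18))
  rownames(vals) <- chain
  expr <- expression_matrix(vals)
  cs <- build_candidate_set(g, expr, "g1", radius = 3)
  expect_s3_class(cs, "CandidateSet")
  expect_equal(cs$genes, c("g2", "g3", "g4"))
  expect_false(cs$seed %in% cs$genes)

  # unexpressed intermediate gene is removed from the set but does not
  # block traversal
  vals2 <- vals; vals2["g2", ] <- 0.1
  cs2 <- build_candidate_set(g, expression_matrix(vals2), "g1", radius = 3)
  expect_equal(cs2$genes, c("g3", "g4"))

  # unexpressed seed is an error pointing at the filter
  expect_error(build_candidate_set(g, expression_matrix(vals2), "g2"),
               "FPKM")
})

test_that("candidate sets cache to TSV and back", {
  g <- path_graph(sprintf("g%d", 1:5))
  expr <- expression_matrix(
    matrix(5, 5, 3, dimnames = list(sprintf("g%d", 1:5), sprintf("S%d", 1:3))))
  sets <- lapply(c("g1", "g3"), function(s)
    build_candidate_set(g, expr, s, radius = 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_candidate_sets(sets, path)
  back <- read_candidate_sets(path)
  expect_equal(back[["g1"]]$genes, sets[[1]]$genes)
  expect_equal(back[["g3"]]$distances, sets[[2]]$distances)
})

test_that("lncRNA target ranking puts an exact linear target first", {
  set.seed(31)
  n <- 40
  lnc <- rnorm(n, 5, 2)
  vals <- rbind(LNC1 = 2^lnc,
                TGT = 2^(2 * lnc + 1),              # exact function of the lncRNA
                make_values(10, n, 2^rnorm(10 * n, 5, 2)))
  colnames(vals) <- sprintf("S%02d", 1:n)
  expr <- expression_matrix(vals)
  ranked <- rank_lncrna_targets(expr, "LNC1", setdiff(rownames(vals), "LNC1"),
                                top_k = 5, rng_seed = 1, n_coregulators = 5,
                                num_trees = 50)
  expect_equal(ranked[1], "TGT")
})

test_that("lncRNA ranking truncates, is deterministic, rejects constant lncRNA", {
  set.seed(32)
  vals <- make_values(8, 20, 2^rnorm(160, 4, 1))
  vals <- rbind(vals, LNC = 2^rnorm(20, 4, 1))
  expr <- expression_matrix(vals)
  targets <- sprintf("G%d", 1:8)
  r1 <- rank_lncrna_targets(expr, "LNC", targets, top_k = 200, rng_seed = 5,
                            n_coregulators = 4, num_trees = 30)
  expect_length(r1, 8L)  # top_k larger than available
  r2 <- rank_lncrna_targets(expr, "LNC", targets, top_k = 200, rng_seed = 5,
                            n_coregulators = 4, num_trees = 30)
  expect_identical(r1, r2)
  const <- vals; const["LNC", ] <- 3
  expect_error(
    rank_lncrna_targets(expression_matrix(const), "LNC", targets),
    "constant")
})

test_that("lncRNA seeds expand from their ranked targets", {
  # LNC -> targets by expression; T1 touches deeper genes through ppi
  set.seed(33)
  n <- 30
  lnc <- rnorm(n, 5, 1)
  vals <- rbind(LNC = 2^lnc, T1 = 2^(lnc + rnorm(n, 0, 0.1)),
                DEEP = 2^rnorm(n, 5, 1), FAR = 2^rnorm(n, 5, 1))
  colnames(vals) <- sprintf("S%02d", 1:n)
  expr <- expression_matrix(vals)
  g <- interaction_graph(
    data.frame(u = c("T1", "DEEP"), v = c("DEEP", "FAR"), kind = "ppi"),
    node_kinds = c(LNC = "lncrna", T1 = "coding", DEEP = "coding",
                   FAR = "coding"))
  cs <- build_candidate_set(g, expr, "LNC", radius = 3, top_k_lnc = 1,
                            rng_seed = 2)
  expect_equal(cs$genes, c("DEEP", "FAR", "T1"))  # T1 ranked, rest by ppi
  cs1 <- build_candidate_set(g, expr, "LNC", radius = 3, top_k_lnc = 1,
                             rng_seed = 2, expand_lnc_targets = FALSE)
  expect_equal(cs1$genes, "T1")
})
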