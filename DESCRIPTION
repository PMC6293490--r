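Package: subnetGA
Title: Phenotype-Discriminative Gene Subnetwork Search by Genetic Algorithm
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers gene subnetworks that discriminate sample phenotypes by
    combining heterogeneous molecular interactions (protein-protein,
    transcription factor to target, and lncRNA to target edges) with gene
    expression. Starting from seed genes, candidate gene sets are built by
    bounded-radius expansion over the interaction graph, an elitist binary
    genetic algorithm searches for gene subsets whose discretized
    subnetwork activity maximizes mutual information with the phenotype,
    core subnetworks are extracted by a driver-gene filter and a
    gene-frequency vote across equally optimal solutions, and empirical
    significance is assessed with label-permutation and random-membership
    nulls. Includes a synthetic-data generator with planted discriminative
    modules for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
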