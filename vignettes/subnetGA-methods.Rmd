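---
title: "subnetGA: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{subnetGA: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subnetGA)
```

## The problem

Genes act in pathways, and the expression change that separates two
phenotypes (for example pre-invasive versus invasive tumour tissue) is often
carried by a *group* of interacting genes rather than by single markers.
subnetGA searches, for each *seed gene* (typically a phenotype-specific
differentially expressed gene), for the subset of its interaction
neighbourhood whose joint expression best discriminates the two phenotype
classes, and then distils the many near-optimal subsets into a single *core
subnetwork* anchored by putative driver genes.

The pipeline has five stages, each exposed as ordinary R functions and as a
file-based stage runner (`run_stage()`):

1. **Gene selection** — expression filtering and differential expression,
   yielding seed genes and (separately) a driver-gene call from a supplied
   per-gene score table.
2. **Candidate expansion** — a bounded-radius ball around each seed in a
   typed interaction graph.
3. **GA search** — an elitist binary genetic algorithm over the candidate
   set, minimizing a mutual-information fitness.
4. **Core extraction** — driver filter plus gene-frequency vote across all
   equally optimal subnetworks.
5. **Significance** — two permutation nulls per core.

## Data model

* **Expression**: a genes × samples matrix of non-negative FPKM-like
  abundances, optionally with an aligned raw-count matrix. Genes with
  median raw count 0 (or median abundance < 1 when only abundances exist)
  are treated as unexpressed.
* **Interaction graph**: typed nodes (`coding`, `tf`, `lncrna`) and typed
  edges — undirected protein–protein (`ppi`) edges, directed
  transcription-factor→target (`tf_target`) and lncRNA→target
  (`lnc_target`) edges. For *neighbourhood expansion* every edge kind is
  traversed in both directions; a regulator upstream of a seed is as
  relevant a candidate as a target downstream, and the directed kinds only
  record provenance. This maximizes candidate recall and reproduces the
  situation where the outermost shell of a radius-3 ball covers most of the
  coding genome.
* **Driver table**: per-gene functional-impact scores in [0, 1] with an
  empirical p-value; a gene is a putative driver when score > 0.8 and
  p < 0.05 (strict inequalities; the score boundary is configurable to
  `>=` because published descriptions of such filters vary on this point).

## Seed-gene selection

Differential expression is deliberately pluggable. The built-in test is a
Welch t-test on `log2(x + 1)` with Benjamini–Hochberg correction per
comparison and fold changes computed as
`log2((mean_case + 1) / (mean_control + 1))`; a count-based fit (e.g. a
negative-binomial model) can be substituted by writing its table to the
documented TSV contract (gene, log2_fc, p_value, fdr) and dropping it into
the stage directory. With a three-class design (control / intermediate /
case) a seed must pass |FC| > 2 and FDR < 0.05 in *both* the
case-vs-intermediate and the case-vs-control comparison; genes significant
in both but with opposite signs are dropped with a warning, since a
consistent direction is what makes the up/down annotation meaningful.

## The GA and its fitness

A candidate solution is a bit vector over the seed's candidate genes; the
seed itself is always a member and has no bit. The fitness of a member set
$S$ is

$$f(S) \;=\; -\,I\!\left(\,\mathrm{disc}\!\left(\tfrac{1}{|S|}\sum_{g \in S} z_g\right);\; Y\right)$$

where $z_g$ is the gene's z-scored expression across the comparison
samples, $\mathrm{disc}$ is equal-width binning with
$\lceil \log_2 n\rceil + 1$ bins (Sturges), $Y$ is the binary phenotype and
$I(\cdot;\cdot)$ is plug-in mutual information in bits. The GA *minimizes*
$f$, so $f \in [-\log_2(\min(\text{bins}, \text{classes})),\, 0]$ and $-1$
means perfect separation of balanced classes. Averaging z-scores before the
MI is one of several reasonable aggregation rules (the alternative, summing
per-gene MI contributions, ignores gene interactions); it is deterministic,
standard in discriminative-subnetwork work, and isolated behind
`subnetwork_activity()` so it can be replaced.

Per generation:

* all chromosomes are evaluated (one matrix product for the activities);
* the top 5% by ascending fitness are copied unchanged — ties broken by
  fewer selected genes, then lexicographically — with elite slots going to
  *distinct* chromosomes first, so equally optimal subnetworks survive side
  by side rather than as copies of one winner (the downstream frequency
  vote needs exactly this diversity);
* the rest are bred by rank-weighted parent sampling and uniform
  crossover, then per-bit mutation at rate 5%, where a mutated bit becomes
  1 with probability 1/(zeroToOneRate + 1) = 5% at the default
  zeroToOneRate of 19 — the sparsity control that keeps subnetworks small;
* a memetic refinement hill-climbs the incumbent best chromosome and one
  uniformly random start by single-bit flips (`local_search = TRUE`).

The memetic step deserves a note. The zeroToOneRate kernel biases both
initialization and mutation toward almost-empty chromosomes, which is right
for the intended regime (small discriminative modules inside large
candidate sets) but makes it essentially impossible for mutation alone to
assemble a *dense* optimum. The deterministic hill climb restores global
search ability at a cost of one chromosome-length evaluation per
improvement step, and on instances small enough to enumerate it makes the
GA reach the exhaustive optimum reliably. On pure-noise data with few
samples, where the global optimum is an arbitrary overfit subset of
roughly half the candidates, no amount of sparse-kernel evolution finds it;
we regard that regime as outside the method's scope and document it as a
limitation rather than tune the kernel away from the published setting.

All equally optimal member sets in the **final** population (within
1e−12 of the minimum, deduplicated as sets) are collected; restricting to
the final population is a simplification — earlier generations could in
principle contribute ties the final one lost.

## Core extraction and significance

Subnetworks without any putative driver gene are removed. Each gene is then
scored by the fraction of remaining optima containing it, and members with
frequency ≥ 50% (inclusive — the rule filters out *low*-frequency genes)
plus the seed form the core; if the core contains no driver, the seed
yields none. Two empirical nulls assess each core:

* **label permutation** — the fixed core's fitness under shuffled
  phenotype labels (exhaustively enumerated, with a message, when fewer
  distinct assignments than permutations exist);
* **random membership** — fitness of uniformly drawn same-size gene sets
  from the expressed-gene universe ("genomic background"; drawing from the
  seed's candidate set instead is a stricter, configurable alternative).

Both use the add-one estimator $p = (1 + \#\{f_{null} \le f_{obs}\}) /
(N + 1)$, which is never 0 and is bounded below by $1/(N+1)$; ties count as
extreme, making the tests conservative when the discrete fitness collides.
No multiple-testing correction is applied across seeds; the per-core
p-values are reported as such.

## The synthetic benchmark

`simulation_config()` defines the study conditions the test suite and the
acceptance script run under:

* 500 genes (20 transcription factors, 10 lncRNAs), random interaction
  graph at mean degree 4;
* one planted 5-gene module wired as a star around its seed gene (all
  members within radius 1, hence well inside the radius-3 search ball);
* log2 expression = gene baseline `N(3, 1.5)` + `N(0, 1)` noise; module
  genes shifted by `effect_size × noise_sd = 3` log2 units in the case
  class, half that in the optional intermediate class (default on), so the
  |FC| > 2 threshold translates to an expected log2FC of 3;
* 50 samples per class; Poisson raw counts proportional to abundance;
* 10 driver-grade genes (score > 0.8, p < 0.05), 10% of them inside the
  module (i.e. exactly one, never the seed), the rest on background genes —
  mirroring the common situation where most putative drivers are not
  differentially expressed.

What the generator does *not* emulate: correlated co-expression within
pathways, library-size and batch effects, count overdispersion beyond
Poisson, mutation-level data, or dependence between the interaction graph
and expression covariance. Passing tests therefore demonstrate the
machinery — selection rules, search optimality, vote behaviour, null
calibration — not performance on real tissue data.

## Numerical choices and degenerate inputs

* Equal-width bins over the observed range; constant vectors map to a
  single bin (MI 0). Zero-variance genes z-score to all-zero profiles.
* Optima are compared at absolute tolerance 1e−12; elite ties break toward
  smaller subnetworks (parsimony), then lexicographic bit strings, making
  runs platform-stable.
* Seeds without interaction partners skip the GA and yield the seed-only
  subnetwork directly; an unexpressed seed is an error naming the filter.
* Every stochastic step (initialization, mutation, lncRNA target ranking,
  permutation draws, simulation) is a pure function of an integer seed.
* The GENIE3-style lncRNA target ranking regresses each candidate target
  on the lncRNA plus 50 random co-regulators (random forest, impurity
  importance, the lncRNA's share as the score) instead of all ~20,000
  genes; this preserves the relative-importance semantics at a desk-scale
  cost and stays reproducible under the seed. Ties rank lexicographically.
  Whether expansion should continue beyond a lncRNA's ranked targets is
  genuinely open; it continues by default (`expand_lnc_targets = FALSE`
  stops at the targets).

## Problem sizes used by the test suite

The acceptance checks enumerate all subsets only for instances of 8–14
candidate genes; the recovery benchmark runs ten full pipeline replicates
at the conditions above with 99 permutations per significance test (the
permutation count affects only the p-value resolution, not core
membership); calibration uses 200 repetitions of a 60-gene null data set;
the plateau check runs the default 500 generations five times and compares
the best fitness at generation 300 against 500. These sizes were chosen so
the whole suite exercises every stage at full parameter defaults where it
matters (GA budget, thresholds) while staying enumerable where exactness
is asserted.

## Known limitations

* Plug-in MI on few samples saturates: many member sets tie at perfect
  separation, so the identity of a single "optimal" subnetwork is not
  well-defined — the frequency vote across collected optima is the
  mechanism that makes the core stable, and it needs the deduplicated
  elite to see genuine diversity.
* The DE substitute is a t-test on transformed abundances, not a count
  model; with strong mean–variance coupling or tiny replicate numbers a
  dedicated count-based fit should be substituted at the TSV interface.
* Dense optima on noise-dominated data are outside the sparse search
  kernel's reach (see above).
* lncRNA target ranking is expression-only and makes no claim of matching
  any published regulatory network inference output.
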