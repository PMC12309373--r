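---
title: "Cluster-anchored over-representation analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-anchored over-representation analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishnet)
```

## The problem

A dose-response (or any other) transcriptomic screen ends with two lists: a
*background* of every transcript detected in the experiment, and a
*deregulated* subset that responded significantly. The conventional route to
biological meaning — one over-representation analysis (ORA) of the whole
deregulated list against GO/KEGG/WikiPathways-style gene-set collections —
suffers from a dilution problem: a pathway whose eight responsive genes sit
inside a list of thousands produces an overlap close to its chance
expectation, and the pathway is missed. It also leaves most deregulated
genes attached to no enriched function at all.

`fishnet` implements the alternative this package is built around:
**anchor the ORA on clusters** of a protein-protein interaction (PPI)
network induced on the deregulated genes, so each test asks whether a
small, interaction-coherent gene group overlaps a function — a far more
sensitive question — and then grow those clusters by merging on shared
functions and by "fishing" isolated genes back in through shared
annotations. Dose-response metrics (benchmark doses, trend shapes) are
consumed as input and summarised per cluster, ranking clusters from most
to least sensitive.

## The pipeline, step by step

1. **Inputs** (`read_dr_results()`, `read_ppi_edges()`, `read_gmt()`,
   `annotate_regulators()`, `read_ontology_edges()`): everything is a
   local file; nothing is fetched from a network service. The
   transcript-to-gene mapping is a column of the input CSV, which keeps
   the tool organism-agnostic.
2. **PPI graph** (`build_graph()`): edges between deregulated genes with
   combined confidence at or above `confidence_min` (default **0.9**,
   high-confidence; 0.4 is the STRING default for exploratory networks).
   Both 0–1 and STRING's 0–1000 score dialects are accepted; the dialect
   is auto-detected from the presence of scores above 1.
3. **Markov clustering** (`mcl_cluster()`): an internal, deterministic MCL
   implementation (details below) with inflation default **4**, the
   granularity that balances few-large against many-small clusters.
4. **Cluster size filter** (`partition_and_filter()`): clusters with fewer
   than `min_cluster_size` (default **4**) genes are dissolved; their
   genes join the off-network genes in the *lonely cluster*. The filter is
   non-strict ("retain size ≥ 4"); the boundary is exposed in the
   configuration for studies that read it the other way.
5. **Cluster-wise ORA** (`ora_query()`): one-tailed
   Fisher/hypergeometric tests per (cluster, database) with
   Benjamini-Hochberg FDR at `fdr_alpha = 0.05` and two additional
   filters: the *biological function size filter* (terms annotating
   5–500 background genes are testable; anything outside the window never
   enters the FDR family) and the *enrichment gene count filter*
   (retained results need ≥ 3 overlap genes; applied after FDR so it
   cannot change the family). The optional *driver-term filter*
   (`driver_filter()`) prunes redundant ontology terms.
6. **Merging** (`merge_clusters()`): clusters sharing at least one
   retained term from one database are combined, database by database in
   descending order of background coverage.
7. **Fishing** (`fish_lonely()`): a lonely gene annotated to a term
   enriched in a cluster joins that cluster; the number of clusters joined
   is its *friendliness*. From this step on clusters may overlap.
8. **Lonely-cluster ORA and summaries** (`run_pipeline()`,
   `build_summary()`): the residual lonely set gets its own ORA under
   identical parameters, and each final cluster is summarised by its
   transcript-level benchmark-dose quantile, trend counts and regulator
   counts, ordered most-sensitive first.

## The statistical model

For a query of size $n$ drawn from a universe of $N$ genes, of which $K$
carry a term's annotation, the probability of observing an overlap of at
least $k$ genes under the null of no association is the hypergeometric
upper tail

$$P(X \ge k) \;=\; \sum_{j=k}^{\min(n,K)} \frac{\binom{K}{j}\binom{N-K}{n-j}}{\binom{N}{n}},$$

computed via `stats::phyper` and verified in the test suite against exact
binomial-coefficient enumeration for every universe up to $N = 20$ at
$10^{-12}$. The universe $N$ is the set of background genes annotated
*anywhere in the given collection* (the "annotated domain" convention),
matching the use of a background list of annotated protein-coding genes;
consequently $N$ differs between databases. FDR control is
Benjamini-Hochberg, applied per (query, database) family — mirroring one
enrichment run per cluster per database — and likewise verified against
the direct step-up formula. Whether FDR should instead be shared across
databases within a query is a genuinely open choice; per-database was
selected because each database is queried independently, and users
comparing across databases should be aware the families are separate.

## MCL internals

The literature describes the clustering step operationally (an MCL run
inside a network tool); the numerical details here are this package's own:

* self-loop weight = the node's maximum incident edge weight, standard
  practice that keeps the column-stochastic matrix well-conditioned;
* expansion power 2 (matrix squaring), inflation exponent
  `inflation` (default 4), entries below `1e-6` pruned each iteration,
  convergence when the largest elementwise change is below `1e-6`,
  hard error (never a partial result) after 200 iterations;
* attractors (nodes with surviving diagonal mass) are grouped into
  attractor systems via the symmetrised support of the limit matrix; each
  node is assigned to the systems whose attractors hold mass in its
  column. In the rare degenerate case of overlapping systems, a node goes
  to the larger cluster, ties to the cluster with the lexicographically
  smallest member — determinism is a hard requirement, and byte-identical
  reruns are asserted in the tests.

One property worth stating precisely: MCL *refines* connected components
(expansion and inflation cannot move probability mass between disconnected
blocks), so disconnected cliques are always recovered exactly — but MCL
does **not** in general equal connected components, even on small graphs.
A four-node path splits into two pairs at any inflation ≥ 2, and a
four-node cycle collapses to singletons at high inflation; both are
textbook MCL behaviour on sparsely connected, symmetric structures, not
implementation artefacts. Interaction-dense functional modules (the
structures the workflow targets) are unaffected.

## Tie-breaking and degenerate inputs

Everything that could depend on iteration order is pinned: cluster ids
`c1, c2, ...` are assigned by decreasing size with ties broken by the
lexicographically smallest member gene; merged clusters take the id
`m` + their smallest constituent id and are never re-tested (their
enriched set is the union of their members'); duplicate undirected PPI
edges keep the maximum score; a gene listed as both TF and CoTF is
flagged TF. Empty inputs are contracts, not errors: an empty deregulated
list short-circuits the pipeline, an empty query logs and returns no
results, and an empty benchmark-dose vector yields an absent quantile.
All character sorting uses radix order so outputs are locale-independent.

## Dose-response summaries

Benchmark doses are pooled per cluster at the *transcript* level (a gene
with several modelled transcripts contributes each of them), and the
sensitivity metric is the first quartile by linear interpolation of order
statistics ($h = (n-1)p$, interpolating between the $\lfloor h\rfloor$-th
and next order statistic — the default convention of R's `quantile`).
No convention is canonical for this summary; the choice is exposed as
`quantile_prob` and the interpolation is cross-checked against a
hand-written order-statistic oracle. Fished genes contribute their
transcripts to every cluster they joined (`pool_fished_bmd` switches this
off), since after fishing they are full cluster members.

## What the synthetic fixtures emulate — and what they do not

`fixture_spec()` / `generate_fixture()` produce complete input bundles
with planted truth. The reference scenario is a 500-gene background with
60 deregulated genes: three 8-gene modules wired as cliques with edge
scores above 0.9, each annotated to a planted term slightly larger than
the module; five lonely genes annotated to those terms (so fishing must
recover them); per-module, non-overlapping log-uniform benchmark-dose
windows (1–2, 4–8, 16–32 dose units, remaining deregulated genes 40–80)
so the sensitivity ranking has a single correct order; and a trend mix of
46/47/3/4% inc/dec/bell/U, the monotone-dominated composition typical of
dose-response screens. A second scenario dilutes one 8-gene module
inside a 150-gene deregulated list with a 40-gene planted term and 60
noise terms: the whole-list ORA's expected overlap (~7.5 of 8) makes the
planted term invisible to the standard approach while the cluster-level
test retains it — the anchoring-sensitivity property demonstrated in the
acceptance tests.

These fixtures emulate the *statistical* structure the workflow assumes
(interaction-dense modules, annotation overlap, a lonely fraction,
noise edges below the confidence threshold). They do not emulate real
PPI degree distributions, correlated annotation hierarchies beyond one
parent level, inter-module edges, or annotation incompleteness — so
green tests certify the machinery and its contracts, not performance on
any particular organism's data.

Problem sizes throughout the test suite (hundreds of genes, tens of
terms, 20-seed stability sweeps, a 100-fixture filter-soundness sweep)
were chosen as the smallest scales at which every contract is exercised
with comfortable statistical margins.

## Known limitations

* The driver-term filter is an elim-flavoured most-specific-term rule
  over a user-supplied DAG; it approximates, but is not, the proprietary
  highlighting algorithm of hosted enrichment services.
* Only over-representation (one-tailed enrichment) is tested; depletion,
  GSEA-style ranked statistics and topology-aware methods are out of
  scope.
* The PPI graph is induced on deregulated genes only; bridging
  interactions through non-deregulated neighbours are not added.
* Dose-response modelling itself (model fitting, BMD estimation) is
  upstream: this package consumes its outputs and never recomputes them.

## A minimal run

```{r example}
dir <- tempfile()
generate_fixture(fixture_spec(seed = 5), dir)
inp <- read_fixture(dir)
cfg <- pipeline_config(seed = 5)
res <- run_pipeline(inp$lists, inp$edges, inp$collections, cfg,
                    ontology = inp$ontology)
res
build_summary(res, inp$lists, cfg)$summary[, 1:7]
```
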