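---
title: "Comparing condition-associated gene networks: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing condition-associated gene networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condnet)
```

## The model

A literature-derived knowledge base is a typed directed multigraph: nodes
are genes/proteins, microRNAs, conditions (diseases, phenotypes) and
annotation terms; edges are typed interactions, each potentially recorded
many times with different relation labels and literature provenance. The
**associative network of a condition** is the subgraph induced by every
gene-like entity with at least one stored link to the condition, together
with the interactions among those genes. Everything in this package
operates on that object or on gene sets derived from it.

Three per-gene statistics summarise a condition network:

* **Connectivity** `K` counts stored links, parallel typed links
  included, between the gene and other members or the condition itself.
  Knowledge bases deliberately keep one edge per extracted assertion, so
  `K` measures evidence volume; the distinct-neighbour count
  (`neighbor_degree`) is emitted alongside because either reading of
  "connectivity" is defensible and downstream users should not have to
  re-derive the other.
* **Betweenness** is computed on the simple undirected unweighted
  gene–gene projection with self-loops and the condition node excluded,
  unnormalized, unordered pairs counted once, equal fractional credit
  across tied shortest paths, per connected component. Undirected-simple
  is the standard network-medicine convention; since only *rankings* of
  hubs are consumed downstream, normalization is omitted.
* **Cross-talk specificity** `CTS = K/M`, with `M` the gene's link count
  in the whole knowledge base. `M >= K >= 1` for any member, so
  `CTS` lies in (0, 1] and is invariant under duplicating the entire
  knowledge base. CTS deliberately counteracts literature bias: heavily
  studied hubs accumulate links everywhere (`M` large, CTS small), while
  a gene whose few known links all fall inside the analyzed network is
  maximally specific.

## Overlap and enrichment statistics

The overlap of a query set (size `K`) and a reference set (size `n`)
sharing `k` genes in a universe of `N` is scored by the exact
hypergeometric upper tail `P(X >= k)`. The implementation sums the
log-probabilities of the tail terms via `lgamma` and combines them by
log-sum-exp, so tails far below the smallest representable double
(`1e-300` and beyond) stay finite and accurate in log10 space. The
at-least-`k` convention (survival function evaluated at `k - 1`) is fixed
by definition and pinned by three independent routes in the tests:
exhaustive draw enumeration for all parameter sets with `N <= 12`, the
closed forms of forced configurations, and `stats::phyper(log.p = TRUE)`.

Two conventions matter and are explicit, overridable parameters:

* **Background size `N`.** Literature knowledge bases rarely publish
  their gene universe. The default is the number of gene entities in the
  loaded knowledge base; every overlap function takes `N` explicitly, and
  `background_sensitivity()` maps `log10 p` over a grid of `N` so users
  can see how conclusions depend on the assumption. For a fixed positive
  overlap the tail probability strictly sharpens as `N` grows.
* **Multiple-testing `m`.** Term enrichment corrects over the number of
  terms carrying at least one query gene — the convention of common
  enrichment tools — not the whole vocabulary; Bonferroni
  (`min(1, m p)`) is the default at `alpha = 0.01`, Benjamini–Hochberg is
  available, and an EASE-style conservative variant (overlap decremented
  by one) sits behind an off-by-default flag. Published p-values from
  hosted enrichment services depend on their annotation release and exact
  universe and are not reproducible from the outside; the machinery here
  is therefore validated on planted synthetic annotations instead of
  against printed service output.

Multi-set structure is reported as a **Venn partition**: each gene of the
union is keyed by its membership bitmask over the declared set order
(`"10110"`), which serializes up to six-way diagrams without drawing
them; the all-ones region equals `mutual_genes()` by construction, and
disjointness/coverage are property-tested invariants.

## Link-pattern classification

Curated studies group gene–condition links into six patterns:
up-regulated by the condition, down-regulated, condition-inducing,
protective/counterregulatory, SNP-risk, and other. `condnet` mechanizes
this with a declarative rulemap over relation labels and edge direction
(see `default_rulemap()`). Semantics are **multi-label**: a gene reported
both up- and down-regulated keeps both classes — published tables list
several such genes, so a partition would contradict the curated counts —
while `OTHER` is reserved for genes with no substantive match (plain
association or PPI records, or labels missing from the rulemap, which
are logged). Two classifications restricted to their shared genes yield a
6×6 contingency table (`cross_classification()`); the transcription of a
published two-condition table is packaged and its decomposition/
recomposition (`cross_table_classifications()`) reproduces every printed
cell.

## The synthetic generator: what it emulates, what it does not

`synthetic_spec()` fixes the study conditions for all validation: a
preferential-attachment global network (2000 genes, 3 edges per new
node), five condition modules of 141/494/424/685/130 genes, a 14-gene
core shared by all, and focus overlaps of 47/50/62/22 — the scale of the
published five-condition comparison. Preferential attachment was chosen
over a configuration model because it has a simpler determinism contract
and produces the heavy-tailed degree distribution that makes CTS
informative. Module members beyond the planted structure are drawn
without replacement with probability proportional to `degree + 1`,
emulating literature bias toward hubs — precisely the bias CTS exists to
counteract, so rank-recovery tests are meaningful. Planted pairwise
overlaps are specified against the first (focus) condition, extras drawn
disjointly so intersections are exact; a full overlap matrix between
arbitrary comparator pairs is not supported because no analysis here
needs it. One enriched term per condition is planted (default: 80% of
the module plus 5 outside genes), on top of random background terms.

What the generator does **not** emulate: the true degree distribution of
any specific knowledge base, correlated annotation structure (ontology
DAGs), asymmetric evidence volumes per edge, or textual provenance.
Passing recovery tests therefore demonstrates that the pipeline's
bookkeeping and statistics are correct, not that any biological
conclusion from real literature graphs is robust to their biases.

Determinism: all draws run through R's Mersenne-Twister with
`sample.kind = "Rejection"` under a locally scoped seed (global RNG state
is restored), which is stable across platforms for a fixed R series.
`generate_synthetic_bundle()` derives stage seeds as `seed`, `seed + 1`,
`seed + 2`.

## Numerical and degenerate-input choices

* Ties in `rank_nodes()` break lexicographically by symbol, making every
  ranking deterministic.
* A condition with zero linked genes yields an empty network with a
  warning, not an error; empty graphs yield empty metric maps.
* Self-interactions are stored but excluded from all metrics; parallel
  edges are stored and collapse only in the simple projection.
* Gene and protein records with one symbol merge into a single node on
  read, since curated tables report "genes/proteins" as single members;
  symbols are upper-cased and passed through a packaged, user-extensible
  alias table (shipping `G6PC -> G6PC1`, `GLUT2 -> SLC2A2`) because the
  transcribed tables themselves mix aliases.
* `hypergeom_tail` returns exactly 0 (log10) whenever `k` does not exceed
  the smallest attainable overlap `max(0, K + n - N)`.
* Pipeline reports exclude the output directory from the serialized
  config, so reruns are byte-identical wherever they are written; the
  config fingerprint is a 32-bit FNV-1a hash.

## Validation problem sizes

The shipped test suite validates betweenness against a brute-force
shortest-path-enumeration oracle on 1000 seeded random graphs of up to 8
nodes (plus credit-conservation checks); the hypergeometric tail against
exhaustive enumeration for every parameter combination with `N <= 12`;
null calibration of overlap p-values with 1000 replicates of random
141- and 494-gene sets in a 5000-gene background (rejection fraction at
0.05 must land in 0.05 ± 0.02); and full-pipeline recovery of planted
cores, overlaps, link classes and enriched terms across 20 seeds at
400 genes / 3 conditions, with the published 2000-gene five-condition
scale exercised once. These sizes were chosen as the smallest at which
each property is non-trivially exercised.

## Known limitations

* The transcriptions inherit the source tables' internal inconsistencies:
  one symbol appears under two aliases across tables (resolved by the
  alias table), and one gene (SERPINA1) is classed up-regulated in the
  published cross-condition table but sits only in the SNP row of the
  per-condition class table. Cross-table reproduction therefore derives
  both classifications from the cross-table transcription itself.
* The published five-condition comparison's full gene lists are
  distributed only as a supplementary file; they can be supplied as GMT
  and fed to `venn_partition()`/`overlap_matrix()` directly, but are not
  packaged. The acceptance script recovers the published counts from a
  synthetic family planted at the same scale instead.
* Enrichment is flat: annotation is taken as given, with no ontology
  propagation.
* No weighted or directed centralities; the betweenness convention is
  the undirected-simple one stated above.

```{r, eval = FALSE}
# end-to-end sketch
spec <- synthetic_spec(seed = 1)
b <- generate_synthetic_bundle(spec)
net <- extract_condition_network(b$kb, "COND1")
head(node_metrics(net, b$kb))
```
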