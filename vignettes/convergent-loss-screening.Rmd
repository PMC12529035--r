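---
title: "Screening convergent gene loss with duplication–loss reconciliation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening convergent gene loss with duplication–loss reconciliation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symscreen)
```

## Motivation

Most land plants host arbuscular mycorrhizal (AM) fungi, an ancient
mutualism supported by a conserved repertoire of symbiosis genes. When a
lineage abandons the symbiosis — for instance after evolving an alternative
nutrient-acquisition strategy such as carnivory — those genes decay and
disappear. Because the pattern repeats independently across lineages,
presence/absence profiling of symbiosis genes over a species tree is a
powerful comparative readout: genes convergently absent in focal lineages
but retained in their close noncarnivorous relatives point at trait-linked
loss rather than technical dropout.

`symscreen` implements that inference chain — gene-tree rooting by
reconciliation, anchor-based orthogroup extraction, dual-evidence
occurrence calling, and the convergent-loss screen — together with a
simulator that generates data with known ground truth. This vignette
documents the models, the tunable parameters, the numerical choices, and
what the synthetic benchmarks do and do not demonstrate.

## Duplication–loss reconciliation

Given a rooted binary gene tree $G$ and a rooted species tree $S$, the LCA
mapping sends each leaf to its species and each internal node $v$ to
$M(v) = \mathrm{lca}_S(M(\mathrm{left}(v)), M(\mathrm{right}(v)))$. Node
$v$ is a *duplication* iff $M(v) = M(c)$ for at least one child $c$,
otherwise a *speciation*. For each gene-tree edge $(u, v)$, let $d$ be the
number of species-tree edges on the path from $M(u)$ down to $M(v)$; the
edge carries $d - 1$ losses under a speciation parent and $d$ under a
duplication parent. The reconciliation cost is
$w_{dup}\,\mathrm{dup} + w_{loss}\,\mathrm{loss}$ with unit weights by
default — conventional DL rooting tools do not document a canonical
weighting, so the weights are exposed as a parameter rather than hard-coded.

Because losses are summed over *gene-tree* edges, species clades lying
entirely outside the MRCA of the represented species contribute no cost.
Zero cost therefore characterizes a family with exactly one copy per
species of the complete species clade under the root's image, with
congruent topology; the tests assert this characterization in both
directions against an independent brute-force oracle.

### Rooting

`root_gene_tree()` re-roots an unrooted gene tree on each of its $2n-3$
edges, reconciles, and returns the full edge-by-edge cost table plus the
minimal-cost root. Exhaustive search is exact and, at the family sizes this
pipeline targets (tens of leaves), faster than any bookkeeping cleverness
would justify.

**Tie handling.** Several edges can share the minimal cost, and no
published convention resolves such ties. The choice here is deterministic
and auditable: prefer the rooting whose root image lies closest to the
species-tree root, then the lexicographically smallest sorted leaf set of
the smaller root-child clade. The entire tie set is returned so users can
report ambiguity instead of silently trusting the tiebreak.

**Degenerate inputs.** Non-binary gene-tree nodes are resolved before
reconciliation into a reproducible binary refinement (children rotated into
sorted-leaf order, then split with zero-length edges), with a warning;
species-tree polytomies are treated as soft and contribute a single edge to
loss paths, which keeps loss counts conservative. Rooting a tree with fewer
than three leaves is an error; reconciling a gene tree containing species
absent from the species tree is an error at this stage — such leaves are
meant to be pruned at ingest (`prune_to_species()`), mirroring upstream
contamination removal.

## Orthogroup extraction

Named marker genes are located in gene trees through *anchor* gene ids
(reference-species orthologs). From each anchor leaf the algorithm ascends
toward the root and returns the smallest clade that has a child subtree
composed exclusively of outgroup-species leaves — the outgroup as
"basalmost ortholog", which delimits the orthogroup at the taxonomic depth
of the outgroup divergence. All leaves of that clade are members,
lineage-specific duplicates included. The qualitative criterion comes from
practice; the structural reading used here (an all-outgroup child of the
clade root) is the weakest checkable formalization, which keeps membership
maximally inclusive.

Open design points, decided as follows:

* **No outgroup-anchored clade** (frequent in transcriptome-derived trees):
  the whole tree is returned with `outgroup_found = FALSE` rather than
  dropping the family, because silently discarding such families would bias
  presence calls toward absence. Downstream treats the membership normally.
* **Several anchors in one tree:** the union of the per-anchor clades. This
  mirrors the union-style consensus used in occurrence calling, and is the
  conservative choice when the alternative (picking one clade) has no
  principled selection rule.
* **Graph clusters:** a cluster containing anchors of two named genes
  yields a call for each (shared membership); a gene split across clusters
  yields several calls whose union is taken downstream. Anchor ids match by
  exact string; a gene id occurring in two clusters violates the cluster
  table's invariant and is an input error.

## Occurrence and retention

A gene is called present in a species if *either* the tree evidence or the
graph evidence contains it — the union rule deliberately favors sensitivity
because downstream screens treat "undetected" as absent. Every cell carries
provenance (`tree` / `graph` / `both` / `none`), and the invariant
`none` ⇔ absent is enforced by the container. Species present in the
dataset but absent from a particular gene tree count as absent for that
source (a detected/undetected dichotomy, not missing data); a species with
both a genome and a transcriptome is one column, merged by union.
`retention_rate()` and `summarize_by_group()` turn the matrix into the
fractions used in comparative summaries (retained $k/n$, lost $1 - k/n$,
per-group min–max ranges).

With two *independent* evidence sources each at completeness $c$, the
consensus false-negative rate per truly-present cell is $(1-c)^2$ — an
advantage of dual-evidence calling the tests verify by Monte Carlo.

## The screen

`convergent_loss_screen()` reports the rows present in every background
species, the rows absent in every focal species, and their intersection
(the hits). Focal lineages may be given separately, but requiring each
lineage to be all-absent is logically identical to pooled absence across
their union, so the sets are pooled internally. Overlap with a target list
is a plain intersection; enrichment is an exact one-sided hypergeometric
tail $P(X \ge k)$, with no multiple-testing correction by default because a
single screen is a single test (`stats::p.adjust` composes naturally when
several target lists are screened).

## The simulator

The generator defines the benchmark conditions; its defaults are fixed
study conditions, not tuning knobs.

* **Gene birth–death:** one lineage enters the species-tree root; each copy
  independently duplicates at rate $\lambda$ and dies at rate $\mu$ per
  unit branch length. $E[N(T)] = e^{(\lambda-\mu)T}$ on a single branch,
  checked at 10,000 replicates. Default $\lambda = \mu = 0.1$: the critical
  regime keeps the expected copy number at one per species, matching the
  mostly single-copy behavior of curated symbiosis gene sets; no empirical
  rate estimates exist for these families, so the value is an
  implementer-chosen, documented default.
* **Trait-linked loss:** a designated fraction of families (default
  assignment: the first `round(frac * n_families)` indices, so each family
  regenerates independently) is trait-linked; on each designated trait
  branch, with probability `p_forced_loss`, *all* copies are terminated at
  the branch midpoint, once, and never regained — a Dollo-like
  irreversibility reflecting that a dismantled symbiosis pathway is not
  easily rebuilt. Forced losses are all-or-nothing at the lineage level by
  design; per-copy decay alternatives are out of scope.
* **Detection dropout:** each truly present cell is observed with
  per-species probability $c_s$ (presets 0.90 for genomes, 0.77 for
  transcriptomes, rounded from typical Busco completeness means of large
  plant datasets).
* **Determinism:** per-family random streams derive from
  `(seed, family_index)` via a fixed linear-congruential mix, so any family
  can be regenerated alone and whole datasets serialize byte-identically.
  The dataset manifest records every scenario parameter and explicit
  species counts rather than assuming them downstream.

**What the simulator does not emulate:** sequence-level evolution and
alignment/tree-estimation error (gene trees are true topologies),
contamination, assembly fragmentation beyond Bernoulli dropout, horizontal
transfer, rate heterogeneity beyond the trait mechanism, and gene regain.
Passing the synthetic benchmarks therefore demonstrates the correctness of
the *inference machinery*, not robustness to phylogenetic estimation error
in real data — on real inputs the rooting stage consumes externally
inferred ML trees, and its behavior depends on their quality.

## Benchmark problem sizes

The test suite runs, among others: oracle-equivalence of the rooting cost
table on 200 simulated families (20-taxon Yule tree,
$\lambda = \mu = 0.1$, 3–12 surviving leaves) against a brute-force
reconciliation written independently of the implementation; 100 congruent
one-copy families (4–20 taxa) for exact root recovery; an end-to-end
truth-recovery scenario with 500 families on 16 species, two trait-loss
lineages (4 focal species), 15% trait-linked families and certain forced
loss, under both perfect detection and background completeness 0.9; and
10,000-replicate birth–death means for $(\lambda, \mu, T) \in
\{(0.1, 0.1, 5), (0.2, 0.1, 3)\}$. These sizes give stable Monte-Carlo
margins (3σ bands) while keeping a full run in the order of a minute.
`scripts/acceptance.R` recomputes the headline quantities of the same
scenario from any seed.

## Known limitations

* The DL model excludes transfer events and likelihood-aware rearrangement;
  externally refined (e.g. species-tree-aware ML) gene trees can be
  supplied but are not recomputed here.
* Orthogroup extraction assumes anchors are correctly placed in the gene
  tree; a misassembled anchor sequence can pull in a paralogous clade.
* The screen is combinatorial, not model-based: it does not correct for
  phylogenetic non-independence of the focal lineages, and treating
  undetected as absent means low-completeness species can inflate the
  focal-absent set. The dropout machinery exists precisely to quantify that
  effect under controlled conditions.
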