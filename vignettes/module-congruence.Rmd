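---
title: "Module discovery and cross-network congruence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Module discovery and cross-network congruence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(congru)
```

`congru` asks a structural question about molecular interaction data: when
the same cell is described by physical, genetic and co-regulation networks,
how much of its modular functional organisation does each description
capture, and what appears only when they are combined?  This vignette
documents the model behind each stage, the parameters that matter, the
synthetic benchmark and its deliberate idealisations, and the places where
the design was genuinely open.

## 1. Network construction

A layer is an undirected simple graph over gene identifiers.  Physical and
genetic layers are unweighted (every edge weight 1).  The co-regulation
layer is derived from a binary significance-call matrix over treatments:
genes co-called in at least one treatment are joined, with weight
$w(a,b) = c_{ab} / (c_{ab} + c_a + c_b)$, where $c_{ab}$ counts treatments
calling both genes and $c_a$, $c_b$ the one-sided calls.  This is a
Jaccard-type frequency: 1 means the genes are never regulated apart, and it
falls symmetrically as either gene is regulated alone.  The upstream error
model that produces the calls is out of scope; calls (or a P-value matrix
plus a threshold, default 0.01) are the input.

The combined network first rescales each layer so that its total edge
weight is the same constant (1 by convention — the partitioner's objective
is ratio-based, so the constant is arbitrary) and then sums weights across
layers per edge.  Common-gene variants restrict every layer to the genes
present in all layers, keep induced edges, and drop genes left edgeless,
by default independently per layer.  Whether the connectivity requirement
should instead be simultaneous across layers is ambiguous; both modes are
implemented (`connected_rule`), and per-layer is the default because it
discards less data.

Partitioners need integer weights.  Unweighted layers use 1; weighted
layers are scaled and rounded half-up, the co-regulation layer by a fixed
scale (default 10, so weights resolve to one decimal) and the combined
network by an automatic scale mapping the mean edge weight to 10.  Edges
rounding to zero leave the cut objective but never the network.

## 2. Multi-resolution partitioning

Modules exist at every scale, so a single resolution is never enough.  For
a network of $n$ genes the plan enumerates candidate part counts
$k \in \{2, \dots, \lceil n/3 \rceil\}$ with average part size $s(k) = n/k$
and, for every integer target size from 3 to $\lfloor n/2 \rfloor$, records
the $k$ whose average size is nearest (ties toward the larger $k$, i.e. the
finer partition, favouring granular modules).  The distinct recorded $k$
values — about $2\sqrt{n}$ of them — are each partitioned once.

The partitioner contract is kmetis-like: $k$ parts, each at most
$\lceil 1.1\, n/k \rceil$ nodes, minimising the integer-weighted edge cut,
deterministic per seed.  The implementation seeds the assignment from
modularity communities (Louvain), peels communities larger than the part
size into chunks by greedy densest-attachment growth (each chunk starts at
the highest in-set degree node and repeatedly absorbs the most strongly
attached remaining node), packs chunks longest-first onto the lightest part
with room, and then refines with balance-constrained single-node moves
(compiled kernel) until no move strictly reduces the cut — a local optimum
under single-node moves.  Community seeding matters: flat local search from
a random balanced start cannot assemble a dense module once the balance cap
is reached, because evicting a filler node is never individually
profitable.  Degenerate cases are defined explicitly: $k = 1$ is the
trivial partition, $k > n$ an error, and empty parts may occur when $k$
approaches $n$.

## 3. Subgraph extraction and validation

Each part contributes the largest connected component of its induced
subgraph, kept only if it has at least 3 genes — a partitioner always cuts
the whole graph into $k$ parts, so small fragments are artefacts of $k$,
not localities.  Within one partition, every surviving subgraph is
validated against its cohort: mean intra-subgraph Dijkstra distance versus
the mean distances to each other subgraph, compared by a one-sample,
one-tailed t-test (alternative: inter exceeds intra).  Distances use unit
edge lengths on unweighted layers and $1/w$ on weighted layers, so strongly
co-regulated pairs are close; unreachable pairs are treated as missing, not
infinite.  The observations of the t-test are the per-neighbour inter
means, hence $df = (\#\text{other subgraphs}) - 1$; with a single other
subgraph (or a zero-variance inter vector) the test is not applicable and
the subgraph is retained flagged.  Subgraphs with $p \ge 0.05$
(`alpha_validate`, configurable) are discarded.  Catalogue entries are
de-duplicated on the gene set alone, recording every resolution that
produced them.

## 4. Congruence

Subgraphs from different single-type networks are compared by their gene
intersection.  Pairs are scored only if their sizes are within ten-fold,
they share at least `n_min = 3` genes and the intersection MCC is at least
`m_min = 0.2` (both configurable).  The MCC uses the congruence convention
for true negatives — the union of the two gene sets minus their
intersection — which has one counter-intuitive consequence worth knowing:
two *identical* gene sets give $TN = FP = FN = 0$ and, by the
zero-denominator convention, MCC $= 0$; exact duplicates across networks
therefore never become best hits, while near-identical pairs score highly.
We keep the convention because it is part of the congruence definition this
analysis rests on.

The significance of an intersection is the upper-tail hypergeometric
probability of drawing at least $TP$ of subgraph A's genes when sampling
$|B|$ genes from the universe.  Taking the universe to be literally the
union of the two subgraphs makes the 2×2 table degenerate (the "neither"
cell is structurally zero), so the default universe is the union of the two
source networks' gene sets; the literal-union mode is available
(`universe_mode = "union"`) for fidelity.  P values from all scored pairs
are pooled for Benjamini–Hochberg correction; among significant pairs
($q < 0.05$) each subgraph's maximal-MCC partner per opposing network is
its best hit (ties by smaller $q$, then partner id), reciprocal best hits
are mutual flags, and the best-hit graph's upper 2.5% degree tail
(`high_degree_percentile`) defines high-degree subgraphs, whose best-hit
partners complete the high-degree neighbourhoods.  Reciprocal pairs can be
merged into composite subnetworks: union of genes, union of each layer's
induced edges tagged by source, and node/edge betweenness on unit lengths
(layer weights have incompatible semantics, so they do not enter the
betweenness).

## 5. Functional enrichment and its reports

The ontology model is a term DAG with one namespace per term and
`is_a`/`part_of` parents; annotations propagate to ancestors (true-path
rule, toggleable).  Evidence modes `all`, `no_iea` and `only_iea` stratify
annotation reliability.  Per network, a term is *eligible* if it annotates
at least two of the network's genes — terms with one or no associated genes
cannot be informative there, and because the layers have different gene
sets, eligibility is genuinely per-network.  Each subgraph is tested
against each eligible term by the upper-tail hypergeometric with the
network's genes as population; BH correction is pooled over all
subgraph × term tests of the run (per-subgraph pooling available), and a
call additionally requires at least `min_tp = 4` supporting genes.  The
floor deserves its own justification: the multi-resolution catalogue
contains on the order of a thousand overlapping subgraphs for a 500-gene
network, which tile every gene pair into some subgraph with appreciable
probability; three specific genes landing together somewhere is then a
coincidence one should expect, and such coincidences would both contaminate
the annotation-randomization control and add cross-network noise to
coverage comparisons.  Four-gene support is beyond what the tiling produces
by chance at this problem size, while genuine module-term overlaps (8–12
genes) are untouched.

Coverage per namespace is the percentage of eligible terms enriched in at
least one subgraph, with the average over enriched terms of the best
per-term MCC ("average MCC"; the averaging set is a design choice —
documented, configurable by recomputation from the returned table).
Co-enrichment classifies pairs of terms enriched in the same subgraph as
same-namespace related (ancestor/descendant), same-namespace unrelated, or
different-namespace; integration-only pairs are those co-enriched in merged
reciprocal-best-hit subnetworks but in no single-layer subgraph.  The
randomization control permutes annotation profiles over genes (per-gene
annotation counts preserved as a multiset, term totals preserved exactly,
topology untouched) and re-runs enrichment.  Relative enrichment by term
size bins eligible terms by annotated-gene count and reports, per bin, the
proportion of accurately captured enriched terms (best MCC ≥ 0.2) minus
the proportion of all eligible terms; as a difference of two unit-sum
vectors these values sum to zero across bins.

## 6. The synthetic benchmark

The generator is a planted-partition (stochastic-block) design: disjoint
modules of fixed size in a shared gene universe, intra-module edge
probability `p_in`, background `p_out`, per-layer module membership.  The
default benchmark has 500 genes and eight modules of 12; modules 1–6 are
expressed by both topology layers, module 7 only by the first, module 8
only by the second; `p_in = 0.6`, `p_out = 0.02`; generation seeds 11/13/17
for layers, calls and ontology.  The co-regulation layer is driven by a
60-treatment call matrix in which each module is active per treatment with
probability 0.3, genes of active modules are called with probability 0.9
and background genes with 0.02 — rates chosen so that module pairs are
co-called in roughly a sixth of treatments (weights near 0.8) while
background co-calls stay rare and weak, a contrast typical of expression
compendia.

Two structures exist specifically because only integration can see them:

* **Split module.**  A ninth module's intra-module pairs are drawn once at
  `p_in` and each dealt to one of three shares — the two topology layers
  and a share standing for interactions detectable only by a third assay
  type, which no layer carries.  Each layer sees ~0.2 density (near the
  detection floor of a cohesive-subgraph analysis), while their union
  restores ~0.4 against a ~0.06 combined background.
* **Cross-network rider trios.**  Six trios of extra genes, each trio
  holding one gene per data type that interacts with a shared host module
  exclusively through that data type — attached at `p_in`/2, enough to
  join the host's combined subgraph but ranking below every module gene
  during peeling — and carrying *no* interactions of the other types (the
  gene is absent from those networks entirely, as genes covered by only
  one assay are in real data).  A per-namespace cross-network term
  annotates two trios plus one anchor gene per host module: any single
  network holds at most two of its genes per subgraph (below the support
  floor), while a combined-network host subgraph holds a full trio plus
  its anchor.  This exercises the per-network eligibility rule rather than
  any new machinery.

The ontology generator emits, per namespace, a root annotated to every
gene (general annotation covers the genome, keeping the root itself
uninformative — and, importantly, leaving nothing for the randomization
control to inherit from annotation sparsity), two mid-level terms
aggregating module groups, one leaf term per module (module genes
annotated with drop-out probability `annotation_noise = 0.1`), the
cross-network terms, and six small unaligned background terms (3–5 genes
sampled outside the planted structure; sampling them from module genes
would plant accidental signal).  Evidence codes are IEA with probability
0.3, EXP otherwise.

**What the benchmark does not emulate.**  Degree heterogeneity (real
interactomes are heavy-tailed; a degree-corrected variant would be the
natural extension), overlapping or nested modules, correlated noise
between layers, ascertainment bias, and a realistically deep ontology
(thousands of terms over many levels rather than ~20 per namespace).
Passing tests on this benchmark therefore demonstrates that the machinery
recovers the structure it is pointed at under calibrated noise — not that
any particular biological dataset will behave as cleanly.

## 7. Numerical and degenerate-input choices

* Rounding of partition weights is half-up; documented because R's
  `round()` is banker's rounding.
* MCC with any zero factor in the denominator is 0; an all-zero table is
  an error.
* Hypergeometric tails come from `phyper(tp - 1, ..., lower.tail = FALSE)`
  and are tested against explicit enumeration for every configuration with
  a universe up to 25 genes.
* Unreachable distance pairs are excluded from means rather than set to
  infinity; a subgraph whose every inter distance is unreachable is kept,
  flagged not-applicable.
* Ties in best-hit calling break by smaller q, then lexicographic partner
  id, making the catalogue order-independent; all tabular outputs are
  sorted and numerically formatted identically, so a rerun with the same
  configuration is byte-identical.
* Randomness is confined to `with_seed()` scopes (generator seeds fixed in
  the design; one partition seed per network/resolution derived from the
  run seed), leaving the caller's RNG state untouched.

## 8. Problem sizes

The shipped tests run the full default benchmark (500 genes, four networks
plus their common-gene variants, ~45 resolutions each, ~1,000–1,200
catalogued subgraphs per network) twice — once shared across the
scientific property tests, once more for the byte-identity check — in
about three minutes total on one CPU; the small worked-example design (120
genes) runs in a few seconds.  These sizes were chosen to keep a full
module-recovery, coverage, randomization and congruence cycle comfortably
interactive while leaving every statistical contrast (module density
versus background, single-layer versus combined coverage, true versus
randomized annotation) far from its decision boundary.

## 9. Known limitations

* The partitioner is a high-quality heuristic, not METIS: on adversarial
  graphs its cut can be worse, though the contract (balance, local
  optimality, determinism) always holds.  An external k-way backend can be
  substituted behind `partition_graph()`.
* The congruence MCC convention blinds best-hit calling to exact duplicate
  gene sets (section 4).
* Coverage compares networks with different eligible-term denominators by
  design; when denominators differ strongly (common-gene co-regulation
  variants), percentages are not directly comparable between reports.
* The co-regulation weight formula and several thresholds reconstruct a
  verbal description; all are configuration points (`coregulation_weight`
  documentation, `run_config()` arguments) rather than hard-coded claims.
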