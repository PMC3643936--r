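# congru

Modular biological function rarely lives in a single data type: a protein
complex shows up in physical interaction data, an epistatic pathway in
genetic interaction screens, a transcriptional program in expression
compendia.  `congru` implements a module-discovery analysis that treats
these as layers of one system.  It partitions each interaction network at
many resolutions, validates the cohesive subgraphs that emerge, asks which
subgraphs from *different* networks describe the same gene module
("congruent subgraphs"), and measures how completely each network — and
their weighted combination — covers the functional space described by a
gene ontology.  It is aimed at computational biologists who want to test,
on controlled synthetic benchmarks, how much functional signal single-type
networks miss and integration recovers.

## The method

**Networks.**  Layers are undirected gene graphs.  A co-regulation layer is
built from a binary gene × treatment significance-call matrix: genes *a*
and *b* are joined when co-called in at least one treatment, weighted by
the co-call frequency

    w(a, b) = c_both / (c_both + c_a_only + c_b_only)

where `c_both` counts treatments calling both genes and the other terms
count one-sided calls.  A combined network rescales every layer to equal
total edge weight and sums shared edges; common-gene variants restrict all
layers to their shared, connected gene set.

**Subgraphs.**  For a network of *n* genes, every target average part size
*i* from 3 to *n*/2 is served by the `k` (2 ≤ k ≤ ⌈n/3⌉) whose average
size *n/k* is nearest to *i*; the network is partitioned at every distinct
recorded `k` by a balanced k-way partitioner minimising the integer-weighted
edge cut (community-seeded initialisation plus balance-constrained local
refinement, kmetis-style).  Each part contributes its largest connected
component (≥ 3 genes); a one-sample, one-tailed t-test of mean
inter-subgraph versus intra-subgraph Dijkstra path lengths discards parts
that are not bona fide localities; duplicates across resolutions collapse
into one catalogue entry.  Edge density `d = 2e / n(n−1)` and weighted
density `h = 2w / (w̄ n(n−1))` summarise cohesion.

**Congruence.**  Subgraph pairs from different networks (sizes within
ten-fold, ≥ 3 shared genes, MCC ≥ 0.2) are scored by the upper-tail
hypergeometric probability of their gene intersection and by the Matthews
correlation coefficient

    MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN))

with TP the intersection, TN the union minus the intersection, FP/FN each
subgraph minus the intersection.  After Benjamini–Hochberg correction, each
subgraph's maximal-MCC significant partner per opposing network is its
*best hit*; mutual best hits are *reciprocal best hits*, and subgraphs with
unusually many best hits (top 2.5% of degree) seed *high-degree
neighbourhoods*.  Reciprocal pairs merge into composite subnetworks with
layer-tagged edges and node/edge betweenness.

**Function.**  Gene Ontology terms (OBO-like ontology, GAF-like
annotations, true-path propagation, optional IEA filtering) are tested for
over-representation in every subgraph (hypergeometric against the network's
gene population, pooled BH-FDR, ≥ 4 supporting genes).  Reports include
per-namespace coverage (share of eligible terms enriched somewhere, with
average best MCC), co-enrichment pair classes, integration-only
co-enrichment, an annotation-randomization control, and relative enrichment
by term size.

**Benchmark.**  A planted-partition generator emulates the study design:
multilayer networks with partially shared modules, a module-driven
treatment-call matrix, and a module-aligned synthetic ontology — including
structures only network integration can see (an edge-split module and
cross-network "rider" genes observed by a single assay type each).

## Worked example

```r
library(congru)

design <- planted_design(
  n_genes = 120, module_size = 8,
  layer_modules = list(ppi = c(1, 2, 3), genetic = c(1, 2, 4)),
  p_in = 0.7, p_out = 0.03,
  seeds = c(layers = 5L, calls = 6L, ontology = 7L))

cfg <- run_config(design = design, seed = 1, n_treatments = 30,
                  include_common = FALSE, annotation_modes = "all")
run <- run_all(cfg)
run
#> <congru_run>
#>   ppi               194 subgraphs (120 nodes, 275 edges)
#>   genetic           182 subgraphs (120 nodes, 283 edges)
#>   coreg              89 subgraphs (120 nodes, 1080 edges)
#>   combined          202 subgraphs (120 nodes, 1451 edges)
#>   congruence: 1582 scored pairs, 271 best hits, 31 reciprocal
#>   high-degree subgraphs: 5 (neighbourhood 77)
```

The two modules planted in both topology layers come back as reciprocal
best hits whose gene sets match the planted truth:

```r
score_module_recovery(run)$detail
#>            module          a              b jaccard_a jaccard_b recovered
#> ppi_sg0078     M1 ppi_sg0078 genetic_sg0094 0.8888889 1.0000000      TRUE
#> ppi_sg0095     M2 ppi_sg0095 genetic_sg0083 1.0000000 0.8888889      TRUE
```

and the combined network covers more of the ontology than the single-type
network (it also reaches the modules private to the other layers):

```r
subset(run$coverage, mode == "all" & network %in% c("ppi", "combined"))
#>     network          namespace enriched_terms total_terms coverage_pct
#>         ppi biological_process              5          13     38.46154
#>    combined biological_process              7          13     53.84615
#>  ...
```

`run_all(cfg, out_dir = "out")` additionally writes the full report bundle
(subgraph catalogues, hits table, coverage/randomization/co-enrichment
tables, merged subnetworks, provenance JSON) as deterministic plain-text
files.

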