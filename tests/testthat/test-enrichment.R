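toy_ontology <- function() {
  ontology(c("r", "m", "t", "u"),
           c("biological_process", "biological_process",
             "biological_process", "molecular_function"),
           list(m = "r", t = "m"))
}

test_that("ontologies validate their DAG and namespaces", {
  onto <- toy_ontology()
  expect_setequal(onto$ancestors[["t"]], c("m", "r"))
  expect_error(ontology("a", "made_up_namespace"), "namespace")
  expect_error(ontology(c("a", "b"), rep("biological_process", 2),
                        list(a = "b", b = "a")), "cyclic")
})

test_that("OBO-like and GAF-like files parse", {
  obo <- withr::local_tempfile(lines = c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:1", "name: root", "namespace: biological_process", "",
    "[Term]", "id: GO:2", "namespace: biological_process", "is_a: GO:1 ! root",
    "[Term]", "id: GO:3", "namespace: cellular_component",
    "relationship: part_of GO:3b", "",
    "[Term]", "id: GO:3b", "namespace: cellular_component"))
  onto <- read_obo(obo)
  expect_length(onto$terms, 4L)
  expect_equal(onto$ancestors[["GO:2"]], "GO:1")
  expect_equal(onto$ancestors[["GO:3"]], "GO:3b")

  gaf <- withr::local_tempfile(lines = c("# comment",
                                         "g1\tGO:2\tEXP", "g2\tGO:2\tIEA"))
  ann <- read_gaf(gaf)
  expect_equal(nrow(ann), 2L)

  empty <- withr::local_tempfile(lines = "# nothing")
  expect_equal(nrow(read_gaf(empty)), 0L)
  expect_length(annotation_map(onto, read_gaf(empty)), 0L)

  both <- load_ontology_and_annotations(obo, gaf)
  expect_s3_class(both$ontology, "congru_ontology")
  expect_equal(both$annotations[["g1"]], c("GO:1", "GO:2"))
})

test_that("annotations propagate by the true-path rule and filter by evidence", {
  onto <- toy_ontology()
  ann <- data.frame(gene = c("g1", "g2", "g2"), term = c("t", "t", "u"),
                    evidence = c("EXP", "IEA", "EXP"))
  all_map <- annotation_map(onto, ann)
  expect_equal(all_map[["g1"]], c("m", "r", "t"))
  no_iea <- annotation_map(onto, ann, use_iea = "no_iea")
  expect_false("t" %in% no_iea[["g2"]])
  expect_true("u" %in% no_iea[["g2"]])
  only <- annotation_map(onto, ann, use_iea = "only_iea")
  expect_equal(names(only), "g2")
  flat <- annotation_map(onto, ann, propagate = FALSE)
  expect_equal(flat[["g1"]], "t")
})

test_that("enrichment hits the closed-form hypergeometric", {
  genes <- sprintf("g%03d", 1:100)
  onto <- toy_ontology()
  ann <- data.frame(gene = genes[1:10], term = "t", evidence = "EXP")
  amap <- annotation_map(onto, ann, propagate = FALSE)
  sub <- fake_subgraph(genes[1:10], "net", "s1")
  res <- enrich_subgraphs(sub, amap, genes)
  row <- res[res$term == "t", ]
  expect_equal(row$tp, 10L)
  expect_equal(row$p, 1 / choose(100, 10))
  expect_equal(row$mcc, 1.0)
  expect_true(row$enriched)

  # a term annotating the whole network can never be informative
  ann_all <- data.frame(gene = genes, term = "t", evidence = "EXP")
  res_all <- enrich_subgraphs(sub, annotation_map(onto, ann_all,
                                                  propagate = FALSE), genes)
  expect_equal(res_all$mcc[res_all$term == "t"], 0)
  expect_equal(res_all$p[res_all$term == "t"], 1)

  # disjoint subgraph: tp = 0, p = 1
  sub2 <- fake_subgraph(genes[50:59], "net", "s2")
  res2 <- enrich_subgraphs(sub2, amap, genes)
  expect_equal(res2$p[res2$term == "t"], 1)
  expect_false(res2$enriched[res2$term == "t"])
})

test_that("enrichment p agrees with enumeration on small universes", {
  onto <- toy_ontology()
  for (N in c(8, 15, 25)) {
    genes <- sprintf("h%02d", 1:N)
    for (K in c(2, 4, 6)) {
      ann <- data.frame(gene = genes[1:K], term = "t", evidence = "EXP")
      amap <- annotation_map(onto, ann, propagate = FALSE)
      for (n in c(3, 5)) {
        for (tp in 0:min(K, n)) {
          sg <- c(genes[seq_len(tp)],
                  if (n > tp) genes[(K + 1):(K + n - tp)])
          res <- enrich_subgraphs(fake_subgraph(sg, "net", "s"), amap, genes)
          expect_equal(res$p[res$term == "t"], hyper_tail_enum(tp, N, K, n),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("enrichment and congruence share one MCC", {
  # counts: tp=4, fp=2, fn=3, tn per enrichment table
  expect_equal(mcc(4, 91, 2, 3), mcc(4, 91, 3, 2))
  genes <- sprintf("g%03d", 1:100)
  onto <- toy_ontology()
  ann <- data.frame(gene = genes[1:7], term = "t", evidence = "EXP")
  amap <- annotation_map(onto, ann, propagate = FALSE)
  sub <- fake_subgraph(c(genes[1:4], genes[90:91]), "net", "s")
  res <- enrich_subgraphs(sub, amap, genes)
  expect_equal(res$mcc[res$term == "t"], mcc(4, 100 - 6 - 7 + 4, 2, 3))
})

test_that("coverage counts eligible terms per namespace", {
  onto <- ontology(paste0("t", 1:5),
                   c(rep("biological_process", 4), "molecular_function"),
                   list())
  genes <- sprintf("g%02d", 1:40)
  # 4 BP terms eligible; t5 MF has a single gene -> ineligible
  ann <- data.frame(gene = c(genes[1:4], genes[5:8], genes[9:12], genes[13:16],
                             genes[1]),
                    term = c(rep(c("t1", "t2", "t3", "t4"), each = 4), "t5"),
                    evidence = "EXP")
  amap <- annotation_map(onto, ann)
  enr <- data.frame(subgraph = "s1", term = c("t1", "t2", "t3"),
                    mcc = c(0.3, 0.9, 0.5), enriched = TRUE)
  cov <- coverage(enr, amap, onto, genes)
  bp <- cov[cov$namespace == "biological_process", ]
  expect_equal(bp$total_terms, 4L)
  expect_equal(bp$enriched_terms, 3L)
  expect_equal(bp$coverage_pct, 75)
  mf <- cov[cov$namespace == "molecular_function", ]
  expect_equal(mf$total_terms, 0L)
  expect_equal(mf$coverage_pct, 0)
  expect_false(mf$any_enriched)

  # max-then-mean: a term enriched twice contributes its best MCC
  enr2 <- data.frame(subgraph = c("s1", "s2"), term = "t1",
                     mcc = c(0.3, 0.9), enriched = TRUE)
  cov2 <- coverage(enr2, amap, onto, genes)
  expect_equal(cov2$avg_mcc[cov2$namespace == "biological_process"], 0.9)
})

test_that("co-enrichment pairs classify by namespace and ancestry", {
  onto <- toy_ontology()
  enr <- data.frame(subgraph = c("s1", "s1", "s1"),
                    term = c("t", "m", "u"), mcc = 0.5, enriched = TRUE)
  ce <- coenrichment_pairs(enr, onto)
  expect_equal(nrow(ce$pairs), 3L)
  cls <- ce$pairs$class[ce$pairs$term_a == "m" & ce$pairs$term_b == "t"]
  expect_equal(cls, "same_ontology_related")
  expect_equal(ce$pairs$class[ce$pairs$term_b == "u"],
               rep("different_ontology", 2))
  expect_equal(sum(ce$summary$pairs), 3L)
  expect_equal(sum(ce$summary$pct), 100)

  novel <- novel_coenrichment(ce$pairs,
                              list(ce$pairs[ce$pairs$term_b != "u", ]))
  expect_equal(nrow(novel), 2L)
})

test_that("annotation randomization permutes profiles but keeps their sizes", {
  onto <- toy_ontology()
  ann <- data.frame(gene = c("g1", "g1", "g1", "g2", "g3"),
                    term = c("t", "m", "u", "u", "t"), evidence = "EXP")
  amap <- annotation_map(onto, ann, propagate = FALSE)
  r1 <- randomize_annotations(amap, seed = 4)
  expect_setequal(names(r1), names(amap))
  expect_equal(sort(unname(lengths(r1))), sort(unname(lengths(amap))))
  expect_setequal(unlist(r1, use.names = FALSE), unlist(amap, use.names = FALSE))
  expect_identical(r1, randomize_annotations(amap, seed = 4))

  single <- structure(list(g1 = "t"), class = "congru_annotations")
  expect_identical(randomize_annotations(single, 1)[["g1"]], "t")
  expect_error(randomize_annotations(structure(list(),
                                               class = "congru_annotations"), 1),
               "empty")
})

test_that("relative enrichment by term size is a difference of proportions", {
  onto <- ontology(paste0("b", 1:4), rep("biological_process", 4), list())
  genes <- sprintf("g%02d", 1:60)
  ann <- data.frame(gene = c(genes[1:3], genes[4:6], genes[10:19], genes[20:29]),
                    term = rep(c("b1", "b2", "b3", "b4"), c(3, 3, 10, 10)),
                    evidence = "EXP")
  amap <- annotation_map(onto, ann)
  # enriched: both small terms, neither large term
  enr <- data.frame(subgraph = "s", term = c("b1", "b2"), mcc = 0.9,
                    enriched = TRUE)
  out <- relative_enrichment_by_term_size(enr, amap, genes,
                                          breaks = c(2, 5, Inf))
  expect_equal(out$relative_enrichment, c(0.5, -0.5))
  expect_equal(sum(out$relative_enrichment), 0, tolerance = 1e-12)

  # identical distributions cancel exactly
  enr_all <- data.frame(subgraph = "s", term = c("b1", "b2", "b3", "b4"),
                        mcc = 0.9, enriched = TRUE)
  out2 <- relative_enrichment_by_term_size(enr_all, amap, genes,
                                           breaks = c(2, 5, Inf))
  expect_true(all(out2$relative_enrichment == 0))

  expect_error(relative_enrichment_by_term_size(
    enr[0, ], amap, genes, breaks = c(2, 5, Inf)), "no enriched")
})
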