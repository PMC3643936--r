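test_that("designs validate their geometry", {
  expect_error(planted_design(p_in = 0.1, p_out = 0.5), "p_out")
  expect_error(planted_design(n_genes = 20, module_size = 12,
                              layer_modules = list(a = 1:2, b = 1:2)), "fit")
  d <- bench_a_design()
  expect_length(d$modules, 9L)
  expect_equal(d$shared, 1:6)
  expect_equal(d$split_modules, 9L)
  expect_equal(nrow(d$riders), 18L)
  expect_true(all(d$riders$module %in% d$shared))
  # modules are disjoint gene blocks
  expect_equal(anyDuplicated(unlist(d$modules)), 0L)
})

test_that("degenerate probabilities give a clique plus isolated genes", {
  d <- planted_design(n_genes = 20, module_size = 5,
                      layer_modules = list(a = 1, b = 1),
                      p_in = 1, p_out = 0,
                      seeds = c(layers = 1L, calls = 2L, ontology = 3L))
  layers <- generate_layers(d)
  a <- layers$a
  expect_equal(nrow(a$edges), choose(5, 2))
  expect_setequal(unique(c(a$edges$from, a$edges$to)), d$modules[[1]])
  expect_length(a$nodes, 20L)          # isolated genes stay listed
})

test_that("edge counts match binomial expectations", {
  d <- planted_design(n_genes = 500, module_size = 12,
                      layer_modules = list(a = 1:4, b = 1:4),
                      p_in = 0.6, p_out = 0.02,
                      seeds = c(layers = 8L, calls = 2L, ontology = 3L))
  layers <- generate_layers(d)
  intra_pairs <- 4 * choose(12, 2)
  other_pairs <- choose(500, 2) - intra_pairs
  expectation <- intra_pairs * 0.6 + other_pairs * 0.02
  sdev <- sqrt(intra_pairs * 0.6 * 0.4 + other_pairs * 0.02 * 0.98)
  for (l in layers)
    expect_lt(abs(nrow(l$edges) - expectation), 3 * sdev)
})

test_that("layer generation is deterministic and shares planted modules", {
  d <- bench_a_design()
  l1 <- generate_layers(d)
  l2 <- generate_layers(d)
  expect_identical(l1, l2)
  # shared modules have identical ground-truth gene sets across layers
  for (m in d$shared) expect_identical(d$modules[[m]], d$modules[[m]])
  # private modules are dense only in their own layer
  dens <- function(net, genes) {
    e <- net$edges
    sum(e$from %in% genes & e$to %in% genes) / choose(length(genes), 2)
  }
  expect_gt(dens(l1$ppi, d$modules[[7]]), 0.4)
  expect_lt(dens(l1$genetic, d$modules[[7]]), 0.1)
  expect_gt(dens(l1$genetic, d$modules[[8]]), 0.4)
  expect_lt(dens(l1$ppi, d$modules[[8]]), 0.1)
  # the split module is thin everywhere but restored in the union
  expect_lt(dens(l1$ppi, d$modules[[9]]), 0.35)
  expect_lt(dens(l1$genetic, d$modules[[9]]), 0.35)
  un <- combine_networks(l1)
  expect_gt(dens(un, d$modules[[9]]), 0.3)
})

test_that("rider genes carry interactions of exactly one data type", {
  d <- bench_a_design()
  layers <- generate_layers(d)
  calls <- generate_treatment_calls(d)
  for (i in seq_len(nrow(d$riders))) {
    r <- d$riders[i, ]
    expect_equal(r$gene %in% layers$ppi$nodes, r$type == "ppi")
    expect_equal(r$gene %in% layers$genetic$nodes, r$type == "genetic")
    expect_equal(r$gene %in% rownames(calls$calls), r$type == "coreg")
  }
})

test_that("treatment calls mirror module activity", {
  d <- planted_design(n_genes = 60, module_size = 10,
                      layer_modules = list(a = 1:2, b = 1:2),
                      p_in = 0.9, p_out = 0.01,
                      seeds = c(layers = 1L, calls = 9L, ontology = 3L))
  # one always-active module, clean calls: perfect intra-module co-regulation
  calls <- generate_treatment_calls(d, n_treatments = 20,
                                    p_active_module = 1, p_call = 1,
                                    p_background = 0)
  net <- build_coregulation_network(calls)
  m1 <- d$modules[[1]]
  intra <- net$edges$from %in% m1 & net$edges$to %in% m1
  expect_equal(sum(intra), choose(10, 2))
  expect_true(all(net$edges$weight[intra] == 1))

  # expected co-call count for a same-module pair within 3 sigma
  calls2 <- generate_treatment_calls(d, n_treatments = 200,
                                     p_active_module = 0.3, p_call = 0.9,
                                     p_background = 0)
  pair <- calls2$calls[d$modules[[1]][1:2], ]
  cb <- sum(pair[1, ] & pair[2, ])
  p_both <- 0.3 * 0.81
  expect_lt(abs(cb - 200 * p_both), 3 * sqrt(200 * p_both * (1 - p_both)))

  # modules never co-active produce no cross-module edges
  calls3 <- generate_treatment_calls(d, n_treatments = 30,
                                     p_active_module = 0, p_call = 1,
                                     p_background = 0)
  expect_equal(nrow(build_coregulation_network(calls3)$edges), 0L)
})

test_that("the synthetic ontology aligns leaf terms to modules", {
  d <- planted_design(n_genes = 200, module_size = 10,
                      layer_modules = list(a = 1:3, b = 1:3),
                      p_in = 0.6, p_out = 0.02, annotation_noise = 0,
                      seeds = c(layers = 1L, calls = 2L, ontology = 12L))
  ob <- generate_ontology(d, background_terms = 4, size_spectrum = c(4, 6))
  onto <- ob$ontology
  ann <- ob$annotations
  # noise-free leaf terms annotate their module exactly
  for (nsname in names(ob$leaf_terms)) {
    lt <- ob$leaf_terms[[nsname]][["M1"]]
    expect_setequal(ann$gene[ann$term == lt], d$modules[[1]])
  }
  # after propagation the root covers every annotated gene
  amap <- annotation_map(onto, ann)
  bp_root <- "BP:ROOT"
  covered <- names(amap)[vapply(amap, function(ts) bp_root %in% ts, logical(1))]
  bp_terms <- onto$terms[onto$namespace == "biological_process"]
  annotated_bp <- unique(ann$gene[ann$term %in% bp_terms])
  expect_setequal(covered, annotated_bp)
  # background terms follow the requested size spectrum
  bg <- grep("^BP:BG", onto$terms, value = TRUE)
  sizes <- sort(as.vector(table(ann$term[ann$term %in% bg])))
  expect_equal(sizes, sort(rep(c(4, 6), 2)))
  # determinism
  expect_identical(generate_ontology(d, background_terms = 4,
                                     size_spectrum = c(4, 6)), ob)
})

test_that("ground truth serialises to JSON", {
  d <- bench_a_design()
  f <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(d, f)
  gt <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(gt$n_genes, 500L)
  expect_equal(gt$modules$M1, d$modules$M1)
  expect_equal(gt$seeds$layers, 11L)
})
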