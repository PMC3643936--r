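test_that("MCC follows its closed form with the zero-denominator convention", {
  expect_equal(mcc(5, 5, 0, 0), 1.0)
  expect_equal(mcc(8, 2, 2, 2), 0.3)
  expect_equal(mcc(0, 0, 3, 3), -1.0)
  expect_equal(mcc(3, 0, 2, 0), 0)     # a zero factor in the denominator
  expect_error(mcc(0, 0, 0, 0), "zero")
})

test_that("MCC is symmetric under swapping the two subgraph roles", {
  set.seed(31)
  for (i in 1:1000) {
    v <- sample(0:30, 4, replace = TRUE)
    if (sum(v) == 0) v[1] <- 1
    expect_identical(mcc(v[1], v[2], v[3], v[4]), mcc(v[1], v[2], v[4], v[3]))
  }
})

test_that("overlap P values hit the closed forms", {
  g <- sprintf("g%02d", 1:20)
  a <- fake_subgraph(g[1:5], "ppi", "a1")
  b <- fake_subgraph(g[1:5], "gen", "b1")
  hit <- overlap_test(a, b, universe = g, n_min = 3, m_min = -1)
  expect_equal(hit$p, 1 / choose(20, 5))
  expect_equal(hit$tp, 5L)

  # disjoint pair: filtered before any P value
  d <- fake_subgraph(g[6:10], "gen", "b2")
  hd <- overlap_test(a, d, universe = g)
  expect_false(hd$passes)
  expect_true(is.na(hd$p))

  expect_error(overlap_test(a, fake_subgraph(g[1:5], "ppi", "a2"), g),
               "different layers")
  expect_error(overlap_test(a, fake_subgraph(g[6:10], "gen", "bx"),
                            universe = g[1:7]), "universe smaller")

  big <- fake_subgraph(sprintf("x%02d", 1:60), "gen", "b3")
  expect_false(overlap_test(a, big, universe = c(g, big$genes))$passes)
})

test_that("overlap P values agree with exhaustive enumeration", {
  for (N in c(10, 18, 25)) {
    uni <- sprintf("u%02d", seq_len(N))
    for (K in c(3, 5, 7)) {
      for (n in c(3, 5, 7)) {
        for (tp in 3:min(K, n)) {
          a <- fake_subgraph(uni[1:K], "ppi", "a")
          bg <- c(uni[seq_len(tp)],
                  if (n > tp) uni[(K + 1):(K + n - tp)])
          b <- fake_subgraph(bg, "gen", "b")
          hit <- overlap_test(a, b, universe = uni, n_min = 1, m_min = -1)
          expect_equal(hit$p, hyper_tail_enum(tp, N, K, n), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("the congruence MCC uses the union-minus-intersection true negatives", {
  g <- sprintf("g%02d", 1:50)
  a <- fake_subgraph(g[1:10], "ppi", "a")
  b <- fake_subgraph(g[3:12], "gen", "b")
  hit <- overlap_test(a, b, universe = g, n_min = 1, m_min = -1)
  tp <- 8; un <- 12
  expect_equal(hit$mcc, mcc(tp, un - tp, 2, 2))
})

test_that("batch scoring matches pairwise scoring", {
  set.seed(17)
  uni <- sprintf("g%03d", 1:60)
  # overlapping pairs: each b-subgraph shares a core with its a-partner
  subs_a <- lapply(1:6, function(i) fake_subgraph(sample(uni, 8),
                                                  "ppi", paste0("a", i)))
  subs_b <- lapply(1:6, function(i)
    fake_subgraph(c(sample(subs_a[[i]]$genes, 5),
                    sample(setdiff(uni, subs_a[[i]]$genes), 4)),
                  "gen", paste0("b", i)))
  tab <- score_overlaps(subs_a, subs_b, universe = uni, n_min = 3, m_min = 0.2)
  expect_gt(nrow(tab), 0L)
  for (i in seq_len(nrow(tab))) {
    a <- subs_a[[match(tab$a[i], vapply(subs_a, `[[`, "", "id"))]]
    b <- subs_b[[match(tab$b[i], vapply(subs_b, `[[`, "", "id"))]]
    hit <- overlap_test(a, b, universe = uni, n_min = 3, m_min = 0.2)
    expect_equal(tab$p[i], hit$p)
    expect_equal(tab$mcc[i], hit$mcc)
  }
})

test_that("BH correction and best-hit flags follow the step-up rule", {
  hits <- data.frame(a = paste0("a", 1:4), b = paste0("b", 1:4),
                     layer_a = "ppi", layer_b = "gen",
                     size_a = 5L, size_b = 5L, tp = 4L,
                     mcc = c(0.9, 0.4, 0.5, 0.6),
                     p = c(0.01, 0.02, 0.03, 0.04), stringsAsFactors = FALSE)
  out <- call_best_hits(hits, fdr_alpha = 0.05)
  expect_equal(out$q, rep(0.04, 4))
  expect_true(all(out$significant))

  # one subgraph with two significant hits: only the larger MCC is its best
  h2 <- data.frame(a = "a1", b = c("b1", "b2"), layer_a = "ppi",
                   layer_b = "gen", size_a = 5L, size_b = 5L, tp = 4L,
                   mcc = c(0.9, 0.4), p = c(0.001, 0.001),
                   stringsAsFactors = FALSE)
  o2 <- call_best_hits(h2)
  expect_equal(o2$best_ab, c(TRUE, FALSE))

  # A<->B mutual, A->C one-way: only the A-B pair is reciprocal
  h3 <- data.frame(a = c("A", "A"), b = c("B", "C"), layer_a = "ppi",
                   layer_b = "gen", size_a = 5L, size_b = 5L, tp = 4L,
                   mcc = c(0.9, 0.5), p = c(0.001, 0.002),
                   stringsAsFactors = FALSE)
  o3 <- call_best_hits(h3)
  expect_true(o3$reciprocal[o3$b == "B"])
  expect_false(o3$reciprocal[o3$b == "C"])
  expect_true(o3$best_ba[o3$b == "C"])  # C's own best is still A
})

test_that("BH q values are monotone and bounded below by p", {
  set.seed(41)
  for (i in 1:1000) {
    m <- sample(1:30, 1)
    p <- runif(m)
    hits <- data.frame(a = paste0("a", 1:m), b = paste0("b", 1:m),
                       layer_a = "ppi", layer_b = "gen", size_a = 5L,
                       size_b = 5L, tp = 4L, mcc = 0.5, p = p,
                       stringsAsFactors = FALSE)
    q <- call_best_hits(hits)$q
    expect_true(all(q >= p - 1e-12))
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-12))
    expect_equal(q, p.adjust(p, "BH"))
  }
})

test_that("the best-hit graph, degrees and high-degree neighbourhoods", {
  hits <- data.frame(a = c("X", "X", "X"), b = c("u", "v", "w"),
                     layer_a = "ppi", layer_b = "gen", size_a = 5L,
                     size_b = 5L, tp = 4L, mcc = 0.5, p = 1e-4,
                     stringsAsFactors = FALSE)
  g <- build_best_hit_graph(call_best_hits(hits))
  expect_equal(unname(g$degree["X"]), 3L)

  deg_graph <- structure(list(
    edges = data.frame(a = c("h", "h", "h", "h", "h", "h", "h", "h", "h",
                             "p", "q", "r", "s"),
                       b = c(paste0("n", 1:9), paste0("m", 1:4)),
                       reciprocal = FALSE),
    degree = c(h = 9L, p = 1L, q = 1L, r = 1L, s = 1L)),
    class = "congru_besthits")
  hd <- high_degree(deg_graph, percentile = 90)
  expect_equal(hd$high_degree, "h")
  expect_setequal(hd$neighbourhood, c("h", paste0("n", 1:9)))

  empty <- structure(list(edges = data.frame(a = character(), b = character(),
                                             reciprocal = logical()),
                          degree = integer()), class = "congru_besthits")
  expect_length(high_degree(empty)$high_degree, 0L)
})

test_that("merged reciprocal pairs carry betweenness annotations", {
  lay1 <- network(data.frame(from = c("A", "B"), to = c("B", "C")), layer = "ppi")
  lay2 <- network(data.frame(from = "A", to = "C"), layer = "gen")
  a <- fake_subgraph(c("A", "B"), "ppi", "a")
  b <- fake_subgraph(c("B", "C"), "gen", "b")

  m <- merge_subgraphs(a, b, list(lay1, lay2), check_reciprocal = FALSE)
  expect_setequal(m$genes, c("A", "B", "C"))
  expect_equal(nrow(m$edges), 3L)
  expect_true(all(c("ppi", "gen") %in% m$edges$source))
  # triangle: no betweenness anywhere
  expect_true(all(m$node_betweenness == 0))

  # path A-B-C: one shortest path through B
  pa <- merge_subgraphs(a, b, list(lay1), check_reciprocal = FALSE)
  expect_equal(unname(pa$node_betweenness["B"]), 1)

  # star: centre carries all C(4,2) leaf-pair paths
  star <- network(data.frame(from = "Z", to = c("l1", "l2", "l3", "l4")),
                  layer = "ppi")
  sa <- fake_subgraph(c("Z", "l1", "l2"), "ppi", "sa")
  sb <- fake_subgraph(c("Z", "l3", "l4"), "gen", "sb")
  ms <- merge_subgraphs(sa, sb, list(star), check_reciprocal = FALSE)
  expect_equal(unname(ms$node_betweenness["Z"]), 6)

  # reciprocity is enforced when a hits table is supplied
  hits <- data.frame(a = "a", b = "b", reciprocal = FALSE)
  expect_error(merge_subgraphs(a, b, list(lay1, lay2), hits = hits),
               "reciprocal")
})

test_that("shared edges between layers collapse with both source tags", {
  l1 <- network(data.frame(from = "A", to = "B"), layer = "ppi")
  l2 <- network(data.frame(from = "A", to = "B"), layer = "gen")
  m <- merge_subgraphs(fake_subgraph(c("A", "B"), "ppi", "x"),
                       fake_subgraph(c("A", "B"), "gen", "y"),
                       list(l1, l2), check_reciprocal = FALSE)
  expect_equal(nrow(m$edges), 1L)
  expect_equal(m$edges$source, "ppi,gen")
})
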