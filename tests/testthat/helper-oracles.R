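# Independent oracles used across the suite.

# Upper-tail hypergeometric by explicit enumeration of the tail:
# P(X >= tp) drawing n from a universe of N with K successes.
hyper_tail_enum <- function(tp, N, K, n) {
  js <- max(tp, 0):min(K, n)
  if (length(js) == 0L || tp > min(K, n)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Floyd-Warshall all-pairs shortest paths on an edge length matrix.
fw_distances <- function(nodes, edges, lengths) {
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  for (i in seq_len(nrow(edges))) {
    a <- match(edges$from[i], nodes); b <- match(edges$to[i], nodes)
    D[a, b] <- min(D[a, b], lengths[i])
    D[b, a] <- D[a, b]
  }
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

# Erdos-Renyi congru_network over `n` nodes.
random_network <- function(n, p, weighted = FALSE, layer = "rand") {
  nodes <- sprintf("v%02d", seq_len(n))
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p
  e <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                  stringsAsFactors = FALSE)
  if (weighted) e$weight <- stats::runif(nrow(e), 0.2, 3)
  network(e, layer = layer, nodes = nodes, weighted = weighted)
}

# Minimal subgraph stand-in for congruence/enrichment tests.
fake_subgraph <- function(genes, layer, id = paste0(layer, "_", genes[1]),
                          edges = NULL) {
  if (is.null(edges))
    edges <- data.frame(from = genes[-length(genes)], to = genes[-1],
                        weight = 1, stringsAsFactors = FALSE)
  s <- structure(list(id = id, layer = layer, k_origin = 2L,
                      genes = sort(genes), edges = edges,
                      density = NA_real_, validation_p = NA_real_),
                 class = "congru_subgraph")
  s
}

# disjoint union of m cliques of the given size
clique_union <- function(m, size) {
  edges <- do.call(rbind, lapply(seq_len(m), function(ci) {
    genes <- sprintf("c%d_%d", ci, seq_len(size))
    p <- t(utils::combn(genes, 2))
    data.frame(from = p[, 1], to = p[, 2], stringsAsFactors = FALSE)
  }))
  network(edges, layer = "cliques")
}
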