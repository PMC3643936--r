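#' Candidate subgraphs from one partition
#'
#' For each part of the partition, the induced subgraph of the source network
#' is taken and its largest connected component kept, provided it has at
#' least `min_nodes` nodes (partitioners always cut the whole graph into `k`
#' parts, so small or fragmented parts are not bona fide localities).
#'
#' @param net the source `congru_network`.
#' @param partition a `congru_partition` of `net`.
#' @param min_nodes smallest admissible component (default 3).
#' @return List of `congru_subgraph` objects (possibly empty).  Each carries
#'   its gene set, induced edges, source layer, originating k and edge
#'   density; `validation_p` is `NA` until [validate_cohort()] is run.
#' @export
extract_subgraphs <- function(net, partition, min_nodes = 3) {
  asg <- partition$assignment
  e <- net$edges
  same <- asg[e$from] == asg[e$to]
  parts <- sort(unique(asg))
  out <- list()
  for (p in parts) {
    genes_p <- names(asg)[asg == p]
    ep <- e[same & asg[e$from] == p, , drop = FALSE]
    if (length(genes_p) < min_nodes) next
    comp <- component_membership(genes_p, ep)
    sizes <- table(comp)
    big <- names(sizes)[which.max(sizes)]
    keep <- names(comp)[comp == big]
    if (length(keep) < min_nodes) next
    eg <- ep[ep$from %in% keep & ep$to %in% keep, , drop = FALSE]
    out[[length(out) + 1L]] <-
      subgraph(genes = sort(keep, method = "radix"), edges = eg,
                   layer = net$layer, k_origin = partition$k)
  }
  out
}

# connected-component labels for a node set with the given edges
component_membership <- function(nodes, edges) {
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")], directed = FALSE,
                                     vertices = data.frame(name = nodes))
  stats::setNames(igraph::components(g)$membership, nodes)
}

#' Construct a subgraph object
#'
#' @param genes character vector of member genes.
#' @param edges induced edge data frame (`from`, `to`, optional `weight`).
#' @param layer source network label.
#' @param k_origin integer vector of originating partition resolutions.
#' @param validation_p path-length validation P value (NA until validated).
#' @return A `congru_subgraph`.
#' @export
subgraph <- function(genes, edges, layer, k_origin, validation_p = NA_real_) {
  rownames(edges) <- NULL
  structure(list(id = NA_character_, layer = layer,
                 k_origin = as.integer(k_origin),
                 genes = genes, edges = edges,
                 density = subgraph_density(length(genes), nrow(edges)),
                 validation_p = validation_p),
            class = "congru_subgraph")
}

subgraph_density <- function(n, e) if (n >= 2) 2 * e / (n * (n - 1)) else NA_real_

#' @export
print.congru_subgraph <- function(x, ...) {
  cat(sprintf("<congru_subgraph> %s [%s, k=%s]: %d genes, %d edges, density %.3f\n",
              x$id %||% "?", x$layer, paste(x$k_origin, collapse = ","),
              length(x$genes), nrow(x$edges), x$density))
  invisible(x)
}

#' Collapse subgraphs with identical gene sets
#'
#' De-duplication key is the gene set alone: the same locality recovered at
#' several resolutions is kept once, with every originating k recorded.
#' Surviving subgraphs get stable ids `<layer>_sg<order>`.
#'
#' @param subs list of `congru_subgraph` objects from one network's run.
#' @return List of unique `congru_subgraph` objects.
#' @export
dedup_subgraphs <- function(subs) {
  if (length(subs) == 0L) return(subs)
  keys <- vapply(subs, function(s) paste(s$genes, collapse = "|"), character(1))
  first <- !duplicated(keys)
  kept <- subs[first]
  kmap <- split(unlist(lapply(subs, function(s) s$k_origin[1])), keys)
  for (i in seq_along(kept)) {
    key <- paste(kept[[i]]$genes, collapse = "|")
    kept[[i]]$k_origin <- sort(unique(as.integer(kmap[[key]])))
    kept[[i]]$id <- sprintf("%s_sg%04d", kept[[i]]$layer, i)
  }
  kept
}

#' Shortest-path distances from a node set
#'
#' Dijkstra distances from each listed node to every network node.  Edge
#' lengths are 1 on unweighted layers and `1 / weight` on weighted layers, so
#' strongly interacting pairs are close.  Unreachable pairs are `Inf`.
#'
#' @param net a `congru_network`.
#' @param nodes source nodes (subset of `net$nodes`); default all.
#' @return Numeric matrix, rows = `nodes`, columns = all network nodes.
#' @export
all_pairs_distances <- function(net, nodes = net$nodes) {
  stopifnot(all(nodes %in% net$nodes))
  g <- as_igraph(net)
  w <- if (net$weighted) 1 / igraph::E(g)$weight else NA
  igraph::distances(g, v = nodes, weights = w, algorithm = "dijkstra")
}

#' Validate a partition's subgraphs by the path-length t-test
#'
#' A bona fide locality should have a smaller mean internal path length than
#' its mean path lengths to the other subgraphs of the same partition.  For
#' each subgraph the mean intra-subgraph distance (over reachable ordered
#' pairs) and the mean inter-subgraph distance to every other cohort subgraph
#' are computed on the full source network; a one-sample, one-tailed t-test
#' then asks whether the inter means exceed the intra mean.  Subgraphs with
#' `p >= alpha` are discarded by the pipeline.  With fewer than two other
#' subgraphs the test is not applicable and `validation_p` stays `NA`.
#'
#' @param subs list of `congru_subgraph` objects from one partition.
#' @param net the source network.
#' @param dist optional precomputed distance matrix over (at least) the
#'   cohort's genes, as from [all_pairs_distances()].
#' @return `subs` with `validation_p` filled in.
#' @export
validate_cohort <- function(subs, net, dist = NULL) {
  q <- length(subs)
  if (q < 2L) return(subs)
  genes <- sort(unique(unlist(lapply(subs, `[[`, "genes"))), method = "radix")
  if (is.null(dist)) dist <- all_pairs_distances(net, genes)
  D <- dist[genes, genes, drop = FALSE]
  Rm <- is.finite(D) * 1
  diag(Rm) <- 0
  D0 <- D
  D0[!is.finite(D0)] <- 0
  diag(D0) <- 0
  Z <- vapply(subs, function(s) as.numeric(genes %in% s$genes), numeric(length(genes)))
  S <- crossprod(Z, D0 %*% Z)
  C <- crossprod(Z, Rm %*% Z)
  M <- ifelse(C > 0, S / C, NA_real_)   # mean distances between/within cohorts
  for (i in seq_len(q)) {
    intra <- M[i, i]
    inter <- M[i, -i]
    inter <- inter[!is.na(inter)]
    subs[[i]]$validation_p <-
      if (length(inter) < 2L || is.na(intra) || stats::sd(inter) == 0) NA_real_
      else stats::t.test(inter, mu = intra, alternative = "greater")$p.value
  }
  subs
}

#' Path-length validation P value for a single subgraph
#'
#' Convenience wrapper around [validate_cohort()] for one subgraph against
#' its cohort.
#'
#' @param sub a `congru_subgraph`.
#' @param cohort list of subgraphs from the same partition (including `sub`).
#' @param net the source network.
#' @param alpha significance threshold used by the pipeline (default 0.05).
#' @return List with `p` (or `NA` when not applicable) and `keep`.
#' @export
validate_subgraph <- function(sub, cohort, net, alpha = 0.05) {
  key <- paste(sub$genes, collapse = "|")
  keys <- vapply(cohort, function(s) paste(s$genes, collapse = "|"), character(1))
  if (!key %in% keys) cohort <- c(cohort, list(sub))
  cohort <- validate_cohort(cohort, net)
  keys <- vapply(cohort, function(s) paste(s$genes, collapse = "|"), character(1))
  p <- cohort[[match(key, keys)]]$validation_p
  list(p = p, keep = is.na(p) || p < alpha)
}

#' Edge density of a subgraph
#'
#' Proportion of all possible gene-gene pairs that are connected:
#' `d = 2 e / (n (n - 1))`.
#'
#' @param sub a `congru_subgraph` (or any list with `genes` and `edges`).
#' @return Density in `[0, 1]`.
#' @export
edge_density <- function(sub) {
  n <- length(sub$genes)
  if (n < 2) stop("edge density needs at least 2 nodes")
  2 * nrow(sub$edges) / (n * (n - 1))
}

#' Weighted density of a subgraph
#'
#' `h = 2 w / (wbar * n (n - 1))` where `w` is the summed induced edge weight
#' and `wbar` the mean edge weight of the whole source network; reduces to
#' [edge_density()] when all weights equal `wbar`.
#'
#' @param sub a `congru_subgraph`.
#' @param network_mean_weight mean edge weight of the source network (> 0).
#' @return Non-negative weighted density.
#' @export
weighted_density <- function(sub, network_mean_weight) {
  if (network_mean_weight <= 0) stop("network mean weight must be positive")
  n <- length(sub$genes)
  if (n < 2) stop("weighted density needs at least 2 nodes")
  2 * sum(sub$edges$weight) / (network_mean_weight * n * (n - 1))
}

#' Write one edge-list file per subgraph
#'
#' Each subgraph's induced edges are written in the edge-list dialect of
#' [write_edge_list()], named `<id>.txt`.
#'
#' @param subs list of `congru_subgraph` objects.
#' @param dir output directory (created if needed).
#' @param weighted write the weight column (default: only when weights
#'   differ from 1).
#' @return The directory, invisibly.
#' @export
write_subgraph_edge_lists <- function(subs, dir, weighted = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in subs) {
    w <- if (is.null(weighted)) !all(s$edges$weight == 1) else weighted
    net <- network(s$edges, layer = s$id, nodes = s$genes, weighted = w)
    write_edge_list(net, file.path(dir, paste0(s$id, ".txt")))
  }
  invisible(dir)
}

#' Subgraph catalogue as a data frame
#'
#' @param subs list of `congru_subgraph` objects.
#' @return Data frame with id, layer, k list, size, density, validation P and
#'   the gene list (comma-separated).
#' @export
subgraph_catalogue <- function(subs) {
  data.frame(
    id = vapply(subs, `[[`, character(1), "id"),
    layer = vapply(subs, `[[`, character(1), "layer"),
    k = vapply(subs, function(s) paste(s$k_origin, collapse = ","), character(1)),
    size = vapply(subs, function(s) length(s$genes), integer(1)),
    density = vapply(subs, `[[`, numeric(1), "density"),
    validation_p = vapply(subs, `[[`, numeric(1), "validation_p"),
    genes = vapply(subs, function(s) paste(s$genes, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
}
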