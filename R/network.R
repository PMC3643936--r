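#' Construct an interaction network layer
#'
#' A network layer is an undirected, simple graph whose nodes are gene
#' identifiers and whose edges carry a positive weight (1 for unweighted
#' layers, e.g. physical or genetic interactions).  Edges are stored in a
#' canonical orientation (`from < to` lexicographically) and sorted, so two
#' networks with the same content are identical object-for-object.
#'
#' @param edges data frame with columns `from`, `to` and optionally `weight`.
#' @param layer layer label, e.g. `"ppi"`.
#' @param nodes optional character vector of node identifiers; defaults to the
#'   genes appearing in `edges`.  Extra entries keep isolated nodes.
#' @param weighted logical; whether the layer carries meaningful weights.
#' @return An object of class `congru_network` with fields `layer`, `nodes`,
#'   `edges` (canonical data frame) and `weighted`.
#' @examples
#' net <- network(data.frame(from = c("A", "B"), to = c("B", "C")), layer = "toy")
#' net
#' @export
network <- function(edges, layer = "network", nodes = NULL, weighted = NULL) {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("from", "to") %in% names(edges)))
    stop("edges must have 'from' and 'to' columns")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (is.null(edges$weight)) {
    edges$weight <- rep(1, nrow(edges))
    if (is.null(weighted)) weighted <- FALSE
  }
  if (is.null(weighted)) weighted <- !all(edges$weight == 1)
  if (any(edges$from == edges$to))
    stop("self-loops are not allowed")
  if (any(!is.finite(edges$weight)) || any(edges$weight <= 0))
    stop("edge weights must be positive and finite")
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]
  edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  key <- paste(edges$from, edges$to, sep = "\t")
  if (anyDuplicated(key))
    stop("duplicate edges: ", paste(utils::head(key[duplicated(key)], 3), collapse = ", "))
  ord <- order(edges$from, edges$to, method = "radix")
  edges <- edges[ord, c("from", "to", "weight"), drop = FALSE]
  rownames(edges) <- NULL
  all_nodes <- sort(unique(c(edges$from, edges$to, as.character(nodes))), method = "radix")
  structure(list(layer = layer, nodes = all_nodes, edges = edges,
                 weighted = weighted),
            class = "congru_network")
}

#' @export
print.congru_network <- function(x, ...) {
  cat(sprintf("<congru_network> layer '%s': %d nodes, %d edges (%s)\n",
              x$layer, length(x$nodes), nrow(x$edges),
              if (x$weighted) "weighted" else "unweighted"))
  invisible(x)
}

n_edges <- function(net) nrow(net$edges)

edge_keys <- function(net) paste(net$edges$from, net$edges$to, sep = "\t")

#' Convert a network layer to an igraph graph
#'
#' @param net a `congru_network`.
#' @return An undirected `igraph` graph with a `weight` edge attribute.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  g
}

#' Read a network from an edge-list file
#'
#' The dialect is a plain-text edge list whose first non-comment line is the
#' number of edges, followed by one edge per line: two whitespace-separated
#' node fields and, for weighted files, a third numeric weight field.  Lines
#' starting with `#` are ignored.  Declared-count mismatches, self-loops and
#' duplicate (unordered) edges are format errors.
#'
#' @param path file path.
#' @param weighted logical; expect a third weight column.
#' @param layer layer label for the returned network.
#' @param lookup optional named character vector mapping file node ids to gene
#'   names (see [read_gene_lookup()]); applied before the network is built.
#' @return A `congru_network`.
#' @export
read_edge_list <- function(path, weighted = FALSE, layer = NULL, lookup = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty edge-list file: ", path)
  declared <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(declared) || declared < 0)
    stop("first line must be a non-negative edge count: ", path)
  body <- lines[-1]
  if (length(body) != declared)
    stop(sprintf("edge count mismatch in %s: declared %d, found %d",
                 path, declared, length(body)))
  if (declared == 0L)
    return(network(NULL, layer = layer %||% basename(path), weighted = weighted))
  parts <- strsplit(trimws(body), "[ \t]+")
  nf <- lengths(parts)
  want <- if (weighted) 3L else 2L
  if (any(nf != want))
    stop(sprintf("malformed edge row(s) in %s (expected %d fields)", path, want))
  m <- matrix(unlist(parts), ncol = want, byrow = TRUE)
  w <- if (weighted) suppressWarnings(as.numeric(m[, 3])) else rep(1, nrow(m))
  if (any(is.na(w))) stop("non-numeric weight in ", path)
  from <- m[, 1]; to <- m[, 2]
  if (!is.null(lookup)) {
    unknown <- setdiff(c(from, to), names(lookup))
    if (length(unknown))
      stop("node ids missing from lookup: ", paste(utils::head(unknown, 3), collapse = ", "))
    from <- unname(lookup[from]); to <- unname(lookup[to])
  }
  network(data.frame(from = from, to = to, weight = w, stringsAsFactors = FALSE),
          layer = layer %||% basename(path), weighted = weighted)
}

#' Write a network to an edge-list file
#'
#' Inverse of [read_edge_list()]: first line is the edge count, then one edge
#' per line.  Weights are written (with full precision) only for weighted
#' networks, so the round trip reproduces the network exactly.
#'
#' @param net a `congru_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  e <- net$edges
  rows <- if (net$weighted) {
    paste(e$from, e$to, formatC(e$weight, format = "g", digits = 17))
  } else {
    paste(e$from, e$to)
  }
  writeLines(c(as.character(nrow(e)), rows), path)
  invisible(path)
}

#' Read a node-id to gene-name lookup table
#'
#' Two-column whitespace-separated table (id, systematic gene name); the
#' mapping must be bijective.
#'
#' @param path file path.
#' @return Named character vector: `names()` are ids, values are gene names.
#' @export
read_gene_lookup <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("id", "name"), colClasses = "character")
  if (anyDuplicated(tab$id) || anyDuplicated(tab$name))
    stop("gene lookup must be bijective")
  stats::setNames(tab$name, tab$id)
}

#' Combine network layers into an integrated weighted network
#'
#' Each layer's edge weights are first rescaled so that every layer
#' contributes the same total weight (the common constant, default 1), then
#' an edge of the combined network gets the sum of the rescaled weights of
#' that edge over all layers containing it.  The node set is the union of the
#' layer node sets.
#'
#' @param layers list of `congru_network` objects, each with at least one edge.
#' @param total common per-layer total weight after rescaling.
#' @param layer label for the combined network.
#' @return A weighted `congru_network`.
#' @export
combine_networks <- function(layers, total = 1, layer = "combined") {
  if (length(layers) < 2L) stop("need at least two layers")
  pieces <- lapply(layers, function(net) {
    s <- sum(net$edges$weight)
    if (nrow(net$edges) == 0L || s <= 0)
      stop("layer '", net$layer, "' has zero total weight")
    data.frame(key = edge_keys(net), w = net$edges$weight * (total / s),
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, pieces)
  agg <- tapply(all$w, all$key, sum)
  keys <- sort(names(agg), method = "radix")
  ft <- do.call(rbind, strsplit(keys, "\t", fixed = TRUE))
  network(data.frame(from = ft[, 1], to = ft[, 2], weight = as.numeric(agg[keys]),
                     stringsAsFactors = FALSE),
          layer = layer,
          nodes = sort(unique(unlist(lapply(layers, `[[`, "nodes"))), method = "radix"),
          weighted = TRUE)
}

#' Restrict layers to their common gene set
#'
#' Keeps only nodes present in every layer, takes the induced edges in each
#' layer, and then drops nodes left without any edge, either per layer
#' (default) or simultaneously in all layers.
#'
#' @param layers list of `congru_network` objects (>= 2).
#' @param connected_rule `"per_layer"` drops a disconnected common node from
#'   the layer where it is isolated; `"all_layers"` keeps only nodes that are
#'   connected in every layer.
#' @return List of restricted `congru_network` objects (same order/labels).
#' @export
common_gene_networks <- function(layers, connected_rule = c("per_layer", "all_layers")) {
  connected_rule <- match.arg(connected_rule)
  if (length(layers) < 2L) stop("need at least two layers")
  common <- Reduce(intersect, lapply(layers, `[[`, "nodes"))
  if (length(common) == 0L) stop("no genes common to all layers")
  induced <- lapply(layers, function(net) {
    keep <- net$edges$from %in% common & net$edges$to %in% common
    net$edges[keep, , drop = FALSE]
  })
  if (connected_rule == "all_layers") {
    keep_nodes <- Reduce(intersect, lapply(induced, function(e) unique(c(e$from, e$to))))
    induced <- lapply(induced, function(e)
      e[e$from %in% keep_nodes & e$to %in% keep_nodes, , drop = FALSE])
  }
  mapply(function(e, net) {
    network(e, layer = paste0(net$layer, "_common"), weighted = net$weighted)
  }, induced, layers, SIMPLIFY = FALSE)
}

#' Integer partitioning weights for a network
#'
#' The k-way partitioner consumes integer edge weights.  Unweighted layers
#' use weight 1.  Weighted layers are scaled and rounded to the nearest whole
#' number (half-up); `scale = "auto"` picks the scale so that the mean edge
#' weight maps to 10.  Edges rounding to 0 are dropped from the partitioning
#' view only.
#'
#' @param net a `congru_network`.
#' @param scale positive scale factor applied before rounding, or `"auto"`.
#' @return Integer vector aligned with `net$edges` rows; zeros mark dropped
#'   edges.
#' @export
partition_weights <- function(net, scale = "auto") {
  if (!net$weighted) return(rep(1L, n_edges(net)))
  if (identical(scale, "auto")) scale <- 10 / mean(net$edges$weight)
  round_half_up(net$edges$weight * scale)
}

round_half_up <- function(x) as.integer(floor(x + 0.5))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a network as GraphML
#'
#' @param net a `congru_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
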