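#' Plan the set of k values for multi-resolution partitioning
#'
#' Partitioning a network of `n` nodes into `k` parts gives parts of average
#' size `s(k) = n / k`.  To sample subgraphs at every granularity, for every
#' integer target size `i` from `min_size` up to `floor(n / 2)` the candidate
#' `k` (from `2` to `ceiling(n / min_size)`) whose average size is nearest to
#' `i` is recorded (ties resolved toward the smaller average size, i.e. the
#' larger `k`).  The distinct recorded `k` values form the plan.
#'
#' @param n node count (must be at least `2 * min_size`).
#' @param min_size smallest useful average part size (default 3).
#' @return Object of class `congru_kplan`: list with `n`, `min_size`, `k`
#'   (increasing distinct k values) and `targets` (data frame mapping each
#'   target size to its recorded k).
#' @examples
#' plan_k_values(12)$k   # 2 3 4
#' @export
plan_k_values <- function(n, min_size = 3) {
  if (n < 2 * min_size) stop("network too small to plan partitions")
  cand <- 2:ceiling(n / min_size)
  s <- n / cand
  targets <- min_size:floor(n / 2)
  rec <- vapply(targets, function(i) {
    d <- abs(s - i)
    best <- which(d == min(d))
    # tie -> smaller average size = larger k; cand increasing, s decreasing
    cand[max(best)]
  }, integer(1))
  structure(list(n = n, min_size = min_size,
                 k = sort(unique(rec)),
                 targets = data.frame(target = targets, k = rec)),
            class = "congru_kplan")
}

#' @export
print.congru_kplan <- function(x, ...) {
  cat(sprintf("<congru_kplan> n = %d: %d distinct k values (%d..%d)\n",
              x$n, length(x$k), min(x$k), max(x$k)))
  invisible(x)
}

#' Balanced k-way partition of a network
#'
#' Partitions the nodes into `k` parts of approximately equal size while
#' minimising the (integer-weighted) edge cut, in the spirit of multilevel
#' k-way partitioners such as kmetis.  The initial assignment is
#' community-aware: modularity communities (Louvain) of the weighted graph
#' are split into chunks no larger than the part size by breadth-first
#' growth and packed into the `k` parts longest-first; the assignment is
#' then refined by balance-constrained single-node moves until no move
#' strictly reduces the cut (a local optimum under single-node moves).
#' Deterministic for a fixed seed.
#'
#' @param net a `congru_network`.
#' @param k number of parts, `1 <= k <= n`.
#' @param seed integer seed for the randomised initialisation.
#' @param balance_tol maximum part size as a multiple of `n / k` (default
#'   1.10, kmetis-like).
#' @param weights integer edge weights for the cut objective, aligned with
#'   `net$edges`; defaults to [partition_weights()].  Zero-weight edges are
#'   ignored by the objective.
#' @param max_passes refinement sweep limit.
#' @return Object of class `congru_partition`: list with `k`, `assignment`
#'   (named integer vector, parts `1..k`), `cut`, `seed`, `layer`.
#' @export
partition_graph <- function(net, k, seed = 1L, balance_tol = 1.10,
                            weights = NULL, max_passes = 50L) {
  nodes <- net$nodes
  n <- length(nodes)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k exceeds node count")
  if (is.null(weights)) weights <- partition_weights(net)
  if (k == 1L) {
    part <- rep(1L, n)
  } else {
    idx <- stats::setNames(seq_len(n), nodes)
    keep <- weights > 0L
    ei <- unname(idx[net$edges$from[keep]])
    ej <- unname(idx[net$edges$to[keep]])
    ew <- as.integer(weights[keep])
    csr <- build_csr(n, ei, ej, ew)
    cap <- max(ceiling(balance_tol * n / k), ceiling(n / k))
    part <- with_seed(seed, {
      g <- igraph::graph_from_data_frame(
        data.frame(from = nodes[ei], to = nodes[ej], weight = ew),
        directed = FALSE, vertices = data.frame(name = nodes))
      init <- pack_communities(g, n, k, cap, csr)
      refine_partition_cpp(csr$ptr, csr$idx - 1L, csr$w,
                           rep(1L, n), as.integer(init - 1L),
                           as.integer(k), as.integer(cap),
                           as.integer(max_passes),
                           as.integer(sample.int(n) - 1L)) + 1L
    })
  }
  assignment <- stats::setNames(as.integer(part), nodes)
  structure(list(k = as.integer(k), assignment = assignment,
                 cut = cut_weight(net, assignment, weights),
                 seed = as.integer(seed), layer = net$layer),
            class = "congru_partition")
}

# CSR adjacency over both edge directions; ptr 0-based, idx 1-based
build_csr <- function(n, ei, ej, ew) {
  di <- c(ei, ej); dj <- c(ej, ei); dw <- c(ew, ew)
  ord <- order(di, dj, method = "radix")
  list(ptr = as.integer(cumsum(c(0L, tabulate(di, nbins = n)))),
       idx = as.integer(dj[ord]), w = as.integer(dw[ord]))
}

# Community-aware chunking: modularity communities (Louvain) are computed on
# the weighted graph; communities larger than the part size are peeled into
# chunks by greedy densest-attachment growth, so cohesive cores come out
# intact ahead of their sparse surroundings.  Chunks are packed into k
# parts, longest first, each onto the currently lightest part with room
# under `cap` (node-by-node spill when no part can take a whole chunk).
pack_communities <- function(g, n, k, cap, csr) {
  target <- ceiling(n / k)
  chunks <- list()
  top <- igraph::membership(igraph::cluster_louvain(g))
  for (cm in split(seq_len(n), as.integer(top))) {
    if (length(cm) <= target) chunks[[length(chunks) + 1L]] <- cm
    else chunks <- c(chunks, attachment_chunks(cm, target, csr, n))
  }
  chunks <- chunks[order(-lengths(chunks))]
  load <- integer(k)
  part <- integer(n)
  for (ch in chunks) {
    open <- which(load + length(ch) <= cap)
    if (length(open)) {
      p <- open[which.min(load[open])]
      part[ch] <- p
      load[p] <- load[p] + length(ch)
    } else {
      for (v in ch) {                      # spill one node at a time
        p <- which.min(load)
        part[v] <- p
        load[p] <- load[p] + 1L
      }
    }
  }
  part
}

# Peel a node set into chunks of at most `target` nodes: each chunk starts
# at the remaining node with the highest in-set degree and greedily adds the
# remaining node with the largest total edge weight into the chunk, so the
# densest substructure is extracted first.  Chunks stop early when nothing
# connected remains.
attachment_chunks <- function(nodes_in, target, csr, n) {
  inset <- rep(FALSE, n); inset[nodes_in] <- TRUE
  nbrs <- function(v) {
    if (csr$ptr[v + 1L] > csr$ptr[v]) {
      j <- (csr$ptr[v] + 1L):csr$ptr[v + 1L]
      list(idx = csr$idx[j], w = csr$w[j])
    } else list(idx = integer(0), w = integer(0))
  }
  indeg <- rep(0, n)
  for (v in nodes_in) {
    nb <- nbrs(v)
    sel <- inset[nb$idx]
    indeg[v] <- sum(nb$w[sel])
  }
  remaining <- rep(FALSE, n); remaining[nodes_in] <- TRUE
  n_left <- length(nodes_in)
  out <- list()
  conn <- rep(0, n)
  while (n_left > 0L) {
    cand <- which(remaining)
    seed <- cand[which.max(indeg[cand])]
    chunk <- integer(0)
    conn[] <- 0
    v <- seed
    repeat {
      remaining[v] <- FALSE; n_left <- n_left - 1L
      chunk <- c(chunk, v)
      if (length(chunk) >= target || n_left == 0L) break
      nb <- nbrs(v)
      sel <- remaining[nb$idx]
      conn[nb$idx[sel]] <- conn[nb$idx[sel]] + nb$w[sel]
      att <- which(conn > 0 & remaining)
      if (length(att) == 0L) break         # nothing connected left
      v <- att[which.max(conn[att])]
    }
    out[[length(out) + 1L]] <- chunk
  }
  out
}

#' Weighted cut of a partition
#'
#' Sum of (integer) weights of edges whose endpoints lie in different parts.
#'
#' @param net a `congru_network`.
#' @param assignment named part vector (as in `congru_partition$assignment`).
#' @param weights edge weights for the objective; default [partition_weights()].
#' @return Numeric cut weight.
#' @export
cut_weight <- function(net, assignment, weights = NULL) {
  if (inherits(assignment, "congru_partition")) assignment <- assignment$assignment
  if (is.null(weights)) weights <- partition_weights(net)
  sum(weights[assignment[net$edges$from] != assignment[net$edges$to]])
}

#' @export
print.congru_partition <- function(x, ...) {
  cat(sprintf("<congru_partition> layer '%s': k = %d, cut = %g, seed = %d\n",
              x$layer, x$k, x$cut, x$seed))
  invisible(x)
}

#' Write a partition as a two-column TSV (node, part)
#'
#' @param partition a `congru_partition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  utils::write.table(data.frame(node = names(partition$assignment),
                                part = unname(partition$assignment)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
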