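#' Matthews correlation coefficient from a 2x2 confusion table
#'
#' `MCC = (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`; when any
#' factor of the denominator is zero the coefficient is defined as 0.
#'
#' Used both for subgraph-intersection congruence (where, following the
#' congruence definition, `tn` is the union of the two gene sets minus the
#' intersection) and for the accuracy of term enrichment.  Vectorised.
#'
#' @param tp,tn,fp,fn non-negative counts (vectors recycle).
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(tp, tn, fp, fn) {
  if (any(tp + tn + fp + fn == 0)) stop("all counts zero")
  num <- as.numeric(tp) * tn - as.numeric(fp) * fn
  den <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
  ifelse(den == 0, 0, num / den)
}

#' Overlap test between two subgraphs from different networks
#'
#' Scores the gene intersection of two subgraphs: a hypergeometric upper-tail
#' P value for observing at least `tp` shared genes when drawing `|B|` genes
#' from a universe containing `|A|` successes, plus the MCC of the
#' intersection.  Two universes are available: `"networks"` (default), the
#' union of the two source networks' gene sets, and `"union"`, the literal
#' union of the two subgraphs (which forces the "neither" cell of the table
#' to 0 and is kept for fidelity with the congruence definition).
#'
#' The pipeline only computes P values for pairs passing the size-ratio
#' filter (sizes within `ratio_max`-fold), `tp >= n_min` and `mcc >= m_min`;
#' this function enforces the ratio filter and reports the others via
#' `passes`.
#'
#' @param a,b `congru_subgraph` objects from different layers.
#' @param universe character vector of universe genes (for the default mode,
#'   the union of the two source networks' gene sets).
#' @param n_min minimum intersection size before a P value is computed.
#' @param m_min minimum MCC before a P value is computed.
#' @param ratio_max maximum size ratio between the two gene sets.
#' @param universe_mode `"networks"` or `"union"`.
#' @return A `congru_hit` list: ids, sizes, counts (`tp`, `fp`, `fn`, `tn`),
#'   `mcc`, `p` (NA when the pre-filters fail), `passes`.
#' @export
overlap_test <- function(a, b, universe, n_min = 3, m_min = 0.2,
                         ratio_max = 10, universe_mode = c("networks", "union")) {
  universe_mode <- match.arg(universe_mode)
  if (identical(a$layer, b$layer)) stop("subgraphs must come from different layers")
  na_ <- length(a$genes); nb <- length(b$genes)
  if (max(na_, nb) / min(na_, nb) > ratio_max)
    return(structure(list(a = a$id, b = b$id, size_a = na_, size_b = nb,
                          tp = NA_integer_, mcc = NA_real_, p = NA_real_,
                          passes = FALSE), class = "congru_hit"))
  tp <- length(intersect(a$genes, b$genes))
  fp <- na_ - tp; fn <- nb - tp
  un <- na_ + nb - tp
  N <- if (universe_mode == "union") un else length(universe)
  if (N < un) stop("universe smaller than the union of the two subgraphs")
  m <- mcc(tp, un - tp, fp, fn)
  passes <- tp >= n_min && m >= m_min
  p <- if (passes) hyper_upper_tail(tp, N, na_, nb) else NA_real_
  structure(list(a = a$id, b = b$id, size_a = na_, size_b = nb,
                 tp = tp, fp = fp, fn = fn, tn = un - tp,
                 mcc = m, p = p, passes = passes),
            class = "congru_hit")
}

# P(X >= tp) for X ~ Hypergeometric(N, K successes, n draws)
hyper_upper_tail <- function(tp, N, K, n) {
  stats::phyper(tp - 1, K, N - K, n, lower.tail = FALSE)
}

#' Score all cross-network subgraph pairs
#'
#' Sparse-matrix batch version of [overlap_test()] over two subgraph
#' catalogues: computes intersections for every pair, applies the ten-fold
#' size filter and the `tp`/MCC pre-filters, and returns one row per scored
#' pair.
#'
#' @param subs_a,subs_b lists of `congru_subgraph` objects from two different
#'   networks.
#' @param universe universe gene set (union of the two networks' genes).
#' @inheritParams overlap_test
#' @return Data frame with columns a, b, layer_a, layer_b, size_a, size_b,
#'   tp, mcc, p (only pairs passing all pre-filters).
#' @export
score_overlaps <- function(subs_a, subs_b, universe, n_min = 3, m_min = 0.2,
                           ratio_max = 10, universe_mode = c("networks", "union")) {
  universe_mode <- match.arg(universe_mode)
  empty <- data.frame(a = character(), b = character(),
                      layer_a = character(), layer_b = character(),
                      size_a = integer(), size_b = integer(), tp = integer(),
                      mcc = numeric(), p = numeric(), stringsAsFactors = FALSE)
  if (length(subs_a) == 0L || length(subs_b) == 0L) return(empty)
  genes <- sort(unique(c(unlist(lapply(subs_a, `[[`, "genes")),
                         unlist(lapply(subs_b, `[[`, "genes")))), method = "radix")
  Za <- incidence_matrix(subs_a, genes)
  Zb <- incidence_matrix(subs_b, genes)
  TP <- Matrix::crossprod(Za, Zb)
  tpw <- Matrix::summary(TP)
  tpw <- tpw[tpw$x >= n_min, , drop = FALSE]
  if (nrow(tpw) == 0L) return(empty)
  sa <- Matrix::colSums(Za); sb <- Matrix::colSums(Zb)
  size_a <- sa[tpw$i]; size_b <- sb[tpw$j]; tp <- tpw$x
  ratio_ok <- pmax(size_a, size_b) / pmin(size_a, size_b) <= ratio_max
  un <- size_a + size_b - tp
  m <- mcc(tp, un - tp, size_a - tp, size_b - tp)
  keep <- ratio_ok & m >= m_min
  if (!any(keep)) return(empty)
  size_a <- size_a[keep]; size_b <- size_b[keep]; tp <- tp[keep]
  m <- m[keep]; un <- un[keep]
  N <- if (universe_mode == "union") un else length(universe)
  p <- hyper_upper_tail(tp, N, size_a, size_b)
  ids_a <- vapply(subs_a, `[[`, character(1), "id")
  ids_b <- vapply(subs_b, `[[`, character(1), "id")
  data.frame(a = ids_a[tpw$i[keep]], b = ids_b[tpw$j[keep]],
             layer_a = subs_a[[1]]$layer, layer_b = subs_b[[1]]$layer,
             size_a = as.integer(size_a), size_b = as.integer(size_b),
             tp = as.integer(tp), mcc = m, p = p, stringsAsFactors = FALSE)
}

incidence_matrix <- function(subs, genes) {
  i <- unlist(lapply(subs, function(s) match(s$genes, genes)))
  j <- rep(seq_along(subs), vapply(subs, function(s) length(s$genes), integer(1)))
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(length(genes), length(subs)))
}

#' FDR correction and best-hit calling
#'
#' Benjamini-Hochberg q values are computed over all scored tests.  Among
#' significant hits (`q < fdr_alpha`), for each subgraph and each opposing
#' layer the hit with maximal MCC is flagged as that subgraph's best hit
#' (ties broken by smaller q, then lexicographic partner id).  Reciprocal
#' best hits are mutually flagged pairs.
#'
#' @param hits data frame from [score_overlaps()] (possibly several layer
#'   pairs row-bound; the BH pool is all rows).
#' @param fdr_alpha significance threshold on q (default 0.05).
#' @return `hits` with columns `q`, `significant`, `best_ab`, `best_ba`,
#'   `reciprocal` added.
#' @export
call_best_hits <- function(hits, fdr_alpha = 0.05) {
  if (nrow(hits) == 0L) {
    hits$q <- numeric(0); hits$significant <- logical(0)
    hits$best_ab <- logical(0); hits$best_ba <- logical(0)
    hits$reciprocal <- logical(0)
    return(hits)
  }
  hits$q <- stats::p.adjust(hits$p, method = "BH")
  hits$significant <- hits$q < fdr_alpha
  hits$best_ab <- FALSE
  hits$best_ba <- FALSE
  sig <- which(hits$significant)
  if (length(sig)) {
    flag_best <- function(side_id, other_layer, other_id) {
      grp <- paste(side_id, other_layer, sep = "\r")
      ord <- order(grp, -hits$mcc[sig], hits$q[sig], other_id, method = "radix")
      sig[ord][!duplicated(grp[ord])]
    }
    hits$best_ab[flag_best(hits$a[sig], hits$layer_b[sig], hits$b[sig])] <- TRUE
    hits$best_ba[flag_best(hits$b[sig], hits$layer_a[sig], hits$a[sig])] <- TRUE
  }
  hits$reciprocal <- hits$best_ab & hits$best_ba
  hits
}

#' Best-hit graph over subgraphs
#'
#' Nodes are subgraphs, edges are best hits (either direction).  Degree is
#' the number of incident best-hit edges.
#'
#' @param hits annotated hits from [call_best_hits()].
#' @return Object of class `congru_besthits`: list with `edges` (data frame
#'   a, b, reciprocal), `degree` (named vector over all subgraphs appearing
#'   in a best hit).
#' @export
build_best_hit_graph <- function(hits) {
  bh <- hits[hits$best_ab | hits$best_ba, , drop = FALSE]
  if (nrow(bh) == 0L) stop("no best hits")
  deg <- table(c(bh$a, bh$b))
  structure(list(edges = bh[, c("a", "b", "reciprocal")],
                 degree = stats::setNames(as.integer(deg), names(deg))),
            class = "congru_besthits")
}

#' High-degree subgraphs and their neighbourhoods
#'
#' High-degree subgraphs sit above the configured upper percentile of the
#' best-hit degree distribution; a neighbourhood is a high-degree subgraph
#' together with all its best-hit partners.
#'
#' @param graph a `congru_besthits` object.
#' @param percentile upper percentile cutoff (default 97.5, i.e. top 2.5%).
#' @return List with `high_degree` (ids) and `neighbourhood` (ids of
#'   high-degree subgraphs plus all their partners).
#' @export
high_degree <- function(graph, percentile = 97.5) {
  deg <- graph$degree
  if (length(deg) == 0L) return(list(high_degree = character(), neighbourhood = character()))
  cut <- stats::quantile(deg, percentile / 100, names = FALSE, type = 7)
  hd <- names(deg)[deg > cut]
  e <- graph$edges
  nb <- unique(c(hd, e$b[e$a %in% hd], e$a[e$b %in% hd]))
  list(high_degree = hd, neighbourhood = sort(nb, method = "radix"))
}

#' Merge a reciprocal best-hit pair into a composite subnetwork
#'
#' Node set is the union of the two gene sets; the edge set is the union of
#' each source layer's induced edges over that node set, tagged with the
#' layer it came from.  Node and edge betweenness (unit edge lengths, shared
#' shortest paths split fractionally) annotate the merged subnetwork.
#'
#' @param a,b reciprocal best-hit `congru_subgraph` objects.
#' @param layers list of the source `congru_network` layers (must include
#'   both subgraphs' layers).
#' @param check_reciprocal set `FALSE` to merge an arbitrary pair.
#' @param hits optional annotated hits table used for the reciprocity check.
#' @return List with `genes`, `edges` (from, to, weight, source), and
#'   betweenness annotations `node_betweenness`, `edge_betweenness`.
#' @export
merge_subgraphs <- function(a, b, layers, check_reciprocal = TRUE, hits = NULL) {
  if (check_reciprocal && !is.null(hits)) {
    ok <- any((hits$a == a$id & hits$b == b$id & hits$reciprocal) |
              (hits$a == b$id & hits$b == a$id & hits$reciprocal))
    if (!ok) stop("pair is not a reciprocal best hit")
  }
  genes <- sort(union(a$genes, b$genes), method = "radix")
  tagged <- lapply(layers, function(net) {
    keep <- net$edges$from %in% genes & net$edges$to %in% genes
    e <- net$edges[keep, , drop = FALSE]
    if (nrow(e)) e$source <- net$layer
    e
  })
  edges <- do.call(rbind, tagged[vapply(tagged, nrow, integer(1)) > 0])
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), source = character())
  # collapse multi-layer duplicates into one edge, sources comma-joined
  key <- paste(edges$from, edges$to, sep = "\t")
  src <- vapply(split(edges$source, key), paste, character(1), collapse = ",")
  uniq <- edges[!duplicated(key), c("from", "to", "weight"), drop = FALSE]
  uniq$source <- unname(src[paste(uniq$from, uniq$to, sep = "\t")])
  uniq <- uniq[order(uniq$from, uniq$to, method = "radix"), , drop = FALSE]
  rownames(uniq) <- NULL
  g <- igraph::graph_from_data_frame(uniq[, c("from", "to")], directed = FALSE,
                                     vertices = data.frame(name = genes))
  nb <- igraph::betweenness(g, weights = NA)
  eb <- igraph::edge_betweenness(g, weights = NA)
  list(genes = genes, edges = uniq,
       node_betweenness = stats::setNames(as.numeric(nb), genes),
       edge_betweenness = eb)
}
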