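GO_NAMESPACES <- c("biological_process", "molecular_function", "cellular_component")

#' Construct an ontology
#'
#' A term DAG: every term has exactly one namespace (biological process,
#' molecular function or cellular component) and zero or more parents via
#' `is_a`/`part_of` links.  The parent graph must be acyclic.
#'
#' @param terms character vector of term ids.
#' @param namespace character vector (same length) of namespaces.
#' @param parents named list: term id -> character vector of parent ids.
#' @return Object of class `congru_ontology`.
#' @export
ontology <- function(terms, namespace, parents = list()) {
  terms <- as.character(terms)
  if (anyDuplicated(terms)) stop("duplicate term ids")
  if (!all(namespace %in% GO_NAMESPACES))
    stop("unknown namespace: ", paste(setdiff(unique(namespace), GO_NAMESPACES), collapse = ", "))
  namespace <- stats::setNames(as.character(namespace), terms)
  parents <- parents[intersect(names(parents), terms)]
  full <- stats::setNames(rep(list(character(0)), length(terms)), terms)
  full[names(parents)] <- lapply(parents, as.character)
  onto <- structure(list(terms = terms, namespace = namespace, parents = full),
                    class = "congru_ontology")
  onto$ancestors <- compute_ancestors(onto)
  onto
}

# transitive parent closure per term; errors on cycles
compute_ancestors <- function(onto) {
  parents <- onto$parents
  anc <- stats::setNames(vector("list", length(onto$terms)), onto$terms)
  state <- stats::setNames(integer(length(onto$terms)), onto$terms)  # 0 new 1 open 2 done
  visit <- function(t) {
    if (state[[t]] == 1L) stop("cyclic ontology at term ", t)
    if (state[[t]] == 2L) return(anc[[t]])
    state[[t]] <<- 1L
    ps <- intersect(parents[[t]], onto$terms)
    up <- unique(c(ps, unlist(lapply(ps, visit))))
    anc[[t]] <<- up
    state[[t]] <<- 2L
    up
  }
  for (t in onto$terms) visit(t)
  anc
}

#' @export
print.congru_ontology <- function(x, ...) {
  cat(sprintf("<congru_ontology> %d terms (%s)\n", length(x$terms),
              paste(sprintf("%s: %d", substr(GO_NAMESPACES, 1, 2),
                            as.integer(table(factor(x$namespace, GO_NAMESPACES)))),
                    collapse = ", ")))
  invisible(x)
}

#' Read an OBO-like ontology file
#'
#' Minimal dialect: `[Term]` stanzas with `id:`, `namespace:`, `is_a:` and
#' `relationship: part_of` lines; everything else is ignored.
#'
#' @param path file path.
#' @return A `congru_ontology`.
#' @export
read_obo <- function(path) {
  lines <- trimws(readLines(path))
  idx <- which(lines == "[Term]")
  if (length(idx) == 0L) stop("no [Term] stanzas in ", path)
  bounds <- c(idx, length(lines) + 1L)
  ids <- character(); ns <- character(); parents <- list()
  for (s in seq_along(idx)) {
    block <- lines[bounds[s]:(bounds[s + 1] - 1L)]
    id <- sub("^id: *", "", grep("^id:", block, value = TRUE)[1])
    nsl <- sub("^namespace: *", "", grep("^namespace:", block, value = TRUE)[1])
    isa <- sub(" *!.*$", "", sub("^is_a: *", "", grep("^is_a:", block, value = TRUE)))
    po <- grep("^relationship: *part_of", block, value = TRUE)
    po <- sub(" *!.*$", "", sub("^relationship: *part_of *", "", po))
    if (is.na(id) || is.na(nsl)) stop("term stanza missing id or namespace in ", path)
    ids <- c(ids, id); ns <- c(ns, nsl)
    parents[[id]] <- unique(c(isa, po))
  }
  ontology(ids, ns, parents)
}

#' Read gene-term annotations from a GAF-like TSV
#'
#' Three tab-separated columns: gene, term id, evidence code.  `#` comment
#' lines are ignored.
#'
#' @param path file path.
#' @return Data frame with columns `gene`, `term`, `evidence`.
#' @export
read_gaf <- function(path) {
  empty <- data.frame(gene = character(), term = character(),
                      evidence = character(), stringsAsFactors = FALSE)
  lines <- readLines(path)
  if (!any(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))) return(empty)
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("annotation file needs gene, term, evidence columns")
  stats::setNames(tab[, 1:3], c("gene", "term", "evidence"))
}

#' Build a propagated annotation map
#'
#' Filters annotations by evidence mode (`all`, `no_iea` = drop IEA,
#' `only_iea`), then propagates each annotation to all ancestors of its term
#' within the same namespace (true-path rule).
#'
#' @param onto a `congru_ontology`.
#' @param annotations data frame as from [read_gaf()].
#' @param use_iea one of `"all"`, `"no_iea"`, `"only_iea"`.
#' @param propagate apply the true-path rule (default TRUE).
#' @return Object of class `congru_annotations`: named list gene -> character
#'   vector of term ids.
#' @export
annotation_map <- function(onto, annotations, use_iea = c("all", "no_iea", "only_iea"),
                           propagate = TRUE) {
  use_iea <- match.arg(use_iea)
  ann <- annotations
  if (use_iea == "no_iea") ann <- ann[ann$evidence != "IEA", , drop = FALSE]
  if (use_iea == "only_iea") ann <- ann[ann$evidence == "IEA", , drop = FALSE]
  ann <- ann[ann$term %in% onto$terms, , drop = FALSE]
  map <- lapply(split(ann$term, ann$gene), unique)
  if (propagate) {
    map <- lapply(map, function(ts)
      sort(unique(c(ts, unlist(onto$ancestors[ts], use.names = FALSE))), method = "radix"))
  } else {
    map <- lapply(map, function(ts) sort(ts, method = "radix"))
  }
  structure(map[order(names(map), method = "radix")], class = "congru_annotations")
}

#' Load an ontology and annotation files together
#'
#' @param obo_path OBO-like ontology file.
#' @param gaf_path GAF-like annotation TSV.
#' @inheritParams annotation_map
#' @return List with `ontology` and `annotations`.
#' @export
load_ontology_and_annotations <- function(obo_path, gaf_path,
                                          use_iea = c("all", "no_iea", "only_iea"),
                                          propagate = TRUE) {
  onto <- read_obo(obo_path)
  ann <- read_gaf(gaf_path)
  list(ontology = onto,
       annotations = annotation_map(onto, ann, use_iea = use_iea, propagate = propagate))
}

# gene x term incidence over given genes; terms restricted to those used
annotation_incidence <- function(annot, genes) {
  sub <- annot[intersect(names(annot), genes)]
  terms <- sort(unique(unlist(sub, use.names = FALSE)), method = "radix")
  if (length(terms) == 0L)
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(length(genes), 0),
                                dimnames = list(genes, character())))
  i <- match(rep(names(sub), lengths(sub)), genes)
  j <- match(unlist(sub, use.names = FALSE), terms)
  Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(length(genes), length(terms)),
                       dimnames = list(genes, terms))
}

#' Term over-representation in subgraphs
#'
#' For every subgraph and every term with at least `min_term_genes` annotated
#' genes in the network, the upper-tail hypergeometric P value of drawing at
#' least `tp` term genes in a sample of subgraph size from the network gene
#' population; Benjamini-Hochberg correction pooled over all subgraph-term
#' tests (set `pool = "per_subgraph"` to correct within each subgraph);
#' results with `q < fdr_alpha` are marked enriched.  MCC measures the
#' accuracy of capture (tp = subgraph genes with the term, tn = network genes
#' outside the subgraph without the term, etc.).
#'
#' @param subs list of `congru_subgraph` objects (or a single one).
#' @param annot a `congru_annotations` map.
#' @param network_genes population gene set.
#' @param fdr_alpha significance threshold (default 0.05).
#' @param min_term_genes term eligibility floor (default 2: terms with one or
#'   no network genes are excluded).
#' @param min_tp smallest overlap that may be called enriched (default 4; a
#'   handful of shared genes is not convincing support for a term however
#'   small the P value, and in a multi-resolution catalogue whose subgraphs
#'   tile the network many times over, three-gene coincidences arise by
#'   chance).
#' @param pool BH pool: `"network"` (all tests, default) or `"per_subgraph"`.
#' @return Data frame: subgraph, term, tp, size, term_genes, p, q, mcc,
#'   enriched.
#' @export
enrich_subgraphs <- function(subs, annot, network_genes, fdr_alpha = 0.05,
                             min_term_genes = 2, min_tp = 4,
                             pool = c("network", "per_subgraph")) {
  pool <- match.arg(pool)
  if (inherits(subs, "congru_subgraph")) subs <- list(subs)
  empty <- data.frame(subgraph = character(), term = character(), tp = integer(),
                      size = integer(), term_genes = integer(), p = numeric(),
                      q = numeric(), mcc = numeric(), enriched = logical(),
                      stringsAsFactors = FALSE)
  if (length(subs) == 0L) return(empty)
  genes <- sort(network_genes, method = "radix")
  Tm <- annotation_incidence(annot, genes)
  K <- Matrix::colSums(Tm)
  Tm <- Tm[, K >= min_term_genes, drop = FALSE]
  K <- K[K >= min_term_genes]
  if (ncol(Tm) == 0L) return(empty)
  Z <- incidence_matrix(subs, genes)
  TP <- as.matrix(Matrix::crossprod(Z, Tm))   # subgraphs x terms
  n <- Matrix::colSums(Z)
  N <- length(genes)
  ns <- length(subs); nt <- ncol(Tm)
  tp <- as.vector(TP)
  nn <- rep(n, times = nt)
  KK <- rep(K, each = ns)
  p <- hyper_upper_tail(tp, N, KK, nn)
  m <- mcc(tp, N - nn - KK + tp, nn - tp, KK - tp)
  res <- data.frame(
    subgraph = rep(vapply(subs, `[[`, character(1), "id"), times = nt),
    term = rep(colnames(Tm), each = ns),
    tp = as.integer(tp), size = as.integer(nn), term_genes = as.integer(KK),
    p = p, mcc = m, stringsAsFactors = FALSE)
  res$q <- if (pool == "network") stats::p.adjust(res$p, method = "BH")
           else stats::ave(res$p, res$subgraph, FUN = function(x) stats::p.adjust(x, "BH"))
  res$enriched <- res$q < fdr_alpha & res$tp >= min_tp
  res[order(res$subgraph, res$term, method = "radix"),
      c("subgraph", "term", "tp", "size", "term_genes", "p", "q", "mcc", "enriched")]
}

#' Ontology coverage of a network's subgraphs
#'
#' Per namespace: the number of eligible terms (>= 2 annotated network
#' genes), the number of those enriched in at least one subgraph, coverage
#' as a percentage, and the average MCC (mean over enriched terms of the
#' best per-term subgraph MCC; 0 with a flag when nothing is enriched).
#'
#' @param enrichments data frame from [enrich_subgraphs()].
#' @param annot the `congru_annotations` used.
#' @param onto the `congru_ontology`.
#' @param network_genes population gene set.
#' @param min_term_genes term eligibility floor (must match the enrichment run).
#' @return Data frame, one row per namespace: namespace, enriched_terms,
#'   total_terms, coverage_pct, avg_mcc, any_enriched.
#' @export
coverage <- function(enrichments, annot, onto, network_genes, min_term_genes = 2) {
  Tm <- annotation_incidence(annot, sort(network_genes, method = "radix"))
  K <- Matrix::colSums(Tm)
  eligible <- colnames(Tm)[K >= min_term_genes]
  enr <- enrichments[enrichments$enriched & enrichments$term %in% eligible, , drop = FALSE]
  best <- if (nrow(enr)) tapply(enr$mcc, enr$term, max) else numeric(0)
  do.call(rbind, lapply(GO_NAMESPACES, function(ns) {
    terms_ns <- eligible[onto$namespace[eligible] == ns]
    enr_ns <- intersect(names(best), terms_ns)
    total <- length(terms_ns)
    data.frame(namespace = ns,
               enriched_terms = length(enr_ns),
               total_terms = total,
               coverage_pct = if (total) 100 * length(enr_ns) / total else 0,
               avg_mcc = if (length(enr_ns)) mean(best[enr_ns]) else 0,
               any_enriched = length(enr_ns) > 0,
               stringsAsFactors = FALSE)
  }))
}

#' Co-enriched term pairs
#'
#' All unordered pairs of terms enriched together in at least one subgraph,
#' classified as same-namespace related (ancestor/descendant), same-namespace
#' unrelated, or different-namespace.
#'
#' @param enrichments data frame from [enrich_subgraphs()].
#' @param onto a `congru_ontology`.
#' @return List with `pairs` (term_a, term_b, class, n_subgraphs) and
#'   `summary` (counts and percentages per class).
#' @export
coenrichment_pairs <- function(enrichments, onto) {
  enr <- enrichments[enrichments$enriched, , drop = FALSE]
  by_sub <- split(enr$term, enr$subgraph)
  by_sub <- by_sub[lengths(by_sub) >= 2L]
  pair_keys <- unlist(lapply(by_sub, function(ts) {
    ts <- sort(unique(ts), method = "radix")
    cmb <- utils::combn(ts, 2)
    paste(cmb[1, ], cmb[2, ], sep = "\t")
  }), use.names = FALSE)
  if (length(pair_keys) == 0L) {
    pairs <- data.frame(term_a = character(), term_b = character(),
                        class = character(), n_subgraphs = integer(),
                        stringsAsFactors = FALSE)
  } else {
    cnt <- table(pair_keys)
    ab <- do.call(rbind, strsplit(names(cnt), "\t", fixed = TRUE))
    pairs <- data.frame(term_a = ab[, 1], term_b = ab[, 2],
                        n_subgraphs = as.integer(cnt), stringsAsFactors = FALSE)
    same_ns <- onto$namespace[pairs$term_a] == onto$namespace[pairs$term_b]
    related <- mapply(function(a, b)
      b %in% onto$ancestors[[a]] || a %in% onto$ancestors[[b]],
      pairs$term_a, pairs$term_b)
    pairs$class <- ifelse(!same_ns, "different_ontology",
                          ifelse(related, "same_ontology_related",
                                 "same_ontology_unrelated"))
    pairs <- pairs[order(pairs$term_a, pairs$term_b, method = "radix"),
                   c("term_a", "term_b", "class", "n_subgraphs")]
    rownames(pairs) <- NULL
  }
  classes <- c("same_ontology_related", "same_ontology_unrelated", "different_ontology")
  n <- as.integer(table(factor(pairs$class, classes)))
  list(pairs = pairs,
       summary = data.frame(class = classes, pairs = n,
                            pct = if (sum(n)) 100 * n / sum(n) else rep(0, 3),
                            stringsAsFactors = FALSE))
}

#' Term pairs co-enriched only through network integration
#'
#' Pairs co-enriched in merged reciprocal-best-hit subnetworks but in no
#' single-layer subgraph.
#'
#' @param merged_pairs `pairs` data frame from [coenrichment_pairs()] on the
#'   merged subnetworks' enrichment.
#' @param layer_pairs list of `pairs` data frames from the single-layer runs.
#' @return Subset of `merged_pairs` absent from every single-layer pair set.
#' @export
novel_coenrichment <- function(merged_pairs, layer_pairs) {
  key <- function(p) paste(p$term_a, p$term_b, sep = "\t")
  seen <- unique(unlist(lapply(layer_pairs, key)))
  merged_pairs[!key(merged_pairs) %in% seen, , drop = FALSE]
}

#' Randomize annotations while preserving annotation structure
#'
#' Permutes the gene labels of the annotation profiles: every gene keeps some
#' gene's full term set, per-gene annotation counts are preserved as a
#' multiset, global term usage is untouched, and network topology is not
#' involved.  Deterministic per seed.
#'
#' @param annot a `congru_annotations` map.
#' @param seed integer seed.
#' @return A `congru_annotations` map.
#' @export
randomize_annotations <- function(annot, seed) {
  if (length(annot) == 0L) stop("empty annotation map")
  genes <- names(annot)
  perm <- with_seed(seed, sample.int(length(genes)))
  out <- stats::setNames(unclass(annot)[perm], genes)
  structure(out[order(names(out), method = "radix")], class = "congru_annotations")
}

#' Relative enrichment of terms by annotation size
#'
#' Terms are binned by the number of network genes they annotate; for each
#' bin the proportion of accurately captured enriched terms (MCC at or above
#' the threshold) minus the proportion of all eligible terms falling in that
#' bin.  Positive values mark term sizes over-represented among enriched
#' terms; the values sum to 0 across bins.
#'
#' @param enrichments data frame from [enrich_subgraphs()].
#' @param annot the annotation map used.
#' @param network_genes population gene set.
#' @param breaks bin breaks on term size (passed to `cut`, right-open).
#' @param mcc_threshold minimum best MCC for an enriched term to count
#'   (default 0.2).
#' @param min_term_genes term eligibility floor.
#' @return Data frame: bin, n_all, n_enriched, prop_all, prop_enriched,
#'   relative_enrichment.
#' @export
relative_enrichment_by_term_size <- function(enrichments, annot, network_genes,
                                             breaks = c(2, 5, 10, 20, 50, 100, Inf),
                                             mcc_threshold = 0.2, min_term_genes = 2) {
  Tm <- annotation_incidence(annot, sort(network_genes, method = "radix"))
  K <- Matrix::colSums(Tm)
  K <- K[K >= min_term_genes]
  enr <- enrichments[enrichments$enriched, , drop = FALSE]
  best <- if (nrow(enr)) tapply(enr$mcc, enr$term, max) else numeric(0)
  passing <- names(best)[best >= mcc_threshold]
  passing <- intersect(passing, names(K))
  if (length(passing) == 0L) stop("no enriched terms pass the MCC threshold")
  bin_all <- cut(K, breaks, right = FALSE, include.lowest = TRUE)
  bin_enr <- cut(K[passing], breaks, right = FALSE, include.lowest = TRUE)
  n_all <- as.integer(table(bin_all))
  n_enr <- as.integer(table(bin_enr))
  data.frame(bin = levels(bin_all), n_all = n_all, n_enriched = n_enr,
             prop_all = n_all / sum(n_all),
             prop_enriched = n_enr / sum(n_enr),
             relative_enrichment = n_enr / sum(n_enr) - n_all / sum(n_all),
             stringsAsFactors = FALSE)
}
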