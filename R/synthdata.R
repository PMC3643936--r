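#' Planted-module benchmark design
#'
#' Describes a multilayer benchmark in the planted-partition (stochastic
#' block) family: a shared gene universe, disjoint modules of fixed size,
#' per-layer module membership (which modules each layer expresses), an
#' optional set of "split" modules whose intra-module edges are divided
#' among the topology layers so that no single layer sees their full
#' density, and the edge probabilities inside (`p_in`) and outside
#' (`p_out`) modules.  Annotation noise is the probability that a module
#' gene misses its aligned ontology term.
#'
#' @param n_genes gene universe size.
#' @param module_size genes per module.
#' @param layer_modules named list: layer name -> indices of the (full)
#'   modules that layer expresses.  Layer names ending in `"coreg"` are
#'   treatment-driven and are generated from calls, not edges.
#' @param split_modules indices of modules whose edges are split between the
#'   topology layers.
#' @param p_in,p_out intra-/inter-module edge probabilities.
#' @param annotation_noise per-gene term drop-out probability.
#' @param rider_trios number of cross-network rider trios.  Each trio holds
#'   one gene per data type (the topology layers plus the co-regulation
#'   layer) that interacts with a shared module exclusively through that
#'   data type and carries no interactions of the other types at all —
#'   emulating genes covered by only one assay.  A term annotating a whole
#'   trio has fewer than two associated genes in every single network but
#'   all its genes in the combined network.
#' @param seeds named integer vector with entries `layers`, `calls`,
#'   `ontology`.
#' @return Object of class `congru_design`; `$modules` holds the planted
#'   gene sets (ground truth), `$shared` the module indices expressed by
#'   more than one topology layer, `$riders` the rider assignment table.
#' @export
planted_design <- function(n_genes = 500, module_size = 12,
                           layer_modules = list(ppi = c(1:6, 7),
                                                genetic = c(1:6, 8)),
                           split_modules = integer(0),
                           p_in = 0.6, p_out = 0.02,
                           annotation_noise = 0.1,
                           rider_trios = 0,
                           seeds = c(layers = 11L, calls = 13L, ontology = 17L)) {
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) stop("need 0 <= p_out < p_in <= 1")
  n_modules <- max(c(unlist(layer_modules), split_modules, 0L))
  if (n_modules * module_size > n_genes) stop("modules do not fit in the gene universe")
  genes <- sprintf("g%04d", seq_len(n_genes))
  modules <- lapply(seq_len(n_modules), function(m)
    genes[((m - 1) * module_size + 1):(m * module_size)])
  names(modules) <- sprintf("M%d", seq_len(n_modules))
  tab <- table(unlist(layer_modules))
  shared <- as.integer(names(tab)[tab > 1])
  riders <- NULL
  if (rider_trios > 0) {
    types <- c(names(layer_modules), "coreg")
    # riders attach to shared modules: the host must be cohesive in every
    # data type so that all three riders join the same combined subgraph
    if (length(shared) == 0L) stop("rider trios need at least one shared module")
    host <- shared[(seq_len(rider_trios) - 1L) %% length(shared) + 1L]
    first_free <- n_modules * module_size
    if (first_free + rider_trios * length(types) > n_genes)
      stop("rider genes do not fit in the gene universe")
    riders <- data.frame(
      gene = genes[first_free + seq_len(rider_trios * length(types))],
      type = rep(types, times = rider_trios),
      trio = rep(seq_len(rider_trios), each = length(types)),
      module = rep(host, each = length(types)),
      stringsAsFactors = FALSE)
  }
  structure(list(n_genes = n_genes, genes = genes, module_size = module_size,
                 modules = modules, layer_modules = layer_modules,
                 split_modules = as.integer(split_modules),
                 shared = shared, p_in = p_in, p_out = p_out,
                 annotation_noise = annotation_noise, riders = riders,
                 seeds = seeds),
            class = "congru_design")
}

#' The default benchmark design
#'
#' 500 genes; eight full modules of 12 (modules 1-6 expressed by both
#' topology layers, module 7 private to the first, module 8 to the second)
#' plus a ninth split module whose edges are divided between the two
#' topology layers; `p_in` 0.6, `p_out` 0.02, annotation noise 0.1, seeds
#' 11/13/17.  The co-regulation layer is driven by treatment calls over the
#' eight full modules (see [generate_treatment_calls()]).
#'
#' @return A `congru_design`.
#' @export
bench_a_design <- function() {
  planted_design(n_genes = 500, module_size = 12,
                 layer_modules = list(ppi = c(1:6, 7), genetic = c(1:6, 8)),
                 split_modules = 9L,
                 p_in = 0.6, p_out = 0.02, annotation_noise = 0.1,
                 rider_trios = 6,
                 seeds = c(layers = 11L, calls = 13L, ontology = 17L))
}

#' @export
print.congru_design <- function(x, ...) {
  cat(sprintf(paste0("<congru_design> %d genes, %d modules of %d ",
                     "(p_in=%.2g, p_out=%.2g, %d shared, %d split)\n"),
              x$n_genes, length(x$modules), x$module_size, x$p_in, x$p_out,
              length(x$shared), length(x$split_modules)))
  invisible(x)
}

#' Generate the topology layers of a planted design
#'
#' Per layer, pairs inside an expressed module are connected with
#' probability `p_in` and all other pairs with `p_out`.  Edges of split
#' modules are drawn once with probability `p_in` and each assigned to one
#' topology layer uniformly, so every layer sees only a fraction of the
#' module's density while their union restores it.  Deterministic for the
#' design's `layers` seed.
#'
#' @param design a `congru_design`.
#' @return Named list of unweighted `congru_network` layers (one per entry
#'   of `design$layer_modules`), each over the full gene universe.
#' @export
generate_layers <- function(design) {
  genes <- design$genes
  n <- design$n_genes
  pair_i <- rep(seq_len(n - 1), times = (n - 1):1)
  pair_j <- sequence((n - 1):1, from = 2:n)
  midx <- stats::setNames(rep(0L, n), genes)
  for (m in seq_along(design$modules)) midx[design$modules[[m]]] <- m
  mi <- midx[pair_i]; mj <- midx[pair_j]
  same_mod <- ifelse(mi > 0 & mi == mj, mi, 0L)
  layer_names <- names(design$layer_modules)
  with_seed(design$seeds[["layers"]], {
    nets <- vector("list", length(layer_names))
    names(nets) <- layer_names
    # Split-module edges are drawn once and dealt uniformly over one share
    # per data type (the topology layers plus one share standing for
    # interactions detectable only by a third assay type, which no topology
    # layer carries): each layer sees a thin slice of the module's density
    # and only the union restores it.
    n_shares <- length(layer_names) + 1L
    split_edge_layer <- rep(NA_integer_, length(pair_i))
    in_split <- same_mod %in% design$split_modules & same_mod > 0L
    if (any(in_split)) {
      drawn <- in_split & stats::runif(length(pair_i)) < design$p_in
      split_edge_layer[drawn] <- sample.int(n_shares, sum(drawn), replace = TRUE)
    }
    for (li in seq_along(layer_names)) {
      mods <- design$layer_modules[[li]]
      p <- ifelse(same_mod %in% mods & same_mod > 0L, design$p_in, design$p_out)
      p[in_split] <- 0
      # rider genes of other data types carry no interactions in this layer;
      # this layer's own riders attach to their module with p_in
      layer_nodes <- genes
      if (!is.null(design$riders)) {
        own <- design$riders[design$riders$type == layer_names[li], , drop = FALSE]
        foreign <- setdiff(design$riders$gene, own$gene)
        excluded <- genes[pair_i] %in% foreign | genes[pair_j] %in% foreign
        p[excluded] <- 0
        if (nrow(own)) {
          ok_mod <- rep(FALSE, length(pair_i))
          for (r in seq_len(nrow(own))) {
            rg <- own$gene[r]; mg <- design$modules[[own$module[r]]]
            ok_mod <- ok_mod |
              (genes[pair_i] == rg & genes[pair_j] %in% mg) |
              (genes[pair_j] == rg & genes[pair_i] %in% mg)
          }
          # riders attach at half the module density: enough to ride the
          # module's combined subgraph, low enough to rank below every
          # module gene when subgraphs are peeled
          p[ok_mod] <- design$p_in / 2
        }
        layer_nodes <- setdiff(genes, foreign)
      }
      keep <- stats::runif(length(pair_i)) < p
      keep <- keep | (!is.na(split_edge_layer) & split_edge_layer == li)
      nets[[li]] <- network(data.frame(from = genes[pair_i[keep]],
                                       to = genes[pair_j[keep]],
                                       stringsAsFactors = FALSE),
                            layer = layer_names[li], nodes = layer_nodes,
                            weighted = FALSE)
    }
    nets
  })
}

#' Generate a treatment significance-call matrix
#'
#' Emulates a compendium of expression-profiling treatments: in each
#' treatment every full (non-split) module is active with probability
#' `p_active_module`; genes of active modules are called significantly
#' regulated with probability `p_call`, all other genes with
#' `p_background`.  Deterministic for the design's `calls` seed.
#'
#' @param design a `congru_design`.
#' @param n_treatments number of treatments (default 60).
#' @param p_active_module per-treatment module activity probability.
#' @param p_call call probability for genes of an active module.
#' @param p_background call probability for all other genes.
#' @return A `congru_calls` object over the full gene universe.
#' @export
generate_treatment_calls <- function(design, n_treatments = 60,
                                     p_active_module = 0.3, p_call = 0.9,
                                     p_background = 0.02) {
  stopifnot(all(c(p_active_module, p_call, p_background) >= 0),
            all(c(p_active_module, p_call, p_background) <= 1))
  full_mods <- setdiff(seq_along(design$modules), design$split_modules)
  with_seed(design$seeds[["calls"]], {
    m <- matrix(stats::rbinom(design$n_genes * n_treatments, 1, p_background),
                nrow = design$n_genes,
                dimnames = list(design$genes, sprintf("t%03d", seq_len(n_treatments))))
    if (!is.null(design$riders)) m[design$riders$gene, ] <- 0L
    for (mod in full_mods) {
      active <- stats::runif(n_treatments) < p_active_module
      if (!any(active)) next
      mod_genes <- design$modules[[mod]]
      if (!is.null(design$riders)) {
        cr <- design$riders[design$riders$type == "coreg" &
                            design$riders$module == mod, "gene"]
        mod_genes <- c(mod_genes, cr)   # co-regulation riders follow the module
      }
      rows <- match(mod_genes, design$genes)
      calls <- matrix(stats::rbinom(length(rows) * sum(active), 1, p_call),
                      nrow = length(rows))
      m[rows, active] <- pmax(m[rows, active], calls)
    }
    if (!is.null(design$riders)) {
      topo <- design$riders$gene[design$riders$type != "coreg"]
      m <- m[setdiff(rownames(m), topo), , drop = FALSE]
    }
    treatment_calls(m)
  })
}

#' Generate a module-aligned synthetic ontology and annotations
#'
#' Builds a shallow DAG per namespace: a root, mid-level terms aggregating
#' several modules, one leaf term per planted module (module genes annotated
#' to it, each dropped with probability `annotation_noise`), and background
#' terms annotating random gene sets drawn from `size_spectrum`.  Every
#' annotation gets an evidence code (`EXP` or `IEA`, IEA with probability
#' `p_iea`).  Deterministic for the design's `ontology` seed.
#'
#' @param design a `congru_design`.
#' @param background_terms number of unaligned background terms per
#'   namespace.
#' @param size_spectrum gene-set sizes the background terms cycle through.
#' @param p_iea probability an annotation is electronically inferred.
#' @return List with `ontology` (a `congru_ontology`), `annotations` (data
#'   frame gene/term/evidence, direct annotations only) and `leaf_terms`
#'   (named list namespace -> module index -> term id, the alignment ground
#'   truth).
#' @export
generate_ontology <- function(design, background_terms = 6,
                              size_spectrum = c(3, 4, 5),
                              p_iea = 0.3) {
  ns_tags <- c(biological_process = "BP", molecular_function = "MF",
               cellular_component = "CC")
  nm <- length(design$modules)
  free_genes <- setdiff(design$genes,
                        c(unlist(design$modules), design$riders$gene))
  with_seed(design$seeds[["ontology"]], {
    ids <- character(); ns <- character(); parents <- list()
    ann <- list(); leaf_terms <- list()
    for (nsi in seq_along(ns_tags)) {
      tag <- ns_tags[nsi]; nsname <- names(ns_tags)[nsi]
      root <- sprintf("%s:ROOT", tag)
      mid1 <- sprintf("%s:GEN1", tag)   # general terms over module groups
      mid2 <- sprintf("%s:GEN2", tag)
      ids <- c(ids, root, mid1, mid2)
      ns <- c(ns, rep(nsname, 3))
      parents[[mid1]] <- root
      parents[[mid2]] <- root
      # every gene carries the namespace root: general annotation covers
      # the genome, so the root itself is never informative
      ann[[length(ann) + 1L]] <- data.frame(gene = design$genes, term = root,
                                            stringsAsFactors = FALSE)
      grp1 <- seq_len(ceiling(nm / 2))
      leaves <- sprintf("%s:M%02d", tag, seq_len(nm))
      leaf_terms[[nsname]] <- stats::setNames(leaves, names(design$modules))
      for (m in seq_len(nm)) {
        ids <- c(ids, leaves[m]); ns <- c(ns, nsname)
        parents[[leaves[m]]] <- if (m %in% grp1) mid1 else mid2
        keep <- stats::runif(design$module_size) >= design$annotation_noise
        gset <- design$modules[[m]][keep]
        if (length(gset))
          ann[[length(ann) + 1L]] <- data.frame(gene = gset, term = leaves[m],
                                                stringsAsFactors = FALSE)
      }
      for (b in seq_len(background_terms)) {
        bt <- sprintf("%s:BG%02d", tag, b)
        ids <- c(ids, bt); ns <- c(ns, nsname)
        parents[[bt]] <- root
        sz <- size_spectrum[(b - 1L) %% length(size_spectrum) + 1L]
        # unaligned terms sample genes outside the planted structure:
        # accidental module alignment would be construction noise
        gset <- sample(free_genes, sz)
        ann[[length(ann) + 1L]] <- data.frame(gene = gset, term = bt,
                                              stringsAsFactors = FALSE)
      }
      # cross-network term: annotates this namespace's rider trios plus one
      # gene of each host module.  A single network carries only its own
      # data type's riders, so at most two of the term's genes (one rider
      # plus the host anchor) ever share a subgraph there; in the combined
      # network a host module's subgraph holds a whole trio plus the
      # anchor.
      if (!is.null(design$riders)) {
        trs <- which((seq_len(max(design$riders$trio)) - 1L) %% 3L + 1L == nsi)
        if (length(trs)) {
          xt <- sprintf("%s:XNET", tag)
          ids <- c(ids, xt); ns <- c(ns, nsname)
          parents[[xt]] <- root
          hosts <- unique(design$riders$module[design$riders$trio %in% trs])
          anchors <- vapply(hosts, function(m) design$modules[[m]][1], "")
          gset <- c(design$riders$gene[design$riders$trio %in% trs], anchors)
          ann[[length(ann) + 1L]] <- data.frame(gene = gset, term = xt,
                                                stringsAsFactors = FALSE)
        }
      }
    }
    annotations <- do.call(rbind, ann)
    annotations$evidence <- ifelse(stats::runif(nrow(annotations)) < p_iea,
                                   "IEA", "EXP")
    annotations <- annotations[order(annotations$gene, annotations$term,
                                     method = "radix"), ]
    rownames(annotations) <- NULL
    list(ontology = ontology(ids, ns, parents),
         annotations = annotations,
         leaf_terms = leaf_terms)
  })
}

#' Write benchmark ground truth as JSON
#'
#' Emits the planted module gene sets, layer membership and design
#' parameters, sufficient to score module recovery without re-deriving the
#' design.
#'
#' @param design a `congru_design`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(design, path) {
  jsonlite::write_json(list(
    n_genes = design$n_genes,
    modules = design$modules,
    layer_modules = design$layer_modules,
    split_modules = design$split_modules,
    shared = design$shared,
    p_in = design$p_in, p_out = design$p_out,
    annotation_noise = design$annotation_noise,
    seeds = as.list(design$seeds)), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
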