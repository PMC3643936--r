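#' Configuration for a full analysis run
#'
#' Collects every threshold, seed and generator setting used by
#' [run_all()], so that a run is reproducible from its config alone and the
#' config can be serialised next to the outputs.
#'
#' @param design a `congru_design` (synthetic input); alternatively supply
#'   `networks` (named list of `congru_network`) plus `calls`, `ontology`
#'   and `annotations` for pre-built inputs.
#' @param seed base seed for partitioning and randomisation controls.
#' @param alpha_validate path-length validation threshold.
#' @param n_min,m_min congruence pre-filters (minimum intersection, minimum
#'   MCC).
#' @param fdr_alpha FDR threshold shared by congruence and enrichment.
#' @param mcc_bin_threshold MCC floor for the term-size relative-enrichment
#'   report.
#' @param high_degree_percentile upper degree percentile defining
#'   high-degree subgraphs.
#' @param coreg_scale integer scale for co-regulation partition weights.
#' @param n_treatments,p_active_module,p_call,p_background treatment-call
#'   generator settings.
#' @param min_size smallest average part size for the k plan (and smallest
#'   admissible subgraph).
#' @param balance_tol partition balance tolerance.
#' @param include_common also analyse the common-gene network variants.
#' @param annotation_modes evidence modes to run enrichment under.
#' @return Object of class `congru_config` (a list).
#' @export
run_config <- function(design = bench_a_design(), seed = 1L,
                       alpha_validate = 0.05, n_min = 3, m_min = 0.2,
                       fdr_alpha = 0.05, mcc_bin_threshold = 0.2,
                       high_degree_percentile = 97.5, coreg_scale = 10,
                       n_treatments = 60, p_active_module = 0.3,
                       p_call = 0.9, p_background = 0.02,
                       min_size = 3, balance_tol = 1.10,
                       include_common = TRUE,
                       annotation_modes = c("all", "no_iea", "only_iea")) {
  structure(list(design = design, seed = as.integer(seed),
                 alpha_validate = alpha_validate, n_min = n_min, m_min = m_min,
                 fdr_alpha = fdr_alpha, mcc_bin_threshold = mcc_bin_threshold,
                 high_degree_percentile = high_degree_percentile,
                 coreg_scale = coreg_scale, n_treatments = n_treatments,
                 p_active_module = p_active_module, p_call = p_call,
                 p_background = p_background, min_size = min_size,
                 balance_tol = balance_tol, include_common = include_common,
                 annotation_modes = annotation_modes),
            class = "congru_config")
}

#' Multi-resolution subgraph discovery on one network
#'
#' Plans the k values, partitions the network at each, extracts
#' largest-connected-component subgraphs, validates each partition's cohort
#' by the path-length t-test, drops subgraphs failing validation
#' (`p >= alpha`; not-applicable cases are retained flagged) and collapses
#' duplicates.
#'
#' @param net a `congru_network`.
#' @param config a `congru_config`.
#' @param weights optional integer partition weights (default
#'   [partition_weights()]; the co-regulation layer uses `coreg_scale`).
#' @return List with `subgraphs` (validated, de-duplicated), `plan`, and
#'   `partitions` (list of `congru_partition`).
#' @export
discover_subgraphs <- function(net, config, weights = NULL) {
  n <- length(net$nodes)
  plan <- plan_k_values(n, min_size = config$min_size)
  if (is.null(weights)) weights <- partition_weights(net)
  dist_cache <- NULL
  all_subs <- list()
  partitions <- vector("list", length(plan$k))
  for (i in seq_along(plan$k)) {
    k <- plan$k[i]
    part <- partition_graph(net, k, seed = config$seed + k,
                            balance_tol = config$balance_tol, weights = weights)
    partitions[[i]] <- part
    subs <- extract_subgraphs(net, part, min_nodes = config$min_size)
    if (length(subs) >= 2L) {
      if (is.null(dist_cache)) dist_cache <- all_pairs_distances(net)
      subs <- validate_cohort(subs, net, dist = dist_cache)
      keep <- vapply(subs, function(s)
        is.na(s$validation_p) || s$validation_p < config$alpha_validate, logical(1))
      subs <- subs[keep]
    }
    all_subs <- c(all_subs, subs)
  }
  list(subgraphs = dedup_subgraphs(all_subs), plan = plan, partitions = partitions)
}

#' Run the full module-congruence analysis
#'
#' Generates (or accepts) the network layers, builds the co-regulation,
#' combined and common-gene networks, discovers and validates subgraphs at
#' every planned resolution, scores cross-network congruence (best and
#' reciprocal best hits, high-degree neighbourhoods, merged subnetworks
#' with betweenness), and computes ontology enrichment, coverage,
#' co-enrichment, annotation-randomization control and term-size
#' relative-enrichment reports.
#'
#' @param config a `congru_config`.
#' @param out_dir optional directory; when given, [write_bundle()] is called
#'   on the result.
#' @return Object of class `congru_run` (see components in the source);
#'   printable.
#' @export
run_all <- function(config = run_config(), out_dir = NULL) {
  design <- config$design
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
    res
  }

  layers <- stage("layers", generate_layers(design))
  calls <- stage("calls", generate_treatment_calls(
    design, n_treatments = config$n_treatments,
    p_active_module = config$p_active_module, p_call = config$p_call,
    p_background = config$p_background))
  coreg <- stage("coreg", build_coregulation_network(calls))
  nets <- c(layers, list(coreg = coreg))
  combined <- stage("combine", combine_networks(nets, layer = "combined"))
  networks <- c(nets, list(combined = combined))
  if (config$include_common) {
    commons <- stage("common", common_gene_networks(networks))
    names(commons) <- vapply(commons, `[[`, character(1), "layer")
    networks <- c(networks, commons)
  }

  single <- names(nets)   # congruence excludes the combined network

  discoveries <- list()
  for (nm in names(networks)) {
    w <- if (identical(nm, "coreg"))
      partition_weights(networks[[nm]], scale = config$coreg_scale)
    else partition_weights(networks[[nm]])
    discoveries[[nm]] <- stage(paste0("discover:", nm),
                               discover_subgraphs(networks[[nm]], config, weights = w))
  }
  subgraphs <- lapply(discoveries, `[[`, "subgraphs")

  hits <- stage("congruence", {
    combos <- utils::combn(single, 2)
    all_hits <- do.call(rbind, lapply(seq_len(ncol(combos)), function(ci) {
      a <- combos[1, ci]; b <- combos[2, ci]
      score_overlaps(subgraphs[[a]], subgraphs[[b]],
                     universe = union(networks[[a]]$nodes, networks[[b]]$nodes),
                     n_min = config$n_min, m_min = config$m_min)
    }))
    call_best_hits(all_hits, fdr_alpha = config$fdr_alpha)
  })

  best_graph <- if (any(hits$best_ab | hits$best_ba))
    build_best_hit_graph(hits) else NULL
  hd <- if (!is.null(best_graph))
    high_degree(best_graph, percentile = config$high_degree_percentile)
  else list(high_degree = character(), neighbourhood = character())

  sub_index <- stats::setNames(
    unlist(subgraphs, recursive = FALSE, use.names = FALSE),
    unlist(lapply(subgraphs, function(ss) vapply(ss, `[[`, character(1), "id"))))
  merged <- stage("merge", {
    rb <- hits[hits$reciprocal, , drop = FALSE]
    lapply(seq_len(nrow(rb)), function(i)
      c(list(a = rb$a[i], b = rb$b[i]),
        merge_subgraphs(sub_index[[rb$a[i]]], sub_index[[rb$b[i]]], networks[single],
                        check_reciprocal = FALSE)))
  })

  onto_bundle <- stage("ontology", generate_ontology(design))
  onto <- onto_bundle$ontology
  annot_modes <- lapply(stats::setNames(nm = config$annotation_modes), function(mode)
    annotation_map(onto, onto_bundle$annotations, use_iea = mode))

  enrich_nets <- names(networks)
  enrichments <- list(); coverages <- list()
  for (mode in config$annotation_modes) {
    for (nm in enrich_nets) {
      key <- paste(nm, mode, sep = ".")
      enr <- stage(paste0("enrich:", key),
                   enrich_subgraphs(subgraphs[[nm]], annot_modes[[mode]],
                                    networks[[nm]]$nodes,
                                    fdr_alpha = config$fdr_alpha))
      enrichments[[key]] <- enr
      coverages[[key]] <- cbind(network = nm, mode = mode,
                                coverage(enr, annot_modes[[mode]], onto,
                                         networks[[nm]]$nodes))
    }
  }
  coverage_report <- do.call(rbind, coverages)
  rownames(coverage_report) <- NULL

  random_control <- stage("randomize", {
    rand <- randomize_annotations(annot_modes[["all"]], seed = config$seed + 7919L)
    do.call(rbind, lapply(enrich_nets, function(nm) {
      enr <- enrich_subgraphs(subgraphs[[nm]], rand, networks[[nm]]$nodes,
                              fdr_alpha = config$fdr_alpha)
      cbind(network = nm, coverage(enr, rand, onto, networks[[nm]]$nodes))
    }))
  })

  coenrich <- lapply(stats::setNames(nm = enrich_nets), function(nm)
    coenrichment_pairs(enrichments[[paste(nm, "all", sep = ".")]], onto))

  merged_enrichment <- stage("merged-enrich", {
    if (length(merged) == 0L) NULL else {
      pseudo <- lapply(merged, function(m) {
        s <- subgraph(genes = m$genes,
                          edges = m$edges[, c("from", "to", "weight")],
                          layer = "merged", k_origin = NA_integer_)
        s$id <- paste0("merged_", m$a, "_", m$b)
        s
      })
      enrich_subgraphs(pseudo, annot_modes[["all"]], combined$nodes,
                       fdr_alpha = config$fdr_alpha)
    }
  })
  novel <- if (!is.null(merged_enrichment)) {
    mp <- coenrichment_pairs(merged_enrichment, onto)$pairs
    novel_coenrichment(mp, lapply(coenrich[single], `[[`, "pairs"))
  } else NULL

  rel_enrich <- lapply(stats::setNames(nm = enrich_nets), function(nm) {
    enr <- enrichments[[paste(nm, "all", sep = ".")]]
    tryCatch(relative_enrichment_by_term_size(
      enr, annot_modes[["all"]], networks[[nm]]$nodes,
      mcc_threshold = config$mcc_bin_threshold),
      error = function(e) NULL)
  })

  best_summary <- stage("summary", {
    if (nrow(hits) == 0L) NULL else {
      agg <- stats::aggregate(cbind(best_ab, best_ba, reciprocal) ~ layer_a + layer_b,
                              data = hits, FUN = sum)
      names(agg) <- c("layer_a", "layer_b", "best_a_to_b", "best_b_to_a", "reciprocal")
      agg[order(agg$layer_a, agg$layer_b), , drop = FALSE]
    }
  })

  run <- structure(list(
    config = config, networks = networks, calls = calls,
    discoveries = discoveries, subgraphs = subgraphs,
    hits = hits, best_graph = best_graph, high_degree = hd,
    merged = merged, ontology = onto, annotations = annot_modes,
    leaf_terms = onto_bundle$leaf_terms,
    enrichments = enrichments, coverage = coverage_report,
    random_control = random_control, coenrichment = coenrich,
    merged_enrichment = merged_enrichment, novel_pairs = novel,
    relative_enrichment = rel_enrich, best_summary = best_summary,
    elapsed = proc.time()[["elapsed"]] - t0), class = "congru_run")
  if (!is.null(out_dir)) write_bundle(run, out_dir)
  run
}

#' @export
print.congru_run <- function(x, ...) {
  cat("<congru_run>\n")
  for (nm in names(x$subgraphs))
    cat(sprintf("  %-16s %4d subgraphs (%d nodes, %d edges)\n", nm,
                length(x$subgraphs[[nm]]), length(x$networks[[nm]]$nodes),
                nrow(x$networks[[nm]]$edges)))
  cat(sprintf("  congruence: %d scored pairs, %d best hits, %d reciprocal\n",
              nrow(x$hits), sum(x$hits$best_ab | x$hits$best_ba),
              sum(x$hits$reciprocal)))
  cat(sprintf("  high-degree subgraphs: %d (neighbourhood %d)\n",
              length(x$high_degree$high_degree), length(x$high_degree$neighbourhood)))
  cat(sprintf("  elapsed: %.1f s\n", x$elapsed))
  invisible(x)
}

#' Score recovery of planted shared modules
#'
#' For every module expressed by both topology layers, checks whether some
#' reciprocal best hit between those layers matches the planted gene set
#' with at least `jaccard_min` Jaccard similarity on both sides.
#'
#' @param run a `congru_run`.
#' @param jaccard_min similarity threshold (default 0.8).
#' @return List with `recovered` (named logical over shared modules),
#'   `rate`, and `detail` data frame of the best matching pair per module.
#' @export
score_module_recovery <- function(run, jaccard_min = 0.8) {
  design <- run$config$design
  shared <- design$shared
  topo <- names(design$layer_modules)
  rb <- run$hits[run$hits$reciprocal &
                 run$hits$layer_a %in% topo & run$hits$layer_b %in% topo, ,
                 drop = FALSE]
  sub_index <- stats::setNames(
    unlist(run$subgraphs, recursive = FALSE, use.names = FALSE),
    unlist(lapply(run$subgraphs, function(ss) vapply(ss, `[[`, character(1), "id"))))
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  detail <- lapply(shared, function(m) {
    planted <- design$modules[[m]]
    if (nrow(rb) == 0L)
      return(data.frame(module = names(design$modules)[m], a = NA, b = NA,
                        jaccard_a = 0, jaccard_b = 0, recovered = FALSE))
    ja <- vapply(rb$a, function(id) jac(sub_index[[id]]$genes, planted), numeric(1))
    jb <- vapply(rb$b, function(id) jac(sub_index[[id]]$genes, planted), numeric(1))
    best <- which.max(pmin(ja, jb))
    data.frame(module = names(design$modules)[m], a = rb$a[best], b = rb$b[best],
               jaccard_a = ja[best], jaccard_b = jb[best],
               recovered = ja[best] >= jaccard_min && jb[best] >= jaccard_min,
               stringsAsFactors = FALSE)
  })
  detail <- do.call(rbind, detail)
  list(recovered = stats::setNames(detail$recovered, detail$module),
       rate = mean(detail$recovered), detail = detail)
}

#' Write a run's report bundle to a directory
#'
#' Deterministic plain-text exports: subgraph catalogues, the hits table,
#' best-hit summary, coverage and randomization reports, co-enrichment
#' tables (incl. novel integration-only pairs), relative-enrichment tables,
#' merged subnetwork edge lists, network edge lists and a provenance JSON.
#'
#' @param run a `congru_run`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) formatC(x, format = "g", digits = 12))
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  for (nm in names(run$subgraphs)) {
    tsv(subgraph_catalogue(run$subgraphs[[nm]]), sprintf("subgraphs_%s.tsv", nm))
    write_edge_list(run$networks[[nm]], file.path(dir, sprintf("network_%s.txt", nm)))
  }
  tsv(run$hits, "congruence_hits.tsv")
  if (!is.null(run$best_summary)) tsv(run$best_summary, "best_hit_summary.tsv")
  tsv(run$coverage, "coverage.tsv")
  jsonlite::write_json(run$coverage, file.path(dir, "coverage.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  tsv(run$random_control, "randomization_control.tsv")
  for (nm in names(run$coenrichment)) {
    tsv(run$coenrichment[[nm]]$summary, sprintf("coenrichment_summary_%s.tsv", nm))
  }
  if (!is.null(run$novel_pairs)) tsv(run$novel_pairs, "novel_coenrichment.tsv")
  for (nm in names(run$relative_enrichment)) {
    if (!is.null(run$relative_enrichment[[nm]]))
      tsv(run$relative_enrichment[[nm]], sprintf("relative_enrichment_%s.tsv", nm))
  }
  if (length(run$merged)) {
    me <- do.call(rbind, lapply(run$merged, function(m)
      cbind(pair = paste0(m$a, "_", m$b), m$edges)))
    tsv(me, "merged_subnetworks.tsv")
  }
  jsonlite::write_json(provenance(run), file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

provenance <- function(run) {
  cfg <- run$config
  list(seed = cfg$seed,
       thresholds = cfg[c("alpha_validate", "n_min", "m_min", "fdr_alpha",
                          "mcc_bin_threshold", "high_degree_percentile",
                          "coreg_scale", "min_size", "balance_tol")],
       design = list(n_genes = cfg$design$n_genes,
                     module_size = cfg$design$module_size,
                     p_in = cfg$design$p_in, p_out = cfg$design$p_out,
                     annotation_noise = cfg$design$annotation_noise,
                     seeds = as.list(cfg$design$seeds)),
       k_plans = lapply(run$discoveries, function(d) d$plan$k),
       n_subgraphs = lapply(run$subgraphs, length),
       # diagnostic: largest fraction of a network's subgraphs containing
       # any one gene (module discovery should not be dominated by hubs)
       max_gene_recurrence = lapply(run$subgraphs, function(ss) {
         if (length(ss) == 0L) return(0)
         max(table(unlist(lapply(ss, `[[`, "genes")))) / length(ss)
       }),
       bh_pool = "all subgraph x term tests per network and mode")
}
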