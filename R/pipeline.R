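#' Run the full ceRNA inference pipeline on a data bundle
#'
#' Executes every stage in dependency order on an in-memory bundle (a
#' [generate_bundle()] result or a list with the same elements read from
#' files): differential screening of lncRNAs and mRNAs, miRNA catalogue
#' reconciliation, target-edge filtering, correlation pairing, triplet
#' assembly, network construction, topology and hub/key selection,
#' over-representation analysis of the miRNA-targeted mRNAs, the
#' key-lncRNA ceRNA-pathway layer, axis extraction, and the TF network.
#' Identical inputs and thresholds yield identical outputs; when `out_dir`
#' is given every intermediate table is written there as TSV plus network
#' exports (SIF, GraphML) and a manifest of per-stage row counts.
#'
#' @param bundle list with elements lnc_mat, mrna_mat, groups,
#'   mirna_evidence, db_universe, lnc_edges, mrna_edges, gene_sets,
#'   tf_bindings (expansion_map optional).
#' @param fc_screen screening fold-change cutoff (strict). Default 1.5.
#' @param fc_refine assembly refinement fold-change cutoff (strict).
#'   Default 2.
#' @param p_threshold p-value cutoff used throughout (strict). Default
#'   0.05.
#' @param mrna_score miRNA->mRNA score cutoff (strict). Default 80.
#' @param lncrna_score miRNA->lncRNA score cutoff; NULL (default) uses the
#'   upper-decile rule of [filter_targets()].
#' @param r_threshold correlation cutoff (strict). Default 0.99.
#' @param hub_degree hub degree cutoff (strict). Default 5.
#' @param k_per_direction key lncRNAs per direction. Default 3.
#' @param min_sites TF binding-site cutoff (inclusive). Default 1.
#' @param welch,abs_r,strict_mirna_direction optional behaviour flags
#'   passed to the respective stages.
#' @param out_dir optional output directory for all artifact files.
#' @return list of class "cerna_pipeline" with every stage result plus
#'   `manifest` (stage/row-count table) and the thresholds used.
#' @export
run_pipeline <- function(bundle,
                         fc_screen = 1.5, fc_refine = 2,
                         p_threshold = 0.05,
                         mrna_score = 80, lncrna_score = NULL,
                         r_threshold = 0.99,
                         hub_degree = 5, k_per_direction = 3,
                         min_sites = 1,
                         welch = FALSE, abs_r = FALSE,
                         strict_mirna_direction = FALSE,
                         out_dir = NULL) {
  need <- c("lnc_mat", "mrna_mat", "groups", "mirna_evidence",
            "lnc_edges", "mrna_edges")
  miss <- setdiff(need, names(bundle))
  if (length(miss))
    stop("pipeline configuration error: bundle lacks input(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  lnc_de <- stage("de_lncrna",
                  de_screen(bundle$lnc_mat, bundle$groups, kind = "lncRNA",
                            fc_threshold = fc_screen,
                            p_threshold = p_threshold, welch = welch))
  mrna_de <- stage("de_mrna",
                   de_screen(bundle$mrna_mat, bundle$groups, kind = "mRNA",
                             fc_threshold = fc_screen,
                             p_threshold = p_threshold, welch = welch))

  catalogue <- stage("mirna_catalogue",
                     reconcile_mirna(bundle$mirna_evidence,
                                     db_universe = bundle$db_universe,
                                     expansion_map = bundle$expansion_map))
  retained <- retained_mirnas(catalogue)

  lnc_edges_f <- stage("filter_lnc_targets",
                       filter_targets(bundle$lnc_edges, retained, lnc_de,
                                      mrna_score = mrna_score,
                                      lncrna_score = lncrna_score))
  mrna_edges_f <- stage("filter_mrna_targets",
                        filter_targets(bundle$mrna_edges, retained, mrna_de,
                                       mrna_score = mrna_score,
                                       lncrna_score = lncrna_score))

  pairs <- stage("coexpression_pairs",
                 coexpression_pairs(bundle$lnc_mat, bundle$mrna_mat,
                                    lnc_de, mrna_de,
                                    r_threshold = r_threshold,
                                    p_threshold = p_threshold,
                                    abs_r = abs_r))

  de_all <- rbind(lnc_de, mrna_de)
  triplets <- stage("assemble_triplets",
                    assemble_triplets(pairs, lnc_edges_f, mrna_edges_f,
                                      de_all, refine_fc = fc_refine,
                                      refine_p = p_threshold,
                                      mirna_directions = retained,
                                      strict_mirna_direction =
                                        strict_mirna_direction))
  network <- stage("build_network",
                   build_network(triplets, de_records = de_all,
                                 mirna_directions = retained))
  cent <- stage("centralities", network_centralities(network))
  hubs <- stage("select_hubs", select_hubs(cent, min_degree = hub_degree))
  keys <- stage("select_key_lncrnas",
                withCallingHandlers(
                  select_key_lncrnas(hubs,
                                     k_per_direction = k_per_direction,
                                     min_degree = hub_degree),
                  warning = function(w) invokeRestart("muffleWarning")))

  # over-representation of the miRNA-targeted dysregulated mRNAs
  query <- sort(unique(mrna_edges_f$target))
  enrichment <- if (length(query) && !is.null(bundle$gene_sets))
    stage("enrichment",
          hypergeom_enrich(query, bundle$gene_sets, alpha = p_threshold))
  else NULL

  pnet <- axes <- NULL
  if (!is.null(enrichment) && nrow(keys)) {
    pnet <- stage("pathway_network",
                  suppressWarnings(
                    pathway_network(keys, triplets, enrichment,
                                    bundle$gene_sets)))
    axes <- stage("extract_axes", extract_axes(pnet))
  }

  tfnet <- if (!is.null(bundle$tf_bindings) && !is.null(pnet) &&
               nrow(pnet$triplets))
    stage("tf_network",
          tf_network(bundle$tf_bindings, unique(pnet$triplets$mrna),
                     min_sites = min_sites))
  else NULL
  if (!is.null(tfnet) && !is.null(axes) && nrow(axes))
    axes <- stage("extract_axes",
                  extract_axes(pnet, tf_net = tfnet))

  # axis referential integrity: every axis triple must be a triplet
  if (!is.null(axes) && nrow(axes)) {
    key3 <- paste(triplets$lncrna, triplets$mirna, triplets$mrna)
    if (!all(paste(axes$lncrna, axes$mirna, axes$mrna) %in% key3))
      stop("pipeline integrity error: axis not backed by a triplet",
           call. = FALSE)
  }

  thresholds <- list(fc_screen = fc_screen, fc_refine = fc_refine,
                     p_threshold = p_threshold, mrna_score = mrna_score,
                     lncrna_score = attr(lnc_edges_f, "thresholds")[["lncRNA"]],
                     r_threshold = r_threshold, hub_degree = hub_degree,
                     k_per_direction = k_per_direction,
                     min_sites = min_sites)
  manifest <- data.frame(
    stage = c("de_lncrna", "de_mrna", "mirna_catalogue", "mirna_retained",
              "lnc_edges", "mrna_edges", "pairs", "triplets",
              "network_nodes", "network_edges", "hubs", "key_lncrnas",
              "enriched_terms", "axes", "tf_edges"),
    rows = c(sum(lnc_de$direction != "ns"), sum(mrna_de$direction != "ns"),
             nrow(catalogue), nrow(retained), nrow(lnc_edges_f),
             nrow(mrna_edges_f), nrow(pairs), nrow(triplets),
             nrow(network$nodes), nrow(network$edges), nrow(hubs),
             nrow(keys),
             if (is.null(enrichment)) 0L else sum(enrichment$significant),
             if (is.null(axes)) 0L else nrow(axes),
             if (is.null(tfnet)) 0L else nrow(tfnet$edges)),
    stringsAsFactors = FALSE)

  res <- structure(list(lnc_de = lnc_de, mrna_de = mrna_de,
                        catalogue = catalogue, retained = retained,
                        lnc_edges = lnc_edges_f, mrna_edges = mrna_edges_f,
                        pairs = pairs, triplets = triplets,
                        network = network, centralities = cent,
                        hubs = hubs, key_lncrnas = keys,
                        enrichment = enrichment, pathway_net = pnet,
                        axes = axes, tf_net = tfnet,
                        thresholds = thresholds, manifest = manifest),
                   class = "cerna_pipeline")
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

#' @export
print.cerna_pipeline <- function(x, ...) {
  cat("ceRNA inference pipeline run\n")
  print(x$manifest, row.names = FALSE)
  invisible(x)
}

#' Write every pipeline artifact to a directory
#'
#' @param result a [run_pipeline()] result.
#' @param out_dir output directory (created if needed).
#' @return named vector of files written.
#' @export
write_pipeline <- function(result, out_dir) {
  stopifnot(inherits(result, "cerna_pipeline"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  files <- character()
  put <- function(df, f) {
    if (!is.null(df)) {
      write_tsv_file(df, p(f))
      files <<- c(files, f)
    }
  }
  put(result$lnc_de, "de_lncrna.tsv")
  put(result$mrna_de, "de_mrna.tsv")
  put(result$catalogue, "mirna_catalogue.tsv")
  put(result$lnc_edges, "lncrna_edges_filtered.tsv")
  put(result$mrna_edges, "mrna_edges_filtered.tsv")
  put(result$pairs, "coexpression_pairs.tsv")
  put(result$triplets, "triplets.tsv")
  put(result$centralities, "centralities.tsv")
  put(result$hubs, "hubs.tsv")
  put(result$key_lncrnas, "key_lncrnas.tsv")
  put(result$enrichment, "enrichment.tsv")
  put(result$axes, "axes.tsv")
  if (!is.null(result$tf_net)) {
    put(result$tf_net$edges, "tf_edges.tsv")
    put(result$tf_net$ranking, "tf_ranking.tsv")
  }
  if (nrow(result$network$nodes)) {
    write_sif(result$network, p("network.sif"))
    write_graphml(result$network, p("network.graphml"))
    write_node_attributes(result$network, p("network_nodes.tsv"))
    files <- c(files, "network.sif", "network.graphml",
               "network_nodes.tsv")
  }
  put(result$manifest, "manifest.tsv")
  stats::setNames(file.path(out_dir, files), files)
}

#' Triplet recovery against a planted ground truth
#'
#' Compares an inferred triplet table with the planted triplets of a
#' synthetic bundle and reports precision, recall and F1.
#'
#' @param triplets inferred triplet table (lncrna, mirna, mrna).
#' @param truth planted triplet table with the same columns.
#' @return list with precision, recall, f1, n_inferred, n_true.
#' @export
triplet_recovery <- function(triplets, truth) {
  inf <- unique(paste(triplets$lncrna, triplets$mirna, triplets$mrna))
  tru <- unique(paste(truth$lncrna, truth$mirna, truth$mrna))
  tp <- length(intersect(inf, tru))
  precision <- if (length(inf)) tp / length(inf) else NA_real_
  recall <- if (length(tru)) tp / length(tru) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(precision = precision, recall = recall, f1 = f1,
       n_inferred = length(inf), n_true = length(tru))
}
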