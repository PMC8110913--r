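#' Key-lncRNA ceRNA-pathway network
#'
#' Restricts the triplet table to triplets containing a key lncRNA and
#' attaches each member mRNA to the significant enriched terms that contain
#' it, producing a four-layer network (lncRNA, miRNA, mRNA, pathway). Key
#' lncRNAs that participate in no triplet are dropped with a warning.
#'
#' @param key_lncrnas character vector of key lncRNA ids (or a data.frame
#'   with an id column, e.g. [select_key_lncrnas()] output).
#' @param triplets assembled triplet table.
#' @param enrichment [hypergeom_enrich()] output; only rows with
#'   `significant == TRUE` attach pathways.
#' @param collection the [gene_set_collection()] the enrichment was run
#'   against (supplies term membership).
#' @return list of class "cerna_pathway_network" with elements `triplets`
#'   (restricted rows), `mrna_terms` (mrna, term, name), and
#'   `lncrna_pathway_counts` (lncrna, n_pathways: number of distinct
#'   significant terms reachable through its partner mRNAs).
#' @export
pathway_network <- function(key_lncrnas, triplets, enrichment, collection) {
  if (is.data.frame(key_lncrnas)) key_lncrnas <- key_lncrnas$id
  key_lncrnas <- unique(key_lncrnas)
  absent <- setdiff(key_lncrnas, triplets$lncrna)
  if (length(absent))
    warning("key lncRNA(s) absent from every triplet omitted: ",
            paste(absent, collapse = ", "), call. = FALSE)
  keep <- intersect(key_lncrnas, triplets$lncrna)
  sub <- triplets[triplets$lncrna %in% keep, , drop = FALSE]
  sub <- sub[order(sub$lncrna, sub$mirna, sub$mrna), , drop = FALSE]
  rownames(sub) <- NULL

  sig <- enrichment[enrichment$significant, , drop = FALSE]
  mrnas <- unique(sub$mrna)
  links <- lapply(seq_len(nrow(sig)), function(i) {
    members <- collection$sets[[sig$term[i]]]
    hit <- intersect(mrnas, members)
    if (!length(hit)) return(NULL)
    data.frame(mrna = hit, term = sig$term[i], name = sig$name[i],
               stringsAsFactors = FALSE)
  })
  mrna_terms <- do.call(rbind, links)
  if (is.null(mrna_terms))
    mrna_terms <- data.frame(mrna = character(), term = character(),
                             name = character(), stringsAsFactors = FALSE)
  mrna_terms <- mrna_terms[order(mrna_terms$mrna, mrna_terms$term), ,
                           drop = FALSE]
  rownames(mrna_terms) <- NULL

  counts <- vapply(keep, function(l) {
    partner <- unique(sub$mrna[sub$lncrna == l])
    length(unique(mrna_terms$term[mrna_terms$mrna %in% partner]))
  }, 1L)
  lnc_counts <- data.frame(lncrna = keep, n_pathways = unname(counts),
                           stringsAsFactors = FALSE)
  lnc_counts <- lnc_counts[order(lnc_counts$lncrna), , drop = FALSE]
  rownames(lnc_counts) <- NULL

  structure(list(triplets = sub, mrna_terms = mrna_terms,
                 lncrna_pathway_counts = lnc_counts),
            class = "cerna_pathway_network")
}

#' Extract lncRNA-miRNA-mRNA regulatory axes
#'
#' Enumerates the key-lncRNA triplet chains of a ceRNA-pathway network,
#' optionally restricted to a focus mRNA, and annotates each chain with the
#' significant pathways containing its mRNA and (optionally) the TFs
#' regulating it.
#'
#' @param pnet a [pathway_network()] result.
#' @param focus optional mRNA id; only axes ending in it are returned (an
#'   unknown id yields an empty list with a warning).
#' @param tf_net optional [tf_network()] result used to attach regulators.
#' @return data.frame with columns lncrna, mirna, mrna, pathways
#'   (";"-separated term ids), tfs (";"-separated TF ids), sorted by
#'   (lncrna, mirna, mrna).
#' @export
extract_axes <- function(pnet, focus = NULL, tf_net = NULL) {
  stopifnot(inherits(pnet, "cerna_pathway_network"))
  ax <- pnet$triplets
  if (!is.null(focus)) {
    if (!focus %in% ax$mrna) {
      warning("focus mRNA '", focus, "' not present in the network",
              call. = FALSE)
      ax <- ax[0, , drop = FALSE]
    } else ax <- ax[ax$mrna == focus, , drop = FALSE]
  }
  paths <- vapply(ax$mrna, function(g)
    paste(sort(unique(pnet$mrna_terms$term[pnet$mrna_terms$mrna == g])),
          collapse = ";"), character(1))
  tfs <- if (!is.null(tf_net))
    vapply(ax$mrna, function(g)
      paste(sort(unique(tf_net$edges$tf[tf_net$edges$gene == g])),
            collapse = ";"), character(1))
  else rep("", nrow(ax))
  out <- data.frame(lncrna = ax$lncrna, mirna = ax$mirna, mrna = ax$mrna,
                    pathways = unname(paths), tfs = unname(tfs),
                    stringsAsFactors = FALSE)
  out <- out[order(out$lncrna, out$mirna, out$mrna), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' TF-to-mRNA binding network from site-count tables
#'
#' Filters a transcription-factor binding table (one row per TF-gene pair
#' with the number of predicted binding sites in a promoter window,
#' conventionally 1000 bp upstream / 100 bp downstream) down to the mRNAs
#' of interest and a minimum site count, then ranks TFs by the number of
#' retained targets (out-degree), using the summed site count as the
#' tie-break. A higher site count is read as a stronger prediction; with no
#' published count cutoff the default `min_sites = 1` keeps every predicted
#' pair.
#'
#' @param bindings data.frame with columns tf, gene, site_count.
#' @param target_mrnas character vector of mRNA ids to keep.
#' @param min_sites minimum (inclusive) site count. Default 1.
#' @return list of class "tf_network" with `edges` (tf, gene, site_count,
#'   directed TF->gene) and `ranking` (tf, n_targets, total_sites, ordered
#'   by out-degree then summed sites descending, then tf id).
#' @export
tf_network <- function(bindings, target_mrnas, min_sites = 1) {
  stopifnot(all(c("tf", "gene", "site_count") %in% names(bindings)),
            min_sites >= 1)
  if (any(bindings$site_count < 0))
    stop("site_count must be non-negative", call. = FALSE)
  keep <- bindings$gene %in% target_mrnas & bindings$site_count >= min_sites
  edges <- bindings[keep, c("tf", "gene", "site_count"), drop = FALSE]
  edges <- edges[order(edges$tf, edges$gene), , drop = FALSE]
  rownames(edges) <- NULL

  if (nrow(edges)) {
    agg_n <- tapply(edges$gene, edges$tf, function(x) length(unique(x)))
    agg_s <- tapply(edges$site_count, edges$tf, sum)
    ranking <- data.frame(tf = names(agg_n),
                          n_targets = as.integer(agg_n),
                          total_sites = as.numeric(agg_s),
                          stringsAsFactors = FALSE)
    ranking <- ranking[order(-ranking$n_targets, -ranking$total_sites,
                             ranking$tf), , drop = FALSE]
    rownames(ranking) <- NULL
  } else {
    ranking <- data.frame(tf = character(), n_targets = integer(),
                          total_sites = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(edges = edges, ranking = ranking,
                 min_sites = min_sites), class = "tf_network")
}
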