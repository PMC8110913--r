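#' Assemble shared-miRNA ceRNA triplets
#'
#' A ceRNA triplet (l, m, g) is a correlated co-dysregulated lncRNA-mRNA
#' pair (l, g) whose two members are both targeted by a common retained
#' miRNA m. Triplet membership is further refined by requiring both the
#' lncRNA and the mRNA to show |signed_fc| > refine_fc and p < refine_p in
#' the screen (default |FC| > 2, p < 0.05). The miRNA's own direction is
#' not constrained: miRNA dysregulation calls come from external literature
#' evidence without fold changes, and mixed-direction miRNAs can legitimately
#' attach to either lncRNA class. `strict_mirna_direction = TRUE` enables
#' the stricter sponge-consistent rule requiring the miRNA's direction to
#' oppose the pair's shared direction.
#'
#' @param pairs [coexpression_pairs()] output (lncrna, mrna, r, p_value, n).
#' @param lnc_edges filtered miRNA->lncRNA edges (mirna, target).
#' @param mrna_edges filtered miRNA->mRNA edges (mirna, target).
#' @param de_records combined DE screen rows for lncRNAs and mRNAs (gene,
#'   signed_fc, p_value, direction).
#' @param refine_fc ratio bound applied to both pair members, strict.
#'   Default 2.
#' @param refine_p p-value bound applied to both pair members, strict.
#'   Default 0.05.
#' @param mirna_directions optional data.frame (mirna, direction) used only
#'   when `strict_mirna_direction` is TRUE.
#' @param strict_mirna_direction require the shared miRNA's direction to be
#'   opposite to the pair's direction (default FALSE).
#' @return data.frame with columns lncrna, mirna, mrna plus provenance
#'   columns (pair r/p, the two edge scores), sorted lexicographically by
#'   (lncrna, mirna, mrna); duplicates impossible by construction.
#' @export
assemble_triplets <- function(pairs, lnc_edges, mrna_edges, de_records,
                              refine_fc = 2, refine_p = 0.05,
                              mirna_directions = NULL,
                              strict_mirna_direction = FALSE) {
  empty <- data.frame(lncrna = character(), mirna = character(),
                      mrna = character(), r = numeric(),
                      pair_p = numeric(), lnc_score = numeric(),
                      mrna_score = numeric(), stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L || nrow(lnc_edges) == 0L || nrow(mrna_edges) == 0L)
    return(empty)

  ok <- de_records$gene[abs(de_records$signed_fc) > refine_fc &
                          de_records$p_value < refine_p]
  pairs <- pairs[pairs$lncrna %in% ok & pairs$mrna %in% ok, , drop = FALSE]
  if (nrow(pairs) == 0L) return(empty)

  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    l <- pairs$lncrna[i]; g <- pairs$mrna[i]
    ml <- lnc_edges[lnc_edges$target == l, , drop = FALSE]
    mg <- mrna_edges[mrna_edges$target == g, , drop = FALSE]
    shared <- intersect(ml$mirna, mg$mirna)
    if (!length(shared)) return(NULL)
    data.frame(lncrna = l, mirna = shared, mrna = g,
               r = pairs$r[i], pair_p = pairs$p_value[i],
               lnc_score = ml$score[match(shared, ml$mirna)],
               mrna_score = mg$score[match(shared, mg$mirna)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)

  if (strict_mirna_direction) {
    if (is.null(mirna_directions))
      stop("mirna_directions required when strict_mirna_direction = TRUE",
           call. = FALSE)
    pair_dir <- de_records$direction[match(out$lncrna, de_records$gene)]
    mir_dir <- mirna_directions$direction[match(out$mirna,
                                                mirna_directions$mirna)]
    opp <- (pair_dir == "up" & mir_dir == "down") |
      (pair_dir == "down" & mir_dir == "up")
    out <- out[!is.na(opp) & opp, , drop = FALSE]
  }

  out <- out[order(out$lncrna, out$mirna, out$mrna), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the typed ceRNA network from assembled triplets
#'
#' Takes the union of all triplet edges (lncRNA-miRNA and miRNA-mRNA) into
#' an undirected simple graph. Node attributes (type, direction, signed
#' fold change) are drawn from the DE records and the miRNA catalogue; edge
#' rows carry the ids of the triplets they support. The network is
#' undirected for topology purposes, matching how interactive network
#' analyzers treat ceRNA graphs; regulatory polarity lives in the edge
#' `etype` column ("lncRNA-miRNA" / "miRNA-mRNA").
#'
#' @param triplets [assemble_triplets()] output.
#' @param de_records combined DE rows supplying direction and signed_fc for
#'   lncRNA/mRNA nodes.
#' @param mirna_directions optional (mirna, direction) for miRNA nodes.
#' @return list of class "cerna_network" with elements `nodes` (id, type,
#'   direction, signed_fc) and `edges` (from, to, etype, triplets), both in
#'   deterministic lexicographic order.
#' @export
build_network <- function(triplets, de_records = NULL,
                          mirna_directions = NULL) {
  nodes <- data.frame(id = character(), type = character(),
                      direction = character(), signed_fc = numeric(),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = character(), to = character(),
                      etype = character(), triplets = character(),
                      stringsAsFactors = FALSE)
  if (nrow(triplets)) {
    trip_id <- sprintf("%s|%s|%s", triplets$lncrna, triplets$mirna,
                       triplets$mrna)
    lookup_dir <- function(ids, tab, key, val) {
      if (is.null(tab)) return(rep(NA_character_, length(ids)))
      as.character(tab[[val]][match(ids, tab[[key]])])
    }
    lookup_fc <- function(ids) {
      if (is.null(de_records)) return(rep(NA_real_, length(ids)))
      de_records$signed_fc[match(ids, de_records$gene)]
    }
    ids <- c(unique(triplets$lncrna), unique(triplets$mirna),
             unique(triplets$mrna))
    types <- c(rep("lncRNA", length(unique(triplets$lncrna))),
               rep("miRNA", length(unique(triplets$mirna))),
               rep("mRNA", length(unique(triplets$mrna))))
    dirs <- ifelse(types == "miRNA",
                   lookup_dir(ids, mirna_directions, "mirna", "direction"),
                   lookup_dir(ids, de_records, "gene", "direction"))
    fcs <- ifelse(types == "miRNA", NA_real_, lookup_fc(ids))
    nodes <- data.frame(id = ids, type = types, direction = dirs,
                        signed_fc = fcs, stringsAsFactors = FALSE)
    # one node id must not carry two conflicting annotations
    if (anyDuplicated(nodes$id)) {
      dup <- nodes$id[duplicated(nodes$id)]
      stop("node id(s) appear with more than one type: ",
           paste(unique(dup), collapse = ", "), call. = FALSE)
    }
    bad <- !is.na(nodes$direction) & nodes$type != "miRNA" &
      !(nodes$direction %in% c("up", "down"))
    if (any(bad))
      stop("network nodes must be dysregulated (up/down): ",
           paste(nodes$id[bad], collapse = ", "), call. = FALSE)
    nodes <- nodes[order(nodes$type, nodes$id), , drop = FALSE]
    rownames(nodes) <- NULL

    e1 <- data.frame(from = triplets$lncrna, to = triplets$mirna,
                     etype = "lncRNA-miRNA", triplet = trip_id,
                     stringsAsFactors = FALSE)
    e2 <- data.frame(from = triplets$mirna, to = triplets$mrna,
                     etype = "miRNA-mRNA", triplet = trip_id,
                     stringsAsFactors = FALSE)
    ee <- rbind(e1, e2)
    key <- sprintf("%s\r%s\r%s", ee$from, ee$to, ee$etype)
    agg <- tapply(ee$triplet, key, function(x)
      paste(sort(unique(x)), collapse = ";"))
    parts <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
    edges <- data.frame(from = parts[, 1L], to = parts[, 2L],
                        etype = parts[, 3L],
                        triplets = unname(as.character(agg)),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$etype, edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges), class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  tab <- table(factor(x$nodes$type, levels = c("lncRNA", "miRNA", "mRNA")))
  cat("ceRNA network:", nrow(x$nodes), "nodes (",
      tab[["lncRNA"]], "lncRNA,", tab[["miRNA"]], "miRNA,",
      tab[["mRNA"]], "mRNA ),", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Convert a ceRNA network to an igraph object
#'
#' @param network a "cerna_network" list.
#' @return undirected simple igraph graph with node/edge attributes.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "cerna_network"))
  igraph::graph_from_data_frame(network$edges,
                                directed = FALSE,
                                vertices = network$nodes)
}
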