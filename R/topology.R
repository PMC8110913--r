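#' Node centralities of a ceRNA network
#'
#' Computes degree, normalized betweenness, and closeness for every node of
#' the undirected simple network. Betweenness is the fraction of all-pairs
#' shortest paths passing through a node, normalized by (n-1)(n-2)/2 so the
#' values lie in [0, 1]. Closeness follows the within-component convention
#' used by interactive network analyzers: the number of nodes reachable
#' from a node divided by the summed shortest-path distances to them
#' (isolated nodes score 0), which also lies in [0, 1] on a simple graph.
#' Disconnected graphs are allowed.
#'
#' @param network a "cerna_network" (or an igraph object).
#' @return data.frame with columns id, type, direction, degree,
#'   betweenness, closeness sorted by degree then betweenness descending.
#' @export
network_centralities <- function(network) {
  if (inherits(network, "cerna_network")) {
    if (nrow(network$nodes) == 0L)
      return(data.frame(id = character(), type = character(),
                        direction = character(), degree = integer(),
                        betweenness = numeric(), closeness = numeric(),
                        stringsAsFactors = FALSE))
    g <- as_igraph(network)
    meta <- network$nodes
  } else {
    g <- network
    meta <- data.frame(id = igraph::V(g)$name,
                       type = NA_character_, direction = NA_character_,
                       stringsAsFactors = FALSE)
  }
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  btw <- if (n > 2) igraph::betweenness(g, directed = FALSE,
                                        normalized = TRUE)
  else rep(0, n)

  # closeness: reachable count / summed distances, per component
  d <- igraph::distances(g)
  clo <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (!length(di)) 0 else length(di) / sum(di)
  }, numeric(1))

  ids <- igraph::V(g)$name
  out <- data.frame(id = ids,
                    type = meta$type[match(ids, meta$id)],
                    direction = meta$direction[match(ids, meta$id)],
                    degree = as.integer(deg),
                    betweenness = unname(btw),
                    closeness = unname(clo),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, -out$betweenness, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select hub nodes by degree
#'
#' A node is a hub when its degree strictly exceeds `min_degree` (default
#' 5). The returned records keep their centrality columns so the hub table
#' can be ranked further by betweenness.
#'
#' @param records [network_centralities()] output, or any data.frame with
#'   id, type, degree (and ideally betweenness) columns.
#' @param min_degree strict lower bound on degree. Default 5.
#' @return the hub subset, sorted by degree then betweenness descending.
#' @export
select_hubs <- function(records, min_degree = 5) {
  stopifnot(all(c("id", "degree") %in% names(records)))
  out <- records[records$degree > min_degree, , drop = FALSE]
  if ("betweenness" %in% names(out))
    out <- out[order(-out$degree, -out$betweenness, out$id), , drop = FALSE]
  else out <- out[order(-out$degree, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select key lncRNAs per dysregulation direction
#'
#' Among hub lncRNAs, ranks nodes within each direction (up / down) by
#' degree descending, breaking ties by betweenness descending and then id
#' ascending, and takes the top `k_per_direction` of each. This
#' operationalises "high degree together with high betweenness" as a
#' deterministic selection; an absolute betweenness floor can be imposed
#' with `min_betweenness`.
#'
#' @param records centrality records (id, type, direction, degree,
#'   betweenness); typically [select_hubs()] output.
#' @param k_per_direction how many lncRNAs to keep per direction. Default 3.
#' @param min_degree hub degree bound re-applied defensively. Default 5.
#' @param min_betweenness optional absolute betweenness floor.
#' @return data.frame of the selected lncRNA records with a rank column,
#'   ordered direction (up first) then rank. If a direction holds fewer
#'   than k hub lncRNAs, all are returned with a warning.
#' @export
select_key_lncrnas <- function(records, k_per_direction = 3,
                               min_degree = 5, min_betweenness = NULL) {
  stopifnot(all(c("id", "type", "direction", "degree", "betweenness")
                %in% names(records)))
  lnc <- records[records$type == "lncRNA" & records$degree > min_degree, ,
                 drop = FALSE]
  if (!is.null(min_betweenness))
    lnc <- lnc[lnc$betweenness >= min_betweenness, , drop = FALSE]
  pick <- lapply(c("up", "down"), function(dd) {
    sub <- lnc[lnc$direction == dd, , drop = FALSE]
    sub <- sub[order(-sub$degree, -sub$betweenness, sub$id), , drop = FALSE]
    if (nrow(sub) < k_per_direction)
      warning("only ", nrow(sub), " hub lncRNA(s) in direction '", dd, "'",
              call. = FALSE)
    sub <- utils::head(sub, k_per_direction)
    sub$rank <- seq_len(nrow(sub))
    sub
  })
  out <- do.call(rbind, pick)
  rownames(out) <- NULL
  out
}
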