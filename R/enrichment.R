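#' Benjamini-Hochberg step-up adjustment
#'
#' Thin, domain-checked wrapper around the standard step-up false discovery
#' rate procedure: adjusted p-values are capped at 1, monotone in rank, and
#' returned in the original input order.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Read/construct a gene-set collection
#'
#' @param sets named list of character vectors (term id -> member genes).
#' @param names optional character vector of human-readable term names.
#' @param namespace per-term namespace label (e.g. "GO_BP", "pathway"),
#'   recycled if length 1. Default "pathway".
#' @param universe background gene set; defaults to the union of all
#'   members.
#' @return list of class "gene_set_collection".
#' @export
gene_set_collection <- function(sets, names = NULL, namespace = "pathway",
                                universe = NULL) {
  stopifnot(is.list(sets), !is.null(base::names(sets)))
  if (any(vapply(sets, length, 1L) == 0L))
    stop("empty gene sets are not allowed", call. = FALSE)
  sets <- lapply(sets, unique)
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  out_of_universe <- setdiff(unlist(sets), universe)
  if (length(out_of_universe))
    stop("gene set members outside the declared universe: ",
         paste(utils::head(out_of_universe, 5), collapse = ", "),
         call. = FALSE)
  if (is.null(names)) names <- base::names(sets)
  namespace <- rep_len(namespace, length(sets))
  structure(list(sets = sets, term_names = names,
                 namespace = namespace, universe = universe),
            class = "gene_set_collection")
}

#' Hypergeometric over-representation analysis
#'
#' For each term, tests whether the query gene list hits the term more often
#' than expected by chance using the one-sided upper-tail hypergeometric
#' test: with universe size N, term size K, query size n, and k query genes
#' in the term, p = P(X >= k) for X ~ Hypergeometric(N, K, n). BH
#' adjustment is applied within each namespace separately, as enrichment
#' tools conventionally do. A term is flagged significant when both the raw
#' and the adjusted p-value are below `alpha` (default 0.05).
#'
#' Query genes outside the collection's universe carry no information for
#' the test and are dropped with a warning.
#'
#' @param query character vector of gene ids.
#' @param collection a [gene_set_collection()].
#' @param alpha significance threshold applied to both raw and adjusted p.
#' @return data.frame with columns term, name, namespace, k, K, n, N,
#'   p_value, adjusted_p, significant; sorted by p_value, ties broken by
#'   term id.
#' @export
hypergeom_enrich <- function(query, collection, alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(query) == 0L) stop("empty query gene list", call. = FALSE)
  query <- unique(query)
  drop <- setdiff(query, collection$universe)
  if (length(drop)) {
    warning(length(drop), " query gene(s) outside the universe dropped",
            call. = FALSE)
    query <- intersect(query, collection$universe)
  }
  if (length(collection$sets) == 0L)
    return(data.frame(term = character(), name = character(),
                      namespace = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p_value = numeric(),
                      adjusted_p = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  if (length(query) == 0L)
    stop("no query genes remain inside the universe", call. = FALSE)

  N <- length(collection$universe)
  n <- length(query)
  k <- vapply(collection$sets, function(s) length(intersect(query, s)), 1L)
  K <- vapply(collection$sets, length, 1L)
  # upper tail P(X >= k) = P(X > k - 1)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)

  out <- data.frame(term = names(collection$sets),
                    name = collection$term_names,
                    namespace = collection$namespace,
                    k = k, K = K, n = n, N = N, p_value = unname(p),
                    stringsAsFactors = FALSE)
  out$adjusted_p <- NA_real_
  for (ns in unique(out$namespace)) {
    idx <- out$namespace == ns
    out$adjusted_p[idx] <- bh_adjust(out$p_value[idx])
  }
  out$significant <- out$p_value < alpha & out$adjusted_p < alpha
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top-N enrichment report table
#'
#' @param enrichment [hypergeom_enrich()] output.
#' @param n how many top terms per namespace (default 20).
#' @param significant_only keep only significant terms (default TRUE).
#' @return subset of the enrichment table, per-namespace top n by p-value
#'   with ties broken by term id.
#' @export
top_terms <- function(enrichment, n = 20, significant_only = TRUE) {
  x <- enrichment
  if (significant_only) x <- x[x$significant, , drop = FALSE]
  parts <- lapply(split(x, x$namespace), function(sub) {
    sub <- sub[order(sub$p_value, sub$term), , drop = FALSE]
    utils::head(sub, n)
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) out <- x
  rownames(out) <- NULL
  out
}
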