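#' Filter scored miRNA target predictions against the DE sets
#'
#' Retains a predicted miRNA->RNA edge only when (i) the miRNA is in the
#' retained consensus catalogue, (ii) the target is dysregulated (direction
#' != "ns" in the screen), and (iii) the prediction score strictly exceeds
#' the threshold for the target kind. Edges duplicated across prediction
#' sources are collapsed to one edge keeping the maximum score, i.e. the
#' most confident prediction.
#'
#' Prediction scores live on tool-specific scales: miRNA->mRNA predictions
#' are typically reported on a 0-100 confidence scale (default cutoff 80,
#' strict), while miRNA->lncRNA predictions come on a different scale with
#' no conventional cutoff. When `lncrna_score` is NULL the lncRNA cutoff is
#' taken as the `lncrna_quantile` quantile (default 0.9, i.e. top 10%) of
#' the supplied lncRNA edge score distribution; the cutoff actually used is
#' recorded in the "thresholds" attribute of the result.
#'
#' @param edges data.frame with columns mirna, target, kind ("mRNA" or
#'   "lncRNA"), score, and optionally source.
#' @param de_mirnas retained miRNA catalogue (data.frame with a mirna
#'   column), e.g. [retained_mirnas()] output.
#' @param de_records DE screen results (data.frame with gene, direction).
#' @param mrna_score strict lower bound for mRNA edge scores. Default 80.
#' @param lncrna_score strict lower bound for lncRNA edge scores, or NULL to
#'   use the score-distribution quantile.
#' @param lncrna_quantile quantile defining the lncRNA cutoff when
#'   `lncrna_score` is NULL. Default 0.9.
#' @return filtered, deduplicated edge data.frame sorted by (mirna, target);
#'   attribute "thresholds" records the per-kind cutoffs used.
#' @export
filter_targets <- function(edges, de_mirnas, de_records,
                           mrna_score = 80, lncrna_score = NULL,
                           lncrna_quantile = 0.9) {
  empty <- data.frame(mirna = character(), target = character(),
                      kind = character(), score = numeric(),
                      source = character(), stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) {
    attr(empty, "thresholds") <- c(mRNA = mrna_score, lncRNA = NA_real_)
    return(empty)
  }
  stopifnot(all(c("mirna", "target", "kind", "score") %in% names(edges)))
  if (!all(edges$kind %in% c("mRNA", "lncRNA")))
    stop("unknown target kind: ",
         paste(setdiff(unique(edges$kind), c("mRNA", "lncRNA")),
               collapse = ", "), call. = FALSE)
  if (any(!is.finite(edges$score)))
    stop("scores must be finite", call. = FALSE)
  if (is.null(edges$source)) edges$source <- "unspecified"

  lnc_cut <- lncrna_score
  if (is.null(lnc_cut)) {
    lnc_scores <- edges$score[edges$kind == "lncRNA"]
    lnc_cut <- if (length(lnc_scores))
      unname(stats::quantile(lnc_scores, lncrna_quantile)) else Inf
  }
  cut <- ifelse(edges$kind == "mRNA", mrna_score, lnc_cut)

  de_genes <- de_records$gene[de_records$direction != "ns"]
  keep <- edges$mirna %in% de_mirnas$mirna &
    edges$target %in% de_genes &
    edges$score > cut
  out <- edges[keep, c("mirna", "target", "kind", "score", "source"),
               drop = FALSE]

  # collapse cross-source duplicates, keeping the best-scoring prediction
  if (nrow(out)) {
    out <- out[order(out$mirna, out$target, -out$score), , drop = FALSE]
    out <- out[!duplicated(out[, c("mirna", "target")]), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "thresholds") <- c(mRNA = mrna_score, lncRNA = lnc_cut)
  out
}

#' Correlated co-dysregulated lncRNA-mRNA pairs
#'
#' For every dysregulated lncRNA x dysregulated mRNA combination, computes
#' the Pearson product-moment correlation of expression across all samples
#' (both groups pooled, maximising n) and its two-sided p-value from the
#' t transform with n-2 degrees of freedom. A pair is retained when
#' r > r_threshold and p < p_threshold (both strict). Under the ceRNA
#' sponge hypothesis competing partners are positively co-expressed, so
#' only positive correlations qualify by default; `abs_r = TRUE` switches
#' to a |r| rule.
#'
#' Pairs involving a zero-variance vector have no defined correlation and
#' are skipped with a warning.
#'
#' @param lnc_mat,mrna_mat expression matrices sharing an identical ordered
#'   sample set (columns).
#' @param lnc_de,mrna_de DE screen results for the two matrices; only genes
#'   with direction != "ns" are paired.
#' @param r_threshold strict lower bound on r, in (0, 1). Default 0.99.
#' @param p_threshold strict upper bound on the correlation p-value.
#' @param abs_r test |r| instead of r (default FALSE).
#' @return data.frame with columns lncrna, mrna, r, p_value, n sorted by
#'   (lncrna, mrna).
#' @export
coexpression_pairs <- function(lnc_mat, mrna_mat, lnc_de, mrna_de,
                               r_threshold = 0.99, p_threshold = 0.05,
                               abs_r = FALSE) {
  stopifnot(r_threshold > 0, r_threshold < 1)
  if (ncol(lnc_mat) != ncol(mrna_mat) ||
      !identical(colnames(lnc_mat), colnames(mrna_mat)))
    stop("matrices must share an identical ordered sample set",
         call. = FALSE)
  n <- ncol(lnc_mat)
  if (n < 3L)
    stop("at least 3 shared samples are required for correlation testing",
         call. = FALSE)

  lncs <- intersect(lnc_de$gene[lnc_de$direction != "ns"], rownames(lnc_mat))
  mrnas <- intersect(mrna_de$gene[mrna_de$direction != "ns"],
                     rownames(mrna_mat))
  empty <- data.frame(lncrna = character(), mrna = character(),
                      r = numeric(), p_value = numeric(), n = integer(),
                      stringsAsFactors = FALSE)
  if (!length(lncs) || !length(mrnas)) return(empty)

  lsub <- lnc_mat[lncs, , drop = FALSE]
  msub <- mrna_mat[mrnas, , drop = FALSE]
  lvar <- apply(lsub, 1L, stats::var)
  mvar <- apply(msub, 1L, stats::var)
  if (any(lvar == 0) || any(mvar == 0)) {
    warning("skipping zero-variance gene(s) in correlation pairing",
            call. = FALSE)
    lsub <- lsub[lvar > 0, , drop = FALSE]
    msub <- msub[mvar > 0, , drop = FALSE]
  }
  if (!nrow(lsub) || !nrow(msub)) return(empty)

  rmat <- stats::cor(t(lsub), t(msub))
  # two-sided p from the exact t transform, df = n - 2
  tstat <- rmat * sqrt((n - 2) / pmax(1 - rmat^2, .Machine$double.eps))
  pmat <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)

  rv <- if (abs_r) abs(rmat) else rmat
  hits <- which(rv > r_threshold & pmat < p_threshold, arr.ind = TRUE)
  if (!nrow(hits)) return(empty)
  out <- data.frame(lncrna = rownames(rmat)[hits[, 1L]],
                    mrna = colnames(rmat)[hits[, 2L]],
                    r = rmat[hits], p_value = pmat[hits], n = n,
                    stringsAsFactors = FALSE)
  out <- out[order(out$lncrna, out$mrna), , drop = FALSE]
  rownames(out) <- NULL
  out
}
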