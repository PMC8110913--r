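#' Signed ratio fold change between two groups
#'
#' Computes the case/control ratio of group means and reports it in the
#' signed-ratio convention used throughout the pipeline: a value of +2 means
#' the case mean is twice the control mean; -2 means the control mean is
#' twice the case mean. The magnitude is therefore always >= 1, so a single
#' threshold such as |FC| > 1.5 applies symmetrically to both directions.
#'
#' @param case_values numeric vector of strictly positive case-group values.
#' @param control_values numeric vector of strictly positive control-group
#'   values.
#' @return a single signed ratio with absolute value >= 1.
#' @examples
#' signed_fold_change(c(4, 5, 6), c(1, 2, 3))  # +2.5
#' signed_fold_change(c(1, 2, 3), c(4, 5, 6))  # -2.5
#' @export
signed_fold_change <- function(case_values, control_values) {
  if (length(case_values) == 0L || length(control_values) == 0L)
    stop("both groups must contain at least one value", call. = FALSE)
  if (any(!is.finite(case_values)) || any(!is.finite(control_values)))
    stop("expression values must be finite", call. = FALSE)
  if (any(case_values <= 0) || any(control_values <= 0))
    stop("expression values must be strictly positive for ratio fold change",
         call. = FALSE)
  r <- mean(case_values) / mean(control_values)
  if (r >= 1) r else -1 / r
}

#' Validate an expression matrix against its sample sheet
#'
#' @param mat numeric matrix, genes in rows (unique rownames), samples in
#'   columns.
#' @param groups character vector, one of "case"/"control" per column of
#'   `mat`.
#' @keywords internal
validate_expression <- function(mat, groups) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("expression must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stop("expression matrix requires unique gene ids as rownames",
         call. = FALSE)
  if (length(groups) != ncol(mat))
    stop("one group label is required per sample column", call. = FALSE)
  if (!all(groups %in% c("case", "control")))
    stop("group labels must be 'case' or 'control'", call. = FALSE)
  if (sum(groups == "case") < 2L || sum(groups == "control") < 2L)
    stop("at least 2 samples per group are required", call. = FALSE)
  if (any(!is.finite(mat)) || any(mat <= 0))
    stop("expression values must be finite and strictly positive",
         call. = FALSE)
  invisible(TRUE)
}

#' Two-class differential expression screen
#'
#' For every gene, computes the signed ratio fold change between case and
#' control group means and a two-sided two-sample t-test p-value. The test is
#' run on log2-transformed values by default, which stabilises the variance
#' of ratio-scale intensity data; set `log_transform = FALSE` to test on the
#' linear scale. Student's (equal-variance) t is the default; `welch = TRUE`
#' switches to the Welch approximation. Genes are flagged "up" when
#' signed_fc >= fc_threshold and p < p_threshold, "down" symmetrically, and
#' "ns" otherwise. No multiple-testing correction is applied at this stage:
#' the screen deliberately filters on raw p-values, so downstream consumers
#' should treat the gene lists as candidate sets, not FDR-controlled calls.
#'
#' Genes with zero variance in both groups and equal means (flat probes) are
#' retained with p = 1 and direction "ns" rather than raising an error.
#'
#' @param mat numeric matrix of positive intensities, genes x samples,
#'   unique gene ids as rownames.
#' @param groups "case"/"control" label per column.
#' @param kind gene kind recorded in the output ("lncRNA" or "mRNA").
#' @param fc_threshold ratio threshold (> 1); a gene is dysregulated only if
#'   |signed_fc| strictly exceeds it. Default 1.5.
#' @param p_threshold raw p-value cutoff in (0, 1), strict. Default 0.05.
#' @param log_transform test on log2 values (default TRUE).
#' @param welch use the Welch unequal-variance t-test (default FALSE).
#' @return data.frame with columns gene, kind, signed_fc, p_value,
#'   direction, ordered by ascending p-value.
#' @export
de_screen <- function(mat, groups, kind = "mRNA",
                      fc_threshold = 1.5, p_threshold = 0.05,
                      log_transform = TRUE, welch = FALSE) {
  validate_expression(mat, groups)
  stopifnot(fc_threshold > 1, p_threshold > 0, p_threshold < 1)
  case_idx <- groups == "case"
  ctrl_idx <- groups == "control"
  tmat <- if (log_transform) log2(mat) else mat

  fc <- apply(mat, 1L, function(x)
    signed_fold_change(x[case_idx], x[ctrl_idx]))
  p <- apply(tmat, 1L, function(x) {
    a <- x[case_idx]; b <- x[ctrl_idx]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      # degenerate: no within-group spread; equal means carry no evidence,
      # unequal means separate perfectly (p kept > 0 per the record contract)
      return(if (mean(a) == mean(b)) 1 else .Machine$double.xmin)
    }
    stats::t.test(a, b, var.equal = !welch)$p.value
  })

  direction <- rep("ns", nrow(mat))
  direction[fc >= fc_threshold & p < p_threshold] <- "up"
  direction[fc <= -fc_threshold & p < p_threshold] <- "down"

  out <- data.frame(gene = rownames(mat), kind = kind,
                    signed_fc = unname(fc), p_value = unname(p),
                    direction = direction, stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relative quantification by the 2^-ddCt method
#'
#' Standard relative qPCR quantification: the target gene's cycle threshold
#' is normalised to a reference gene within each condition, and the
#' case-vs-control difference of those deltas is exponentiated, giving the
#' fold change of the target relative to the reference between conditions.
#'
#' @param ct_target_case,ct_ref_case mean Ct of target and reference gene in
#'   the case condition.
#' @param ct_target_ctrl,ct_ref_ctrl mean Ct of target and reference gene in
#'   the control condition.
#' @return relative expression 2^-((dCt_case) - (dCt_control)).
#' @examples
#' ddct_quantify(25, 20, 24, 20)  # ddCt = 1 -> 0.5
#' @export
ddct_quantify <- function(ct_target_case, ct_ref_case,
                          ct_target_ctrl, ct_ref_ctrl) {
  vals <- c(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl)
  if (any(!is.finite(vals)))
    stop("Ct values must be finite", call. = FALSE)
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
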