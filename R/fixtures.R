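# Bundled example data: the published spinal cord ischemia/reperfusion
# injury (SCII) rat study tables that the desk-scale worked examples run
# on. The miRNA evidence file is a synthetic reconstruction: miRNA names,
# directions, conflicts and the precursor are as published, but per-dataset
# attribution of the unconflicted calls is nominal (the publication lists
# only the pooled catalogue).

extdata <- function(f) {
  path <- system.file("extdata", f, package = "cernet")
  if (path == "") stop("bundled file not found: ", f, call. = FALSE)
  path
}

#' Literature miRNA evidence for the SCII case study
#'
#' A 78-candidate miRNA catalogue gathered from 9 rat SCII expression
#' datasets, reconstructed from the published study tables: one candidate
#' (rno-miR-320a) absent from the target database, two reported with
#' conflicting directions across datasets (rno-miR-22-3p in three
#' datasets, rno-miR-632 in two), and one precursor (rno-miR-323) with two
#' mature forms. Dataset attribution of the unconflicted calls is
#' synthetic (nominal round-robin over the 9 published dataset ids); the
#' conflicts are attributed to the datasets the publication names.
#'
#' @return list with `evidence` (mirna, dataset, direction, method),
#'   `db_universe` (character), `expansion_map` (precursor, mature),
#'   `datasets` (the 9 declared dataset ids).
#' @export
scii_mirna_evidence <- function() {
  list(evidence = read_tsv_file(extdata("scii_mirna_evidence_synthetic.tsv")),
       db_universe = readLines(extdata("scii_mirdb_universe.txt")),
       expansion_map = read_tsv_file(extdata("scii_mirna_expansion.tsv")),
       datasets = c("HJR2013", "LL2015", "LJA2016", "LXQ2016", "LXQ2018",
                    "LY2018", "WXY2019", "HF2020", "ZGL2020"))
}

#' Published hub table of the SCII ceRNA network
#'
#' The 69 nodes of the published SCII ceRNA network with degree above 5,
#' with their betweenness and closeness centralities, dysregulation
#' direction and molecular type, as printed in the study.
#'
#' @return data.frame with columns id, betweenness, closeness, degree,
#'   direction, type.
#' @export
scii_hub_table <- function() {
  read_tsv_file(extdata("scii_hub_table.tsv"))
}

#' Published information on the six candidate SCII lncRNAs
#'
#' Fold change, p-value and centralities of the six key lncRNAs selected
#' in the published study.
#'
#' @return data.frame with columns id, fold_change, p_value, degree,
#'   betweenness, closeness, direction.
#' @export
scii_key_lncrna_info <- function() {
  read_tsv_file(extdata("scii_key_lncrna_info.tsv"))
}
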