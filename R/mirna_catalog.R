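#' Reconcile multi-study miRNA evidence into a consensus catalogue
#'
#' Literature surveys of differentially expressed miRNAs typically pool calls
#' from several independent datasets, which requires three reconciliation
#' rules before the calls can seed a target analysis:
#'
#' \enumerate{
#'   \item a miRNA reported as up in one dataset and down in another carries
#'     conflicting evidence and is dropped entirely (no majority vote);
#'   \item a miRNA absent from the target-prediction database universe
#'     cannot contribute target edges and is dropped;
#'   \item a precursor-level name with several annotated mature forms is
#'     expanded into its mature children, each inheriting the precursor's
#'     direction and counted individually.
#' }
#'
#' The db-absence check is applied to mature names after expansion, since it
#' is a constraint of the downstream target database.
#'
#' @param evidence data.frame with columns mirna, dataset, direction
#'   ("up"/"down"); an optional method column is carried as provenance.
#' @param db_universe character vector of mature miRNA ids present in the
#'   target-prediction database. NULL skips the membership check.
#' @param expansion_map data.frame with columns precursor, mature mapping
#'   precursor names to their mature forms. NULL skips expansion.
#' @param datasets optional character vector of declared dataset ids; when
#'   supplied, evidence rows referencing an undeclared dataset are an error.
#' @return data.frame with columns mirna, direction, status, n_datasets,
#'   datasets, precursor. `status` is one of "retained", "expanded_child"
#'   (retained, created by precursor expansion), "dropped_conflict",
#'   "dropped_not_in_db". The retained catalogue is the subset with status
#'   in (retained, expanded_child).
#' @export
reconcile_mirna <- function(evidence, db_universe = NULL,
                            expansion_map = NULL, datasets = NULL) {
  if (nrow(evidence) == 0L)
    return(data.frame(mirna = character(), direction = character(),
                      status = character(), n_datasets = integer(),
                      datasets = character(), precursor = character(),
                      stringsAsFactors = FALSE))
  req <- c("mirna", "dataset", "direction")
  if (!all(req %in% names(evidence)))
    stop("evidence requires columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (!all(evidence$direction %in% c("up", "down")))
    stop("direction must be 'up' or 'down'", call. = FALSE)
  if (!is.null(datasets)) {
    bad <- setdiff(unique(evidence$dataset), datasets)
    if (length(bad))
      stop("evidence references undeclared dataset id(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }

  # order-independence: canonicalise row order before grouping
  evidence <- evidence[order(evidence$mirna, evidence$dataset,
                             evidence$direction), , drop = FALSE]

  per <- split(evidence, evidence$mirna)
  rows <- lapply(names(per), function(id) {
    ev <- per[[id]]
    dirs <- unique(ev$direction)
    dsets <- unique(ev$dataset)
    if (length(dirs) > 1L)
      return(data.frame(mirna = id, direction = NA_character_,
                        status = "dropped_conflict",
                        n_datasets = length(dsets),
                        datasets = paste(dsets, collapse = ";"),
                        precursor = NA_character_,
                        stringsAsFactors = FALSE))
    data.frame(mirna = id, direction = dirs,
               status = "retained", n_datasets = length(dsets),
               datasets = paste(dsets, collapse = ";"),
               precursor = NA_character_, stringsAsFactors = FALSE)
  })
  cat <- do.call(rbind, rows)

  # precursor expansion: replace each mapped precursor by its mature forms
  if (!is.null(expansion_map) && nrow(expansion_map) > 0L) {
    stopifnot(all(c("precursor", "mature") %in% names(expansion_map)))
    keep <- cat[!(cat$mirna %in% expansion_map$precursor &
                    cat$status == "retained"), , drop = FALSE]
    todo <- cat[cat$mirna %in% expansion_map$precursor &
                  cat$status == "retained", , drop = FALSE]
    if (nrow(todo)) {
      children <- do.call(rbind, lapply(seq_len(nrow(todo)), function(i) {
        prec <- todo[i, ]
        mats <- expansion_map$mature[expansion_map$precursor == prec$mirna]
        data.frame(mirna = mats, direction = prec$direction,
                   status = "expanded_child", n_datasets = prec$n_datasets,
                   datasets = prec$datasets, precursor = prec$mirna,
                   stringsAsFactors = FALSE)
      }))
      cat <- rbind(keep, children)
    } else cat <- keep
  }

  # database membership applies to mature names, after expansion
  if (!is.null(db_universe)) {
    miss <- cat$status %in% c("retained", "expanded_child") &
      !(cat$mirna %in% db_universe)
    cat$status[miss] <- "dropped_not_in_db"
  }

  cat <- cat[order(cat$mirna), , drop = FALSE]
  rownames(cat) <- NULL
  cat
}

#' Retained subset of a reconciled miRNA catalogue
#'
#' @param catalogue output of [reconcile_mirna()].
#' @return rows with status "retained" or "expanded_child".
#' @export
retained_mirnas <- function(catalogue) {
  out <- catalogue[catalogue$status %in% c("retained", "expanded_child"), ,
                   drop = FALSE]
  rownames(out) <- NULL
  out
}
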