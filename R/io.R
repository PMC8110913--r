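# File formats: tab-separated UTF-8, '#' comment lines, no quoting --
# importable by spreadsheets and network-visualization tools alike.

write_tsv_file <- function(df, path, comment = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_file <- function(path, ...) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", quote = "", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Read an expression matrix with its sample sheet
#'
#' The matrix file is tab-separated with the gene id in the first column
#' and one column per sample; the sample sheet maps sample ids to the
#' "case"/"control" groups.
#'
#' @param matrix_path path to the matrix TSV.
#' @param samples_path path to a two-column TSV (sample, group).
#' @return list with `mat` (numeric matrix, genes x samples) and `groups`
#'   (character vector aligned to the matrix columns).
#' @export
read_expression <- function(matrix_path, samples_path) {
  raw <- read_tsv_file(matrix_path)
  if (ncol(raw) < 2L)
    stop("expression matrix needs a gene column plus >= 1 sample column",
         call. = FALSE)
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate gene id(s) in ", matrix_path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  vals <- raw[, -1L, drop = FALSE]
  bad <- which(!vapply(vals, is.numeric, TRUE))
  if (length(bad))
    stop("non-numeric expression column(s) in ", matrix_path, ": ",
         paste(names(vals)[bad], collapse = ", "), call. = FALSE)
  mat <- as.matrix(vals)
  rownames(mat) <- ids

  sheet <- read_tsv_file(samples_path)
  if (!all(c("sample", "group") %in% names(sheet)))
    stop("sample sheet requires columns: sample, group", call. = FALSE)
  idx <- match(colnames(mat), sheet$sample)
  if (any(is.na(idx)))
    stop("sample(s) missing from sheet: ",
         paste(colnames(mat)[is.na(idx)], collapse = ", "), call. = FALSE)
  list(mat = mat, groups = as.character(sheet$group[idx]))
}

#' Write an expression matrix and sample sheet
#'
#' @param mat numeric matrix with gene rownames.
#' @param groups group label per column.
#' @param matrix_path,samples_path output paths.
#' @param gene_col name of the id column. Default "gene".
#' @export
write_expression <- function(mat, groups, matrix_path, samples_path,
                             gene_col = "gene") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- gene_col
  write_tsv_file(df, matrix_path)
  write_tsv_file(data.frame(sample = colnames(mat), group = groups,
                            stringsAsFactors = FALSE), samples_path)
  invisible(matrix_path)
}

#' Read a gene-set collection from a GMT file
#'
#' GMT is the tab-delimited gene-set format: one set per line as
#' name, description, member genes.
#'
#' @param path GMT file path.
#' @param namespace namespace label applied to every set. Default
#'   "pathway".
#' @param universe optional explicit background; defaults to the union of
#'   members.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, namespace = "pathway", universe = NULL) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, 1L) < 3L)
  if (length(short))
    stop("malformed GMT line(s) (need name, description, >=1 gene): line ",
         paste(short, collapse = ", "), call. = FALSE)
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate gene-set id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  sets <- lapply(parts, function(x) x[-(1:2)])
  names(sets) <- ids
  descs <- vapply(parts, `[[`, "", 2L)
  gene_set_collection(sets, names = descs, namespace = namespace,
                      universe = universe)
}

#' Write a gene-set collection to GMT
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(seq_along(collection$sets), function(i)
    paste(c(names(collection$sets)[i], collection$term_names[i],
            collection$sets[[i]]), collapse = "\t"), character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Export a ceRNA network in SIF format
#'
#' One line per edge: source, interaction type, target.
#'
#' @param network a "cerna_network".
#' @param path output path.
#' @export
write_sif <- function(network, path) {
  stopifnot(inherits(network, "cerna_network"))
  lines <- sprintf("%s\t%s\t%s", network$edges$from, network$edges$etype,
                   network$edges$to)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Export a ceRNA network in GraphML format
#'
#' Node attributes (type, direction, signed_fc) and edge attributes (etype,
#' supporting triplets) are preserved so the file re-imports with identical
#' annotation.
#'
#' @param network a "cerna_network".
#' @param path output path.
#' @export
write_graphml <- function(network, path) {
  g <- as_igraph(network)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Import a GraphML file written by [write_graphml()]
#'
#' @param path GraphML file path.
#' @return a "cerna_network" with nodes/edges reconstructed from the file's
#'   attributes.
#' @export
read_graphml <- function(path) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(id = igraph::V(g)$name,
                      type = igraph::V(g)$type,
                      direction = igraph::V(g)$direction,
                      signed_fc = igraph::V(g)$signed_fc,
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$type, nodes$id), , drop = FALSE]
  el <- igraph::as_edgelist(g)
  edges <- data.frame(from = el[, 1L], to = el[, 2L],
                      etype = igraph::E(g)$etype,
                      triplets = igraph::E(g)$triplets,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$etype, edges$from, edges$to), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "cerna_network")
}

#' Write node attributes of a ceRNA network
#'
#' @param network a "cerna_network".
#' @param path output TSV path.
#' @export
write_node_attributes <- function(network, path) {
  stopifnot(inherits(network, "cerna_network"))
  write_tsv_file(network$nodes, path)
}
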