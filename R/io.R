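#' Read and write the pipeline's plain-text interchange formats
#'
#' All stages communicate through small tab-separated files so that any stage
#' can be re-run independently: fold-change tables (`probe_id`, `condition`,
#' `ratio`), probe maps (`probe_id`, `gene_id`), edge lists (two-column TSV or
#' three-column SIF), GMT gene-set catalogs, one-symbol-per-line gene lists,
#' and CT tables (`sample`, `gene`, `replicate`, `ct`).
#'
#' @param path File path.
#' @param x Object to serialize.
#' @return The parsed object, or (for writers) `path` invisibly.
#' @name perturbnet-io
NULL

#' @rdname perturbnet-io
#' @export
read_fold_changes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  fold_change_table(df)
}

#' @rdname perturbnet-io
#' @export
write_fold_changes <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname perturbnet-io
#' @export
read_probe_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_that(all(c("probe_id", "gene_id") %in% names(df)),
              "probe map needs columns probe_id, gene_id")
  df[c("probe_id", "gene_id")]
}

#' @rdname perturbnet-io
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  unique(x[nzchar(x)])
}

#' @rdname perturbnet-io
#' @export
write_gene_list <- function(x, path) {
  writeLines(as.character(x), path)
  invisible(path)
}

#' Read an undirected edge list (TSV or SIF)
#'
#' Two-column files are read as `node_a<TAB>node_b`; three-column files as
#' SIF (`node_a<TAB>relation<TAB>node_b`), the relation being discarded.
#' Header lines whose first field is `node_a` are skipped.
#'
#' @param path File path.
#' @return A two-column character matrix of edges.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "[\t ]+")
  if (length(parts) && identical(parts[[1]][1], "node_a")) {
    parts <- parts[-1]
  }
  nf <- lengths(parts)
  assert_that(all(nf %in% c(2L, 3L)),
              "edge list rows must have 2 (TSV) or 3 (SIF) fields")
  edges <- t(vapply(parts, function(p) p[c(1L, length(p))], character(2)))
  colnames(edges) <- c("node_a", "node_b")
  edges
}

#' @rdname perturbnet-io
#' @export
write_edge_list <- function(x, path) {
  if (inherits(x, "igraph")) x <- igraph::as_edgelist(x)
  colnames(x) <- c("node_a", "node_b")
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set catalog
#'
#' One category per line: `id<TAB>description<TAB>member1<TAB>member2...`.
#' The background universe is not part of the GMT format and must be given
#' (or defaults to the union of all members).
#'
#' @param path GMT file path.
#' @param universe Character vector of background genes.
#' @param collection `"go_like"` or `"kegg_like"`.
#' @return An [annotation_catalog()].
#' @export
read_gmt <- function(path, universe = NULL, collection = "go_like") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  assert_that(all(lengths(parts) >= 3L),
              "GMT rows need id, description and at least one member")
  ids <- vapply(parts, `[[`, character(1), 1L)
  desc <- vapply(parts, `[[`, character(1), 2L)
  members <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(members) <- ids
  if (is.null(universe)) universe <- sort(unique(unlist(members)))
  annotation_catalog(members, universe, collection = collection,
                     descriptions = stats::setNames(desc, ids))
}

#' @rdname perturbnet-io
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "annotation_catalog"))
  desc <- x$descriptions %||% stats::setNames(names(x$categories),
                                              names(x$categories))
  lines <- vapply(names(x$categories), function(id) {
    paste(c(id, desc[[id]], x$categories[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname perturbnet-io
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_that(all(c("sample", "gene", "replicate", "ct") %in% names(df)),
              "CT table needs columns sample, gene, replicate, ct")
  df
}

#' @rdname perturbnet-io
#' @export
write_ct_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
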