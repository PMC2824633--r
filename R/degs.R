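#' Construct a fold-change table
#'
#' Per-probe linear-scale expression ratios (treated/control), one row per
#' (probe, condition).  Ratios must be strictly positive; a ratio of 1 means
#' no change, 0.5 a two-fold decrease.
#'
#' @param df Data frame with columns `probe_id`, `condition`, `ratio`.
#' @return The validated data frame with class `fold_change_table`.
#' @export
fold_change_table <- function(df) {
  assert_that(all(c("probe_id", "condition", "ratio") %in% names(df)),
              "fold-change table needs columns probe_id, condition, ratio")
  df <- as.data.frame(df)[c("probe_id", "condition", "ratio")]
  assert_that(is.numeric(df$ratio) && all(is.finite(df$ratio)) &&
                all(df$ratio > 0),
              "ratios must be finite and strictly positive")
  assert_that(!anyDuplicated(df[c("probe_id", "condition")]),
              "one entry per (probe, condition) required")
  class(df) <- c("fold_change_table", "data.frame")
  df
}

#' Select probes deregulated at least `threshold`-fold
#'
#' A probe is selected iff its ratio is `>= threshold` (up) or
#' `<= 1/threshold` (down); the boundary is inclusive on both sides
#' ("altered at least 2-fold").
#'
#' @param table A [fold_change_table()].
#' @param condition Condition label to filter.
#' @param threshold Fold-change threshold, > 1 (default 2).
#' @return Data frame `probe_id`, `ratio`, `direction` ("up"/"down").
#' @export
#' @examples
#' tab <- fold_change_table(data.frame(
#'   probe_id = c("a", "b", "c"), condition = "KD1",
#'   ratio = c(0.25, 1, 3)))
#' filter_probes(tab, "KD1")
filter_probes <- function(table, condition, threshold = 2) {
  stopifnot(inherits(table, "fold_change_table"))
  assert_that(threshold > 1, "threshold must exceed 1")
  assert_that(condition %in% table$condition,
              "unknown condition: ", condition)
  sub <- table[table$condition == condition, , drop = FALSE]
  up <- sub$ratio >= threshold
  down <- sub$ratio <= 1 / threshold
  out <- data.frame(
    probe_id = sub$probe_id[up | down],
    ratio = sub$ratio[up | down],
    direction = ifelse(sub$ratio[up | down] >= threshold, "up", "down"),
    stringsAsFactors = FALSE)
  out[order(out$ratio), , drop = FALSE]
}

#' Collapse deregulated probes to genes
#'
#' A gene is deregulated iff at least one of its probes passes the filter in
#' a direction.  The representative fold change is the most extreme passing
#' ratio in that direction (min for down, max for up).  Genes with passing
#' probes in both directions are flagged discordant and excluded from both
#' sets; selected probes absent from the map are reported, never silently
#' dropped.
#'
#' @param probes Output of [filter_probes()].
#' @param probe_map Data frame `probe_id`, `gene_id` (many-to-one).
#' @return A list: `genes` (data frame `gene_id`, `direction`,
#'   `fold_change`, sorted ascending by fold change), `unmapped` (probe ids
#'   with no map entry), `discordant` (excluded gene ids).
#' @export
collapse_to_genes <- function(probes, probe_map) {
  assert_that(all(c("probe_id", "ratio", "direction") %in% names(probes)),
              "probes must come from filter_probes()")
  m <- match(probes$probe_id, probe_map$probe_id)
  unmapped <- probes$probe_id[is.na(m)]
  probes <- probes[!is.na(m), , drop = FALSE]
  probes$gene_id <- probe_map$gene_id[m[!is.na(m)]]

  per_gene <- split(probes, probes$gene_id)
  discordant <- names(per_gene)[vapply(per_gene, function(p) {
    length(unique(p$direction)) > 1
  }, logical(1))]
  per_gene <- per_gene[setdiff(names(per_gene), discordant)]
  genes <- do.call(rbind, lapply(per_gene, function(p) {
    dir <- p$direction[[1]]
    data.frame(gene_id = p$gene_id[[1]], direction = dir,
               fold_change = if (dir == "down") min(p$ratio) else max(p$ratio),
               stringsAsFactors = FALSE)
  }))
  if (is.null(genes)) {
    genes <- data.frame(gene_id = character(), direction = character(),
                        fold_change = numeric(), stringsAsFactors = FALSE)
  }
  genes <- genes[order(genes$fold_change), , drop = FALSE]
  rownames(genes) <- NULL
  list(genes = genes, unmapped = unmapped, discordant = discordant)
}

#' Call deregulated gene sets for every condition
#'
#' Runs [filter_probes()] and [collapse_to_genes()] per condition.
#'
#' @param table A [fold_change_table()].
#' @param probe_map Data frame `probe_id`, `gene_id`.
#' @param threshold Fold-change threshold (> 1).
#' @return An object of class `deregulated_sets`: per condition, the
#'   gene-level calls (`genes`, `unmapped`, `discordant`).
#' @export
deregulated_sets <- function(table, probe_map, threshold = 2) {
  stopifnot(inherits(table, "fold_change_table"))
  conditions <- unique(table$condition)
  out <- lapply(conditions, function(cn) {
    collapse_to_genes(filter_probes(table, cn, threshold), probe_map)
  })
  names(out) <- conditions
  structure(list(conditions = out, threshold = threshold),
            class = "deregulated_sets")
}

#' @export
print.deregulated_sets <- function(x, ...) {
  cat("deregulated_sets (threshold ", x$threshold, "-fold):\n", sep = "")
  for (cn in names(x$conditions)) {
    g <- x$conditions[[cn]]$genes
    cat(sprintf("  %s: %d genes (%d down, %d up)", cn, nrow(g),
                sum(g$direction == "down"), sum(g$direction == "up")))
    nd <- length(x$conditions[[cn]]$discordant)
    if (nd) cat(";", nd, "discordant excluded")
    cat("\n")
  }
  invisible(x)
}

#' Partition two deregulated gene sets into unique and common parts
#'
#' Exact set difference and intersection; a gene is common iff it passes in
#' both conditions, regardless of direction agreement (disagreements are
#' flagged in the `direction_conflict` column).  Per-condition fold changes
#' are carried into the common table.
#'
#' @param set_a,set_b Gene call data frames (`gene_id`, `direction`,
#'   `fold_change`) as produced by [collapse_to_genes()], or entries of
#'   [deregulated_sets()].
#' @param labels Length-2 character vector naming the conditions.
#' @return List with `unique_a`, `unique_b` (same shape as inputs, sorted
#'   ascending by fold change) and `common` (`gene_id`, `fold_change_a`,
#'   `fold_change_b`, `direction_a`, `direction_b`, `direction_conflict`).
#' @export
partition_sets <- function(set_a, set_b, labels = c("A", "B")) {
  grab <- function(s) if (is.list(s) && !is.data.frame(s)) s$genes else s
  set_a <- grab(set_a); set_b <- grab(set_b)
  shared <- intersect(set_a$gene_id, set_b$gene_id)
  ua <- set_a[!set_a$gene_id %in% shared, , drop = FALSE]
  ub <- set_b[!set_b$gene_id %in% shared, , drop = FALSE]
  ia <- match(shared, set_a$gene_id)
  ib <- match(shared, set_b$gene_id)
  common <- data.frame(
    gene_id = shared,
    fold_change_a = set_a$fold_change[ia],
    fold_change_b = set_b$fold_change[ib],
    direction_a = set_a$direction[ia],
    direction_b = set_b$direction[ib],
    stringsAsFactors = FALSE)
  common$direction_conflict <- common$direction_a != common$direction_b
  common <- common[order(common$fold_change_a), , drop = FALSE]
  rownames(ua) <- rownames(ub) <- rownames(common) <- NULL
  structure(list(unique_a = ua, unique_b = ub, common = common,
                 labels = labels),
            class = "set_partition")
}

#' @export
print.set_partition <- function(x, ...) {
  cat(sprintf("set_partition: %d unique to %s, %d unique to %s, %d common\n",
              nrow(x$unique_a), x$labels[1], nrow(x$unique_b), x$labels[2],
              nrow(x$common)))
  if (any(x$common$direction_conflict)) {
    cat("  note:", sum(x$common$direction_conflict),
        "common genes with conflicting directions\n")
  }
  invisible(x)
}

#' Write a three-block unique/unique/common gene table
#'
#' Serializes a [partition_sets()] result as a TSV with a `block` column
#' (`unique_<A>`, `unique_<B>`, `common`), fold-change columns and the gene
#' symbol, each block ordered ascending by fold change.
#'
#' @param partition A `set_partition`.
#' @param path Output TSV path.
#' @export
write_partition_table <- function(partition, path) {
  stopifnot(inherits(partition, "set_partition"))
  la <- partition$labels[1]; lb <- partition$labels[2]
  blk <- function(df, block, fa, fb) {
    if (!nrow(df)) {
      return(data.frame(block = character(), fold_change_a = numeric(),
                        fold_change_b = numeric(), gene_symbol = character(),
                        stringsAsFactors = FALSE))
    }
    data.frame(block = block, fold_change_a = fa, fold_change_b = fb,
               gene_symbol = df$gene_id, stringsAsFactors = FALSE)
  }
  out <- rbind(
    blk(partition$unique_a, paste0("unique_", la),
        partition$unique_a$fold_change, NA_real_),
    blk(partition$unique_b, paste0("unique_", lb),
        NA_real_, partition$unique_b$fold_change),
    blk(partition$common, "common",
        partition$common$fold_change_a, partition$common$fold_change_b))
  names(out)[2:3] <- paste0("fold_change_", c(la, lb))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
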