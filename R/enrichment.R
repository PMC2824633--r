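#' Construct an annotation catalog
#'
#' Named gene categories (GO-like terms or a fixed KEGG-like pathway
#' collection) over a background universe — all genes represented on the
#' expression platform.  Members outside the universe are rejected;
#' category ids must be unique and categories non-empty.
#'
#' @param categories Named list of character vectors (category id -> member
#'   genes).
#' @param universe Character vector: the background gene universe.
#' @param collection `"go_like"` or `"kegg_like"`.
#' @param descriptions Optional named character vector of category
#'   descriptions.
#' @return Object of class `annotation_catalog`.
#' @export
annotation_catalog <- function(categories, universe,
                               collection = c("go_like", "kegg_like"),
                               descriptions = NULL) {
  collection <- match.arg(collection)
  assert_that(length(universe) >= 1 && !anyDuplicated(universe),
              "universe must be a non-empty set of distinct genes")
  assert_that(!is.null(names(categories)) && all(nzchar(names(categories))),
              "categories must be named")
  assert_that(!anyDuplicated(names(categories)),
              "duplicate category ids rejected")
  assert_that(all(lengths(categories) >= 1),
              "categories of size 0 rejected")
  categories <- lapply(categories, unique)
  stray <- setdiff(unlist(categories), universe)
  assert_that(length(stray) == 0,
              "category members outside the universe: ",
              paste(utils::head(stray, 5), collapse = ", "))
  structure(list(categories = categories, universe = universe,
                 collection = collection, descriptions = descriptions),
            class = "annotation_catalog")
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat(sprintf("annotation_catalog (%s): %d categories over %d genes\n",
              x$collection, length(x$categories), length(x$universe)))
  invisible(x)
}

#' Restrict a catalog to a new (smaller) universe
#'
#' Intersects every category and the universe with `genes`; categories left
#' empty are dropped.  Used to re-base a chip-wide catalog onto the genes
#' present in an interactome.
#'
#' @param catalog An [annotation_catalog()].
#' @param genes Character vector of genes to keep.
#' @return A new `annotation_catalog`.
#' @export
restrict_catalog <- function(catalog, genes) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  universe <- intersect(catalog$universe, genes)
  cats <- lapply(catalog$categories, intersect, universe)
  cats <- cats[lengths(cats) > 0]
  annotation_catalog(cats, universe, collection = catalog$collection,
                     descriptions = catalog$descriptions)
}

# Category sizes (m) and changed-in-category counts (k) for a changed set,
# vectorized over the catalog.
catalog_counts <- function(catalog, changed) {
  m <- lengths(catalog$categories)
  k <- vapply(catalog$categories, function(mem) {
    sum(changed %in% mem)
  }, integer(1))
  list(k = k, m = m)
}

# One-sided (over-representation) hypergeometric upper-tail p-values,
# vectorized: P(X >= k), X ~ Hypergeom(N, m, n).
hyper_upper_p <- function(k, m, n, N) {
  stats::phyper(k - 1L, m, N - m, n, lower.tail = FALSE)
}

#' Category over-representation by one-sided Fisher's exact test
#'
#' For each category: `k` changed genes in the category, `m` category size,
#' `n` changed genes total, `N` universe size.  The enrichment ratio is the
#' proportion of changed genes in the category relative to the category's
#' expected proportion over the whole platform, `(k/n) / (m/N)`; the p-value
#' is the upper hypergeometric tail `P(X >= k)` (one-sided Fisher's exact
#' test for over-representation).
#'
#' @param changed Character vector of deregulated genes.  Genes outside the
#'   universe are dropped with a warning.
#' @param catalog An [annotation_catalog()].  Categories with no members in
#'   the universe are skipped.
#' @return Data frame `category`, `k`, `m`, `n`, `N`, `enrichment`, `p`,
#'   sorted ascending by p.
#' @export
#' @examples
#' cat10 <- annotation_catalog(list(c1 = paste0("g", 1:4)), paste0("g", 1:10))
#' fisher_enrich(paste0("g", 1:3), cat10)$p  # 1/30
fisher_enrich <- function(changed, catalog) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  assert_that(length(catalog$universe) > 0, "empty universe")
  changed <- unique(changed)
  stray <- setdiff(changed, catalog$universe)
  if (length(stray)) {
    warning(length(stray), " changed gene(s) outside the universe dropped: ",
            paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
    changed <- setdiff(changed, stray)
  }
  assert_that(length(changed) > 0, "empty changed set")
  cc <- catalog_counts(catalog, changed)
  n <- length(changed)
  N <- length(catalog$universe)
  out <- data.frame(
    category = names(catalog$categories),
    k = cc$k, m = cc$m, n = n, N = N,
    enrichment = (cc$k / n) / (cc$m / N),
    p = hyper_upper_p(cc$k, cc$m, n, N),
    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Randomization false-discovery rate for category enrichment
#'
#' For each of `R` randomizations, `|changed|` genes are drawn uniformly
#' without replacement from the universe and all category p-values are
#' recomputed.  The FDR of a category with observed p-value `p0` is the mean
#' over randomizations of
#' `#(null p <= p0) / max(1, #(observed p <= p0))` — the expected count of
#' null categories at least as significant, relative to the observed count —
#' clipped to `[0, 1]` and made monotone non-decreasing in p.  Ties are
#' counted inclusively (`<=`).
#'
#' @param changed Character vector of deregulated genes.
#' @param catalog An [annotation_catalog()].
#' @param R Number of randomizations (>= 1; 1000 in production use).
#' @param seed RNG seed for the null draws.
#' @return The [fisher_enrich()] data frame with an `fdr` column appended.
#' @export
randomization_fdr <- function(changed, catalog, R = 1000, seed = 1L) {
  assert_that(R >= 1, "need at least one randomization")
  obs <- fisher_enrich(changed, catalog)
  n <- obs$n[[1]]
  universe <- catalog$universe
  N <- length(universe)
  m <- lengths(catalog$categories)
  # denominator: observed categories at least as significant (ties inclusive)
  obs_counts <- vapply(obs$p, function(p0) sum(obs$p <= p0), integer(1))
  null_exceed <- matrix(0L, nrow = R, ncol = nrow(obs))
  with_seed(child_seed(seed, "fdr"), {
    member_idx <- lapply(catalog$categories, match, table = universe)
    for (r in seq_len(R)) {
      draw <- sample.int(N, n)
      z <- logical(N); z[draw] <- TRUE
      k_null <- vapply(member_idx, function(idx) sum(z[idx]), integer(1))
      p_null <- sort(hyper_upper_p(k_null, m, n, N))
      null_exceed[r, ] <- findInterval(obs$p, p_null)
    }
  })
  fdr <- colMeans(null_exceed) / pmax(1L, obs_counts)
  fdr <- pmin(1, pmax(0, fdr))
  obs$fdr <- cummax(fdr)  # obs is sorted by p; enforce monotonicity in p
  obs
}

#' Fixed-collection pathway test with Bonferroni correction
#'
#' One-sided Fisher's exact p per pathway as in [fisher_enrich()], then
#' Bonferroni adjustment across the collection:
#' `adjusted p = min(1, p * collection size)` (38 for the default pathway
#' collection).
#'
#' @param changed Character vector of deregulated genes.
#' @param catalog An [annotation_catalog()] tagged `kegg_like`.
#' @return [fisher_enrich()] data frame with an `adjusted_p` column.
#' @export
kegg_collection_test <- function(changed, catalog) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  assert_that(identical(catalog$collection, "kegg_like"),
              "catalog must be tagged kegg_like")
  out <- fisher_enrich(changed, catalog)
  out$adjusted_p <- pmin(1, out$p * length(catalog$categories))
  out
}

#' Write an enrichment result table
#'
#' @param x Result of [fisher_enrich()], [randomization_fdr()] or
#'   [kegg_collection_test()].
#' @param path Output TSV path.
#' @export
write_enrichment <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
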