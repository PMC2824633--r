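#' Construct a protein-protein interaction graph
#'
#' An undirected simple graph over gene/protein symbols: self-loops and
#' parallel edges are removed on construction.
#'
#' @param edges Two-column matrix/data frame of symbol pairs, or an existing
#'   `igraph` object.
#' @return An undirected simple `igraph` with named vertices.
#' @export
ppi_graph <- function(edges) {
  if (inherits(edges, "igraph")) {
    g <- edges
    assert_that(!is.null(igraph::V(g)$name), "graph vertices must be named")
    if (igraph::is_directed(g)) g <- igraph::as_undirected(g)
  } else {
    edges <- as.matrix(edges)
    assert_that(ncol(edges) == 2, "edge list must have two columns")
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  }
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

# Plain adjacency list (integer indices) — the hot loop of the null ensemble
# avoids igraph calls per replicate.
adjacency_index <- function(graph) {
  nodes <- igraph::V(graph)$name
  adj <- igraph::as_adj_list(graph, mode = "all")
  list(nodes = nodes, adj = lapply(adj, as.integer))
}

expand_indices <- function(idx, seed_ids) {
  unique(c(seed_ids, unlist(idx$adj[seed_ids], use.names = FALSE)))
}

#' Expand seed genes through the interactome at depth 1 plus
#'
#' Takes the seeds matched in the graph, adds all their immediate
#' interacting partners (depth 1), and keeps every interaction among the
#' resulting nodes — seed--seed, seed--interactor and
#' interactor--interactor alike (depth 1 plus); i.e. the induced subgraph on
#' seeds plus their neighborhood.  Seeds absent from the graph are recorded
#' as unmatched, never dropped silently.
#'
#' @param graph A [ppi_graph()].
#' @param seeds Character vector of target gene symbols.
#' @return Object of class `expanded_network`: `matched_seeds`,
#'   `unmatched_seeds`, `interactors`, `nodes`, `graph` (the induced
#'   `igraph` subgraph), `components` (membership vector), `n_components`.
#' @export
#' @examples
#' g <- ppi_graph(cbind(c("A", "B", "C"), c("B", "C", "D")))
#' net <- expand_depth1plus(g, c("A", "C"))
#' sort(net$nodes)  # A B C D
expand_depth1plus <- function(graph, seeds) {
  assert_that(inherits(graph, "igraph") && igraph::vcount(graph) > 0,
              "empty graph")
  seeds <- unique(seeds)
  vnames <- igraph::V(graph)$name
  matched <- intersect(seeds, vnames)
  unmatched <- setdiff(seeds, vnames)
  if (length(matched) == 0) {
    sub <- igraph::make_empty_graph(0, directed = FALSE)
    return(structure(list(
      matched_seeds = character(), unmatched_seeds = unmatched,
      interactors = character(), nodes = character(), graph = sub,
      components = integer(), n_components = 0L),
      class = "expanded_network"))
  }
  nbr_ids <- unique(unlist(igraph::adjacent_vertices(graph, matched),
                           use.names = FALSE))
  nodes <- union(matched, vnames[nbr_ids])
  sub <- igraph::induced_subgraph(graph, nodes)
  comp <- igraph::components(sub)
  structure(list(
    matched_seeds = matched,
    unmatched_seeds = unmatched,
    interactors = setdiff(nodes, matched),
    nodes = igraph::V(sub)$name,
    graph = sub,
    components = comp$membership,
    n_components = comp$no),
    class = "expanded_network")
}

#' @export
print.expanded_network <- function(x, ...) {
  cat(sprintf(
    "expanded_network: %d nodes (%d seeds + %d interactors), %d edges, %d component(s)\n",
    length(x$nodes), length(x$matched_seeds), length(x$interactors),
    igraph::ecount(x$graph), x$n_components))
  if (length(x$unmatched_seeds)) {
    cat("  unmatched seeds:", paste(x$unmatched_seeds, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Proportion of network nodes annotated to a category
#'
#' Counts all network nodes — matched seeds and interactors alike.
#'
#' @param net An [expand_depth1plus()] result.
#' @param category Character vector of category member genes.
#' @return `|nodes intersect category| / |nodes|`.
#' @export
network_proportion <- function(net, category) {
  stopifnot(inherits(net, "expanded_network"))
  assert_that(length(net$nodes) > 0, "empty network")
  sum(net$nodes %in% category) / length(net$nodes)
}

#' Empirical null ensemble of random seed networks
#'
#' Draws `R` random seed sets of exactly `s` distinct genes uniformly
#' without replacement from the candidate pool (genes on the platform that
#' are present in the graph), expands each at depth 1 plus, and records the
#' per-category annotation proportion of every null network.
#'
#' @param graph A [ppi_graph()].
#' @param pool Character vector: candidate genes (must be graph nodes).
#' @param s Seed-set size (number of matched seed proteins to emulate).
#' @param R Number of replicates (>= 2; 1000 in production use).
#' @param catalog An [annotation_catalog()].
#' @param seed RNG seed.
#' @return Object of class `null_ensemble`: `proportions` (R x categories
#'   matrix), `s`, `R`, `pool_size`, `seed`.
#' @export
build_null <- function(graph, pool, s, R, catalog, seed = 1L) {
  stopifnot(inherits(graph, "igraph"), inherits(catalog, "annotation_catalog"))
  pool <- unique(pool)
  vnames <- igraph::V(graph)$name
  assert_that(all(pool %in% vnames), "pool genes must be graph nodes")
  assert_that(s <= length(pool), "pool (", length(pool),
              ") smaller than seed size s = ", s)
  assert_that(R >= 2, "need at least two null replicates")
  idx <- adjacency_index(graph)
  pool_ids <- match(pool, idx$nodes)
  cat_ids <- names(catalog$categories)
  member <- matrix(FALSE, nrow = length(idx$nodes), ncol = length(cat_ids),
                   dimnames = list(idx$nodes, cat_ids))
  for (j in seq_along(cat_ids)) {
    member[idx$nodes %in% catalog$categories[[j]], j] <- TRUE
  }
  props <- matrix(NA_real_, nrow = R, ncol = length(cat_ids),
                  dimnames = list(NULL, cat_ids))
  with_seed(child_seed(seed, "null"), {
    for (r in seq_len(R)) {
      seed_ids <- pool_ids[sample.int(length(pool_ids), s)]
      nodes <- expand_indices(idx, seed_ids)
      props[r, ] <- colSums(member[nodes, , drop = FALSE]) / length(nodes)
    }
  })
  structure(list(proportions = props, s = as.integer(s), R = as.integer(R),
                 pool_size = length(pool), seed = seed),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf(
    "null_ensemble: %d random networks from %d-gene pool, seed size %d, %d categories\n",
    x$R, x$pool_size, x$s, ncol(x$proportions)))
  invisible(x)
}

#' Test an observed annotation proportion against a random-network null
#'
#' One-sample Student comparison of the observed proportion against the
#' null ensemble's distribution:
#' `t = (observed - null mean) / (null SD * sqrt(1 + 1/R))` (the
#' prediction-interval form; the plain z-form `(observed - mean)/SD` is
#' available via `form = "z"`), with a one-sided upper-tail p on `R - 1`
#' degrees of freedom — enrichment only.  The empirical percentile
#' `(1 + #(null >= observed)) / (R + 1)` is reported alongside.  When the
#' null SD is 0 the result is flagged degenerate: p is 1 if the observation
#' does not exceed the null mean, else the empirical floor `1/(R + 1)`.
#'
#' @param observed Observed proportion (from [network_proportion()]).
#' @param ensemble A [build_null()] result.
#' @param category Category id (column of the ensemble).
#' @param form `"predictive"` (default) or `"z"`.
#' @return One-row data frame `category`, `observed`, `null_mean`,
#'   `null_sd`, `t`, `p`, `empirical_p`, `degenerate`.
#' @export
net_enrich_test <- function(observed, ensemble, category,
                            form = c("predictive", "z")) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  form <- match.arg(form)
  assert_that(category %in% colnames(ensemble$proportions),
              "unknown category: ", category)
  x <- ensemble$proportions[, category]
  assert_that(length(x) >= 2, "need >= 2 null replicates")
  R <- length(x)
  mu <- mean(x)
  sdev <- stats::sd(x)
  emp <- (1 + sum(x >= observed)) / (R + 1)
  if (sdev == 0) {
    p <- if (observed <= mu) 1 else 1 / (R + 1)
    return(data.frame(category = category, observed = observed,
                      null_mean = mu, null_sd = 0, t = NA_real_, p = p,
                      empirical_p = emp, degenerate = TRUE,
                      stringsAsFactors = FALSE))
  }
  scale <- if (form == "predictive") sdev * sqrt(1 + 1 / R) else sdev
  tval <- (observed - mu) / scale
  p <- stats::pt(tval, df = R - 1, lower.tail = FALSE)
  data.frame(category = category, observed = observed, null_mean = mu,
             null_sd = sdev, t = tval, p = p, empirical_p = emp,
             degenerate = FALSE, stringsAsFactors = FALSE)
}

#' Network-level pathway enrichment against a random-network null
#'
#' Convenience wrapper: expands the seeds, computes each category's observed
#' proportion, builds (or reuses) the null ensemble, runs
#' [net_enrich_test()] per category and applies Bonferroni correction
#' across the tested collection.
#'
#' @param graph A [ppi_graph()].
#' @param seeds Target gene symbols (unmatched seeds are reported but
#'   excluded from proportions).
#' @param pool Candidate pool for null seeds (platform genes present in the
#'   graph).
#' @param catalog An [annotation_catalog()].
#' @param R Null replicates (default 1000).
#' @param seed RNG seed.
#' @param ensemble Optional pre-built [build_null()] ensemble (must match
#'   `s =` number of matched seeds).
#' @param form Test form, see [net_enrich_test()].
#' @return Object of class `net_enrichment`: `network` (the
#'   [expand_depth1plus()] result), `results` (data frame with `adjusted_p`,
#'   sorted by adjusted then raw p), `ensemble`.
#' @export
net_enrich <- function(graph, seeds, pool, catalog, R = 1000, seed = 1L,
                       ensemble = NULL, form = c("predictive", "z")) {
  form <- match.arg(form)
  net <- expand_depth1plus(graph, seeds)
  assert_that(length(net$matched_seeds) > 0, "no seeds matched in the graph")
  if (is.null(ensemble)) {
    ensemble <- build_null(graph, pool, s = length(net$matched_seeds),
                           R = R, catalog = catalog, seed = seed)
  } else {
    assert_that(ensemble$s == length(net$matched_seeds),
                "ensemble seed size (", ensemble$s,
                ") does not match the ", length(net$matched_seeds),
                " matched seeds")
  }
  res <- do.call(rbind, lapply(names(catalog$categories), function(id) {
    net_enrich_test(network_proportion(net, catalog$categories[[id]]),
                    ensemble, id, form = form)
  }))
  res$adjusted_p <- pmin(1, res$p * nrow(res))
  res <- res[order(res$adjusted_p, res$p, res$category), , drop = FALSE]
  rownames(res) <- NULL
  structure(list(network = net, results = res, ensemble = ensemble),
            class = "net_enrichment")
}

#' @export
print.net_enrichment <- function(x, ...) {
  print(x$network)
  top <- utils::head(x$results, 5)
  cat("top categories by adjusted p:\n")
  print(top[c("category", "observed", "null_mean", "t", "p", "adjusted_p")])
  invisible(x)
}

#' Write an expanded network as node and edge tables
#'
#' Nodes carry a `role` column (`seed_up`/`seed_down`/`seed`/`interactor`);
#' unmatched seeds are listed with role `unmatched` and degree 0, keeping
#' them visible.  Optionally a `category` membership column is added.
#'
#' @param net An [expand_depth1plus()] result.
#' @param prefix Output path prefix; writes `<prefix>_nodes.tsv` and
#'   `<prefix>_edges.tsv`.
#' @param directions Optional named character vector gene -> "up"/"down".
#' @param category Optional category member vector to annotate.
#' @export
write_network <- function(net, prefix, directions = NULL, category = NULL) {
  stopifnot(inherits(net, "expanded_network"))
  role <- ifelse(net$nodes %in% net$matched_seeds, "seed", "interactor")
  if (!is.null(directions)) {
    is_seed <- role == "seed"
    dir <- directions[net$nodes]
    role[is_seed & !is.na(dir)] <- paste0("seed_", dir[is_seed & !is.na(dir)])
  }
  nodes <- data.frame(
    node = c(net$nodes, net$unmatched_seeds),
    role = c(role, rep("unmatched", length(net$unmatched_seeds))),
    component = c(net$components,
                  rep(NA_integer_, length(net$unmatched_seeds))),
    stringsAsFactors = FALSE)
  if (!is.null(category)) nodes$in_category <- nodes$node %in% category
  utils::write.table(nodes, paste0(prefix, "_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  write_edge_list(net$graph, paste0(prefix, "_edges.tsv"))
  invisible(prefix)
}
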