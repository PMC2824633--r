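# Small design used throughout: zero noise by default so planted structure is
# recovered exactly; override any field via ...
tiny_design <- function(seed = 1, ...) {
  defaults <- list(
    n_genes = 300, n_probes = 345, conditions = c("KD1", "KD2"),
    planted_down = list(KD1 = list(size = 40, effect = 0.25),
                        KD2 = list(size = 30, effect = 0.25)),
    planted_up = list(KD1 = list(size = 10, effect = 4),
                      KD2 = list(size = 5, effect = 4)),
    shared_down = 10, shared_up = 0, noise_sd = 0,
    graph_m = 2, graph_absent_frac = 0.4,
    planted_module = list(size = 25, n_dereg = 10, condition = "KD2",
                          p_within = 0.5),
    n_go = 20, n_kegg = 38, catalog_size_range = c(5, 60), seed = seed)
  do.call(synthetic_design, utils::modifyList(defaults, list(...)))
}

planted_genes <- function(truth, condition, direction = NULL) {
  keep <- truth$condition == condition
  if (!is.null(direction)) keep <- keep & truth$direction == direction
  sort(unique(truth$gene_id[keep]))
}

# Independent oracle: one-sided over-representation p by exhaustive
# enumeration of all C(N, n) draws, category taken as genes 1..m.
hyper_tail_oracle <- function(N, m, n, k) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= m) >= k)
}

# Independent oracle: depth-1-plus expansion by brute-force edge-list scan.
expand_oracle <- function(edges, seeds) {
  stopifnot(is.matrix(edges), ncol(edges) == 2)
  vertices <- unique(c(edges))
  matched <- intersect(seeds, vertices)
  nbrs <- unique(c(edges[edges[, 1] %in% matched, 2],
                   edges[edges[, 2] %in% matched, 1]))
  nodes <- union(matched, nbrs)
  keep <- edges[, 1] %in% nodes & edges[, 2] %in% nodes
  list(nodes = sort(nodes), edges = canonical_edges(edges[keep, , drop = FALSE]))
}

# Undirected edge set as a sorted canonical key vector.
canonical_edges <- function(edges) {
  if (!nrow(edges)) return(character())
  sort(unique(paste(pmin(edges[, 1], edges[, 2]),
                    pmax(edges[, 1], edges[, 2]), sep = "|")))
}

random_named_gnp <- function(n, p, seed) {
  g <- withr::with_seed(seed, igraph::sample_gnp(n, p))
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  g
}

# A fold-change table from a named list: list(probe = c(KD1 = r1, KD2 = r2))
fc_table <- function(ratios, conditions = NULL) {
  rows <- do.call(rbind, lapply(names(ratios), function(p) {
    r <- ratios[[p]]
    data.frame(probe_id = p, condition = names(r), ratio = unname(r),
               stringsAsFactors = FALSE)
  }))
  fold_change_table(rows)
}

simple_catalog <- function(categories, universe, collection = "go_like") {
  annotation_catalog(categories, universe, collection = collection)
}
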