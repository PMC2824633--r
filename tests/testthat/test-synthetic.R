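test_that("identical designs give bit-identical artifacts", {
  d1 <- tiny_design(seed = 11, noise_sd = 0.2)
  d2 <- tiny_design(seed = 11, noise_sd = 0.2)
  x1 <- generate_expression(d1)
  x2 <- generate_expression(d2)
  expect_identical(x1, x2)
  expect_identical(igraph::as_edgelist(generate_ppi(d1)),
                   igraph::as_edgelist(generate_ppi(d2)))
  expect_identical(generate_catalog(d1, "kegg_like")$categories,
                   generate_catalog(d2, "kegg_like")$categories)
  p1 <- generate_qpcr_plate(x1$truth, c("r1", "r2"), seed = 3, noise_sd = 0.1)
  p2 <- generate_qpcr_plate(x2$truth, c("r1", "r2"), seed = 3, noise_sd = 0.1)
  expect_identical(p1$ct, p2$ct)
  # and a different seed perturbs the expression table
  expect_false(identical(
    x1$table$ratio, generate_expression(tiny_design(seed = 12,
                                                    noise_sd = 0.2))$table$ratio))
})

test_that("artifact seed streams are independent", {
  # regenerating the graph does not depend on whether expression was drawn
  d <- tiny_design(seed = 5, noise_sd = 0.3)
  g1 <- generate_ppi(d)
  invisible(generate_expression(d))
  g2 <- generate_ppi(d)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
})

test_that("zero-noise ratios equal planted effects exactly", {
  d <- tiny_design(seed = 2)
  x <- generate_expression(d)
  tab <- x$table
  tab$gene <- x$probe_map$gene_id[match(tab$probe_id, x$probe_map$probe_id)]
  for (cn in d$conditions) {
    down <- planted_genes(x$truth, cn, "down")
    up <- planted_genes(x$truth, cn, "up")
    sub <- tab[tab$condition == cn, ]
    expect_true(all(sub$ratio[sub$gene %in% down] ==
                      d$planted_down[[cn]]$effect))
    expect_true(all(sub$ratio[sub$gene %in% up] == d$planted_up[[cn]]$effect))
    expect_true(all(sub$ratio[!sub$gene %in% c(down, up)] == 1))
  }
})

test_that("probe map is many-to-one and covers every gene", {
  d <- tiny_design(seed = 3)
  x <- generate_expression(d)
  expect_equal(nrow(x$probe_map), d$n_probes)
  expect_setequal(unique(x$probe_map$gene_id),
                  sprintf("g%03d", seq_len(d$n_genes)))
  expect_false(anyDuplicated(x$probe_map$probe_id) > 0)
})

test_that("planted sets are disjoint within condition and inside universe", {
  d <- tiny_design(seed = 7, shared_down = 5)
  x <- generate_expression(d)
  genes <- sprintf("g%03d", seq_len(d$n_genes))
  expect_true(all(x$truth$gene_id %in% genes))
  for (cn in d$conditions) {
    expect_length(intersect(planted_genes(x$truth, cn, "down"),
                            planted_genes(x$truth, cn, "up")), 0)
  }
  shared <- intersect(planted_genes(x$truth, "KD1", "down"),
                      planted_genes(x$truth, "KD2", "down"))
  expect_length(shared, 5)
})

test_that("expected recovery size under noise matches Monte-Carlo tail oracle", {
  # 47 genes planted down at 0.3 with log2 noise sd 0.1: the filter keeps a
  # planted gene iff 0.3 * 2^eps <= 0.5
  p_keep <- withr::with_seed(99, {
    mean(0.3 * 2^rnorm(1e6, 0, 0.1) <= 0.5)
  })
  expected <- 47 * p_keep
  recovered <- vapply(1:5, function(i) {
    d <- synthetic_design(
      n_genes = 1000, n_probes = 1000, conditions = "A",
      planted_down = list(A = list(size = 47, effect = 0.3)),
      planted_up = list(A = list(size = 0, effect = 4)),
      shared_down = 0, shared_up = 0, noise_sd = 0.1,
      planted_module = list(size = 10, n_dereg = 5, condition = "A",
                            p_within = 0.5),
      seed = 100 + i)
    x <- generate_expression(d)
    sets <- deregulated_sets(x$table, x$probe_map)
    sum(sets$conditions$A$genes$direction == "down")
  }, numeric(1))
  # miss probability is ~1e-13 here, so every run recovers all 47; the oracle
  # and the pipeline must agree within binomial noise either way
  expect_equal(mean(recovered), expected, tolerance = 0.01)
})

test_that("oversized planted sets are rejected with a parameter error", {
  expect_error(tiny_design(planted_down = list(
    KD1 = list(size = 400, effect = 0.25),
    KD2 = list(size = 30, effect = 0.25))), "exceeds the gene universe")
  expect_error(tiny_design(planted_down = list(
    KD1 = list(size = 200, effect = 0.25),
    KD2 = list(size = 150, effect = 0.25))), "exceed the universe")
  expect_error(tiny_design(planted_down = list(
    KD1 = list(size = 40, effect = 0.7),
    KD2 = list(size = 30, effect = 0.25))), "below 0.5")
  expect_error(tiny_design(planted_up = list(
    KD1 = list(size = 10, effect = 1.5),
    KD2 = list(size = 5, effect = 4))), "exceed 2.0")
})

test_that("generated graph is simple, named within the universe, half absent", {
  d <- tiny_design(seed = 13)
  g <- generate_ppi(d)
  expect_false(igraph::any_loop(g))
  expect_false(igraph::any_multiple(g))
  genes <- sprintf("g%03d", seq_len(d$n_genes))
  expect_true(all(igraph::V(g)$name %in% genes))
  expect_equal(igraph::vcount(g),
               round(d$n_genes * (1 - d$graph_absent_frac)))
})

test_that("edges-per-node 0 gives an edgeless graph; expansions return seeds", {
  d <- tiny_design(graph_m = 0, planted_module = list(
    size = 25, n_dereg = 10, condition = "KD2", p_within = 0))
  g <- generate_ppi(d)
  expect_equal(igraph::ecount(g), 0)
  seeds <- igraph::V(g)$name[1:5]
  net <- expand_depth1plus(g, seeds)
  expect_setequal(net$nodes, seeds)
  expect_length(net$interactors, 0)
})

test_that("module with within-probability 1 forms a clique", {
  d <- tiny_design(planted_module = list(size = 12, n_dereg = 5,
                                         condition = "KD2", p_within = 1))
  g <- generate_ppi(d)
  x <- generate_expression(d)
  module <- x$module_genes
  expect_length(module, 12)
  sub <- igraph::induced_subgraph(g, module)
  expect_equal(igraph::ecount(sub), 12 * 11 / 2)
})

test_that("preferential-attachment edge list is deduplicated and loop-free", {
  d <- tiny_design(n_genes = 500, n_probes = 500, graph_m = 2, seed = 21)
  el <- igraph::as_edgelist(generate_ppi(d))
  expect_true(all(el[, 1] != el[, 2]))
  expect_false(anyDuplicated(canonical_edges(el)) > 0)
})

test_that("catalogs have the configured collection sizes and the module", {
  d <- tiny_design(seed = 4)
  kegg <- generate_catalog(d, "kegg_like")
  go <- generate_catalog(d, "go_like")
  expect_length(kegg$categories, 38)
  expect_length(go$categories, 20)
  expect_identical(kegg$collection, "kegg_like")
  module <- generate_expression(d)$module_genes
  expect_setequal(kegg$categories$path_module, module)
  expect_setequal(go$categories$go_module, module)
})

test_that("catalog constructor rejects bad input", {
  u <- paste0("g", 1:10)
  expect_error(annotation_catalog(list(a = "g1", a = "g2"), u), "duplicate")
  expect_error(annotation_catalog(list(a = character()), u), "size 0")
  expect_error(annotation_catalog(list(a = "zz"), u), "outside the universe")
})

test_that("disjoint categories covering the universe have row sums 1", {
  u <- paste0("g", 1:30)
  cats <- split(u, rep(1:3, each = 10))
  names(cats) <- paste0("c", 1:3)
  cat <- annotation_catalog(cats, u)
  membership <- vapply(cat$categories, function(m) u %in% m, logical(30))
  expect_true(all(rowSums(membership) == 1))
})

test_that("zero-noise qPCR plates invert to planted ratios", {
  truth <- data.frame(gene_id = c("tA", "tB", "tC"),
                      condition = "KD",
                      effect = c(0.5, 1.0, 0.25),
                      direction = c("down", "none", "down"),
                      stringsAsFactors = FALSE)
  plate <- generate_qpcr_plate(truth, references = c("r1", "r2", "r3", "r4"),
                               seed = 8)
  fc <- qpcr_fold_changes(plate)
  expect_equal(fc$fold_change[match("tA", fc$gene)], 0.5)
  expect_equal(fc$ddct[match("tB", fc$gene)], 0)
  expect_equal(fc$fold_change[match("tC", fc$gene)], 0.25)
  # the four references have unequal base CTs by construction
  refs_ct <- plate$ct[plate$gene %in% c("r1", "r2", "r3", "r4") &
                        plate$sample == "control" & plate$replicate == 1]
  expect_gt(length(unique(round(refs_ct, 3))), 1)
})
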