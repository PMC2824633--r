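test_that("2-fold filter selects inclusively on both boundaries", {
  tab <- fc_table(list(
    usp24_like = c(KD1 = 0.1626),  # strong down, as in a real knockdown table
    boundary_dn = c(KD1 = 0.5),
    boundary_up = c(KD1 = 2.0),
    unchanged = c(KD1 = 1.0),
    near_dn = c(KD1 = 0.5001),
    near_up = c(KD1 = 1.9999)))
  hits <- filter_probes(tab, "KD1", threshold = 2)
  expect_setequal(hits$probe_id, c("usp24_like", "boundary_dn", "boundary_up"))
  expect_equal(hits$direction[hits$probe_id == "usp24_like"], "down")
  expect_equal(hits$direction[hits$probe_id == "boundary_dn"], "down")
  expect_equal(hits$direction[hits$probe_id == "boundary_up"], "up")
})

test_that("filter validates condition and threshold", {
  tab <- fc_table(list(a = c(KD1 = 0.2)))
  expect_error(filter_probes(tab, "KD9"), "unknown condition")
  expect_error(filter_probes(tab, "KD1", threshold = 1), "exceed 1")
})

test_that("fold-change table rejects bad ratios and duplicates", {
  expect_error(fold_change_table(data.frame(
    probe_id = "a", condition = "c", ratio = -1)), "positive")
  expect_error(fold_change_table(data.frame(
    probe_id = c("a", "a"), condition = c("c", "c"), ratio = c(1, 2))),
    "one entry per")
})

test_that("filter is monotone in threshold and idempotent", {
  tab <- withr::with_seed(31, fold_change_table(data.frame(
    probe_id = sprintf("p%03d", 1:200), condition = "KD1",
    ratio = 2^rnorm(200, 0, 1.2))))
  prev <- filter_probes(tab, "KD1", 2)$probe_id
  for (thr in c(2.5, 3, 4, 8)) {
    cur <- filter_probes(tab, "KD1", thr)$probe_id
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  # re-filtering the surviving probes at the same threshold changes nothing
  hits <- filter_probes(tab, "KD1", 2)
  again <- filter_probes(
    fold_change_table(data.frame(probe_id = hits$probe_id, condition = "KD1",
                                 ratio = hits$ratio)), "KD1", 2)
  expect_setequal(again$probe_id, hits$probe_id)
})

test_that("collapse takes the most extreme passing probe per gene", {
  probes <- filter_probes(fc_table(list(
    p1 = c(K = 0.3), p2 = c(K = 0.45),   # same gene, both down
    p3 = c(K = 2.5), p4 = c(K = 3.5),    # same gene, both up
    p5 = c(K = 0.4))), "K")
  map <- data.frame(probe_id = paste0("p", 1:5),
                    gene_id = c("gDown", "gDown", "gUp", "gUp", "gSolo"))
  res <- collapse_to_genes(probes, map)
  expect_equal(res$genes$fold_change[res$genes$gene_id == "gDown"], 0.3)
  expect_equal(res$genes$fold_change[res$genes$gene_id == "gUp"], 3.5)
  expect_equal(res$genes$direction[res$genes$gene_id == "gSolo"], "down")
  expect_length(res$unmapped, 0)
  expect_length(res$discordant, 0)
})

test_that("discordant genes are excluded and reported; unmapped reported", {
  probes <- filter_probes(fc_table(list(
    p1 = c(K = 0.4), p2 = c(K = 2.5),   # one gene, both directions
    p3 = c(K = 0.2))), "K")
  map <- data.frame(probe_id = c("p1", "p2"), gene_id = c("gX", "gX"))
  res <- collapse_to_genes(probes, map)
  expect_identical(res$discordant, "gX")
  expect_identical(res$unmapped, "p3")
  expect_equal(nrow(res$genes), 0)
})

test_that("collapse can only shrink the count (many-to-one pigeonhole)", {
  d <- tiny_design(seed = 17, noise_sd = 0.4)
  x <- generate_expression(d)
  probes <- filter_probes(x$table, "KD1")
  res <- collapse_to_genes(probes, x$probe_map)
  expect_lte(nrow(res$genes) + length(res$discordant), nrow(probes))
})

test_that("partition handles shared-both-conditions genes with both ratios", {
  a <- data.frame(gene_id = c("SLC18A2_like", "onlyA"),
                  direction = "down", fold_change = c(0.105, 0.3))
  b <- data.frame(gene_id = c("SLC18A2_like", "onlyB"),
                  direction = "down", fold_change = c(0.4495, 0.2))
  part <- partition_sets(a, b, labels = c("D1", "D3"))
  expect_equal(part$common$gene_id, "SLC18A2_like")
  expect_equal(part$common$fold_change_a, 0.105)
  expect_equal(part$common$fold_change_b, 0.4495)
  expect_false(part$common$direction_conflict)
  expect_equal(part$unique_a$gene_id, "onlyA")
  expect_equal(part$unique_b$gene_id, "onlyB")
})

test_that("partition of an empty set leaves everything unique to the other", {
  empty <- data.frame(gene_id = character(), direction = character(),
                      fold_change = numeric())
  b <- data.frame(gene_id = c("x", "y"), direction = "down",
                  fold_change = c(0.2, 0.3))
  part <- partition_sets(empty, b)
  expect_equal(nrow(part$unique_a), 0)
  expect_equal(nrow(part$common), 0)
  expect_setequal(part$unique_b$gene_id, c("x", "y"))
})

test_that("partition identity |unique| + |common| = |set| on random sets", {
  withr::with_seed(55, {
    for (i in 1:20) {
      pool <- sprintf("g%04d", 1:400)
      a <- data.frame(gene_id = sample(pool, 165), direction = "down",
                      fold_change = runif(165, 0.1, 0.5))
      b <- data.frame(gene_id = sample(pool, 106), direction = "down",
                      fold_change = runif(106, 0.1, 0.5))
      part <- partition_sets(a, b)
      expect_equal(nrow(part$unique_a) + nrow(part$common), 165)
      expect_equal(nrow(part$unique_b) + nrow(part$common), 106)
      expect_length(intersect(part$unique_a$gene_id, part$common$gene_id), 0)
      expect_length(intersect(part$unique_b$gene_id, part$common$gene_id), 0)
    }
  })
})

test_that("filter+collapse+partition equals brute-force enumeration", {
  # instances of <= 50 probes, checked against direct per-gene enumeration
  brute <- function(tab, map, cond, thr = 2) {
    calls <- list()
    for (g in unique(map$gene_id)) {
      probes <- map$probe_id[map$gene_id == g]
      r <- tab$ratio[tab$condition == cond & tab$probe_id %in% probes]
      dn <- r[r <= 1 / thr]; up <- r[r >= thr]
      if (length(dn) && length(up)) next  # discordant
      if (length(dn)) calls[[g]] <- c(dir = "down", fc = min(dn))
      if (length(up)) calls[[g]] <- c(dir = "up", fc = max(up))
    }
    calls
  }
  withr::with_seed(77, {
    for (i in 1:10) {
      n <- sample(10:50, 1)
      map <- data.frame(probe_id = sprintf("p%02d", 1:n),
                        gene_id = sprintf("g%02d", sample(ceiling(n / 2), n,
                                                          replace = TRUE)))
      tab <- fold_change_table(data.frame(
        probe_id = rep(map$probe_id, 2),
        condition = rep(c("A", "B"), each = n),
        ratio = 2^rnorm(2 * n, 0, 1.5)))
      for (cond in c("A", "B")) {
        expected <- brute(tab, map, cond)
        got <- collapse_to_genes(filter_probes(tab, cond), map)
        expect_setequal(got$genes$gene_id, names(expected))
        for (g in got$genes$gene_id) {
          expect_equal(got$genes$fold_change[got$genes$gene_id == g],
                       as.numeric(expected[[g]][["fc"]]))
          expect_equal(got$genes$direction[got$genes$gene_id == g],
                       unname(expected[[g]][["dir"]]))
        }
      }
      ba <- brute(tab, map, "A"); bb <- brute(tab, map, "B")
      part <- partition_sets(
        collapse_to_genes(filter_probes(tab, "A"), map),
        collapse_to_genes(filter_probes(tab, "B"), map))
      expect_setequal(part$common$gene_id,
                      intersect(names(ba), names(bb)))
    }
  })
})

test_that("zero-noise synthetic data is recovered exactly", {
  for (s in c(1, 9)) {
    d <- tiny_design(seed = s)
    x <- generate_expression(d)
    sets <- deregulated_sets(x$table, x$probe_map)
    for (cn in d$conditions) {
      g <- sets$conditions[[cn]]$genes
      expect_identical(sort(g$gene_id[g$direction == "down"]),
                       planted_genes(x$truth, cn, "down"))
      expect_identical(sort(g$gene_id[g$direction == "up"]),
                       planted_genes(x$truth, cn, "up"))
      expect_length(sets$conditions[[cn]]$discordant, 0)
    }
  }
})

test_that("partition table writes three ordered blocks", {
  d <- tiny_design(seed = 1)
  x <- generate_expression(d)
  sets <- deregulated_sets(x$table, x$probe_map)
  part <- partition_sets(sets$conditions$KD1, sets$conditions$KD2,
                         labels = c("KD1", "KD2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_partition_table(part, path)
  out <- utils::read.delim(path)
  expect_setequal(unique(out$block), c("unique_KD1", "unique_KD2", "common"))
  common <- out[out$block == "common", ]
  expect_false(is.unsorted(common$fold_change_KD1))
  expect_equal(sum(out$block == "common"), nrow(part$common))
})
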