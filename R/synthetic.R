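#' Describe a synthetic two-knockdown experiment with planted structure
#'
#' The design is the single source of truth for every synthetic artifact:
#' the expression table, the probe-to-gene map, the interactome, the
#' annotation catalogs and the qPCR plate are all derived from it through
#' deterministic per-artifact seed streams, so regenerating one artifact
#' never perturbs the others.
#'
#' Defaults emulate a two-knockdown plus non-specific-control siRNA design
#' profiled on a large expression array: two conditions whose deregulated
#' sets overlap in a shared-down core, many-to-one probe-to-gene mapping with
#' mean multiplicity ~1.15, a scale-free interactome from which about half
#' the genes are absent (matching the typical fraction of targets that find
#' no interactome match), and one dense "pathway module" wired into the graph
#' whose members are partly deregulated — the ground truth that downstream
#' enrichment and network-null stages must recover.
#'
#' @param n_genes Number of genes in the background universe.
#' @param n_probes Number of probe identifiers (>= `n_genes`; the map is
#'   many-to-one, extra probes are assigned to random genes).
#' @param conditions Character vector of condition labels (each is a
#'   knockdown compared against the implicit non-specific control).
#' @param planted_down,planted_up Per-condition lists `list(size=, effect=)`;
#'   `effect` is a linear-scale treated/control ratio (< 0.5 for down,
#'   > 2 for up, so planting is detectable by the 2-fold filter in
#'   expectation).
#' @param shared_down,shared_up Number of planted genes shared by *all*
#'   conditions (the "common" core; counts toward each condition's `size`).
#' @param noise_sd Standard deviation of additive log2 noise (multiplicative
#'   on linear ratios), in log2 units.
#' @param graph_m Preferential-attachment edges per node for the interactome
#'   generator (0 gives an edgeless graph).
#' @param graph_absent_frac Fraction of the gene universe deliberately absent
#'   from the interactome.
#' @param planted_module List `list(size=, n_dereg=, condition=, p_within=)`:
#'   a category of `size` genes wired pairwise with probability `p_within`,
#'   of which `n_dereg` are taken from `condition`'s planted-down set.
#' @param n_go,n_kegg Number of categories in the GO-like and KEGG-like
#'   catalogs (the fixed pathway collection defaults to 38).
#' @param catalog_size_range Range of category sizes (genes) for non-module
#'   categories.
#' @param seed Root RNG seed; identical designs give bit-identical artifacts.
#' @return An object of class `synthetic_design`.
#' @export
#' @examples
#' d <- synthetic_design(n_genes = 200, n_probes = 230, seed = 1)
#' x <- generate_expression(d)
#' head(x$table)
synthetic_design <- function(n_genes = 4000,
                             n_probes = round(n_genes * 1.15),
                             conditions = c("KD1", "KD2"),
                             planted_down = list(
                               KD1 = list(size = 140, effect = 0.25),
                               KD2 = list(size = 90, effect = 0.25)),
                             planted_up = list(
                               KD1 = list(size = 25, effect = 4),
                               KD2 = list(size = 16, effect = 4)),
                             shared_down = 34,
                             shared_up = 0,
                             noise_sd = 0.25,
                             graph_m = 3,
                             graph_absent_frac = 0.5,
                             planted_module = list(size = 60, n_dereg = 20,
                                                   condition = "KD2",
                                                   p_within = 0.1),
                             n_go = 60,
                             n_kegg = 38,
                             catalog_size_range = c(10, 150),
                             seed = 1L) {
  assert_that(n_genes >= 1 && n_probes >= n_genes,
              "need n_probes >= n_genes >= 1")
  assert_that(length(conditions) >= 1 && !anyDuplicated(conditions),
              "conditions must be distinct labels")
  norm_planted <- function(pl, what, hi) {
    pl <- pl[intersect(names(pl), conditions)]
    for (cn in conditions) {
      if (is.null(pl[[cn]])) pl[[cn]] <- list(size = 0L, effect = if (hi) 4 else 0.25)
      p <- pl[[cn]]
      assert_that(p$size >= 0 && p$size <= n_genes,
                  "planted ", what, " set size for ", cn,
                  " exceeds the gene universe")
      assert_that(p$effect > 0, "effect ratios must be positive")
      if (p$size > 0) {
        if (hi) assert_that(p$effect > 2, "up effects must exceed 2.0")
        else    assert_that(p$effect < 0.5, "down effects must be below 0.5")
      }
      pl[[cn]] <- p
    }
    pl
  }
  planted_down <- norm_planted(planted_down, "down", hi = FALSE)
  planted_up <- norm_planted(planted_up, "up", hi = TRUE)
  min_down <- min(vapply(planted_down, function(p) p$size, 0))
  min_up <- min(vapply(planted_up, function(p) p$size, 0))
  assert_that(shared_down <= min_down && shared_up <= min_up,
              "shared planted counts cannot exceed the smallest condition set")
  total <- shared_down + shared_up +
    sum(vapply(planted_down, function(p) p$size, 0) - shared_down) +
    sum(vapply(planted_up, function(p) p$size, 0) - shared_up)
  assert_that(total <= n_genes,
              "planted sets (", total, " genes) exceed the universe (",
              n_genes, ")")
  pm <- planted_module
  assert_that(is.list(pm) && all(c("size", "n_dereg", "condition",
                                   "p_within") %in% names(pm)),
              "planted_module needs size, n_dereg, condition, p_within")
  assert_that(pm$condition %in% conditions, "planted_module condition unknown")
  assert_that(pm$n_dereg <= pm$size, "planted_module n_dereg exceeds its size")
  assert_that(pm$n_dereg <= planted_down[[pm$condition]]$size,
              "planted_module n_dereg exceeds the condition's down set")
  assert_that(pm$size - pm$n_dereg <= n_genes - total,
              "planted_module does not fit in the unplanted remainder")
  assert_that(pm$p_within >= 0 && pm$p_within <= 1, "p_within must be in [0,1]")
  assert_that(noise_sd >= 0 && graph_m >= 0 &&
                graph_absent_frac >= 0 && graph_absent_frac < 1,
              "invalid noise/graph parameters")
  assert_that(n_kegg >= 1 && n_go >= 1, "catalogs need at least one category")

  structure(list(
    n_genes = as.integer(n_genes), n_probes = as.integer(n_probes),
    conditions = conditions,
    planted_down = planted_down, planted_up = planted_up,
    shared_down = as.integer(shared_down), shared_up = as.integer(shared_up),
    noise_sd = noise_sd, graph_m = graph_m,
    graph_absent_frac = graph_absent_frac,
    planted_module = pm, n_go = as.integer(n_go), n_kegg = as.integer(n_kegg),
    catalog_size_range = catalog_size_range,
    seed = as.integer(seed)
  ), class = "synthetic_design")
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat("synthetic_design:", x$n_genes, "genes /", x$n_probes, "probes;",
      "conditions:", paste(x$conditions, collapse = ", "), "\n")
  for (cn in x$conditions) {
    cat(sprintf("  %s: %d down @%.3g, %d up @%.3g\n", cn,
                x$planted_down[[cn]]$size, x$planted_down[[cn]]$effect,
                x$planted_up[[cn]]$size, x$planted_up[[cn]]$effect))
  }
  cat(sprintf("  shared: %d down, %d up; noise_sd(log2)=%.3g; seed=%d\n",
              x$shared_down, x$shared_up, x$noise_sd, x$seed))
  invisible(x)
}

design_genes <- function(design) {
  sprintf("g%0*d", nchar(design$n_genes), seq_len(design$n_genes))
}

# Deterministic allocation of planted gene sets and the module, shared by all
# artifact generators.  Uses its own seed stream so expression noise, graph
# wiring etc. cannot shift which genes are planted.
planted_assignment <- function(design) {
  genes <- design_genes(design)
  with_seed(child_seed(design$seed, "misc"), {
    perm <- sample(genes)
    take <- function(k) {
      if (k == 0) return(character())
      out <- perm[seq_len(k)]
      perm <<- perm[-seq_len(k)]
      out
    }
    shared_dn <- take(design$shared_down)
    shared_up <- take(design$shared_up)
    down <- lapply(design$conditions, function(cn) {
      c(shared_dn, take(design$planted_down[[cn]]$size - design$shared_down))
    })
    up <- lapply(design$conditions, function(cn) {
      c(shared_up, take(design$planted_up[[cn]]$size - design$shared_up))
    })
    names(down) <- names(up) <- design$conditions
    pm <- design$planted_module
    # module's deregulated members come from the tail of the condition's down
    # set: the condition-unique portion when n_dereg fits there, so the module
    # signal is condition-specific rather than shared
    dn <- down[[pm$condition]]
    module <- c(dn[seq.int(length(dn) - pm$n_dereg + 1, length.out = pm$n_dereg)],
                take(pm$size - pm$n_dereg))
    truth <- do.call(rbind, lapply(design$conditions, function(cn) {
      rbind(
        if (length(down[[cn]]))
          data.frame(gene_id = down[[cn]], condition = cn,
                     effect = design$planted_down[[cn]]$effect,
                     direction = "down", stringsAsFactors = FALSE),
        if (length(up[[cn]]))
          data.frame(gene_id = up[[cn]], condition = cn,
                     effect = design$planted_up[[cn]]$effect,
                     direction = "up", stringsAsFactors = FALSE)
      )
    }))
    list(down = down, up = up, module = module, truth = truth)
  })
}

#' Generate a fold-change table with planted deregulation
#'
#' Each probe's linear-scale ratio is the planted effect of its gene in that
#' condition (1.0 if unplanted) times `2^eps` with
#' `eps ~ Normal(0, noise_sd)` — multiplicative noise on the ratio scale,
#' additive on log2.
#'
#' @param design A [synthetic_design()].
#' @return A list with `table` (a [fold_change_table()]), `probe_map`
#'   (`probe_id`, `gene_id`), `truth` (planted `gene_id`, `condition`,
#'   `effect`, `direction`) and `module_genes` (the planted dense module).
#' @export
generate_expression <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  genes <- design_genes(design)
  asg <- planted_assignment(design)

  probe_map <- with_seed(child_seed(design$seed, "probe_map"), {
    extra <- design$n_probes - design$n_genes
    gene_of <- c(genes, sample(genes, extra, replace = TRUE))
    gene_of <- sample(gene_of)  # decouple probe order from gene order
    data.frame(
      probe_id = sprintf("p%0*d", nchar(design$n_probes),
                         seq_len(design$n_probes)),
      gene_id = gene_of, stringsAsFactors = FALSE)
  })

  effect_of <- function(cn) {
    e <- stats::setNames(rep(1, design$n_genes), genes)
    e[asg$down[[cn]]] <- design$planted_down[[cn]]$effect
    e[asg$up[[cn]]] <- design$planted_up[[cn]]$effect
    e
  }
  table <- with_seed(child_seed(design$seed, "expression"), {
    do.call(rbind, lapply(design$conditions, function(cn) {
      eff <- effect_of(cn)[probe_map$gene_id]
      eps <- stats::rnorm(design$n_probes, 0, design$noise_sd)
      data.frame(probe_id = probe_map$probe_id, condition = cn,
                 ratio = unname(eff) * 2^eps, stringsAsFactors = FALSE)
    }))
  })
  list(table = fold_change_table(table), probe_map = probe_map,
       truth = asg$truth, module_genes = asg$module)
}

#' Generate a synthetic interactome with a planted dense module
#'
#' An undirected simple scale-free graph (preferential attachment,
#' `graph_m` edges per node) over a subset of the gene universe; a fraction
#' `graph_absent_frac` of genes is deliberately absent, emulating targets
#' with no interactome match.  Genes of the planted module are always
#' present and additionally wired pairwise with probability `p_within`.
#'
#' @param design A [synthetic_design()].
#' @return An `igraph` object with gene symbols as vertex names.
#' @export
generate_ppi <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  genes <- design_genes(design)
  module <- planted_assignment(design)$module
  with_seed(child_seed(design$seed, "ppi"), {
    n_present <- max(length(module),
                     round(design$n_genes * (1 - design$graph_absent_frac)))
    others <- setdiff(genes, module)
    present <- c(module, sample(others, n_present - length(module)))
    present <- sample(present)  # PA vertex age must not correlate with planting
    if (design$graph_m >= 1) {
      g <- igraph::sample_pa(n_present, m = design$graph_m, directed = FALSE)
    } else {
      g <- igraph::make_empty_graph(n_present, directed = FALSE)
    }
    igraph::V(g)$name <- present
    pm <- design$planted_module
    if (length(module) >= 2 && pm$p_within > 0) {
      pairs <- utils::combn(module, 2)
      keep <- stats::runif(ncol(pairs)) <= pm$p_within
      if (any(keep)) {
        g <- igraph::add_edges(g, as.vector(pairs[, keep, drop = FALSE]))
      }
    }
    igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  })
}

#' Generate an annotation catalog with the planted module as one category
#'
#' The KEGG-like collection has exactly `n_kegg` (default 38) categories,
#' emulating a fixed collection of cancer- and signaling-related pathways;
#' the GO-like collection has `n_go`.  In both, one category (`*_module`)
#' is exactly the planted module's gene set; the remaining categories are
#' uniform draws from the universe with sizes in `catalog_size_range`.
#'
#' @param design A [synthetic_design()].
#' @param collection `"kegg_like"` (fixed pathway collection) or `"go_like"`.
#' @return An [annotation_catalog()].
#' @export
generate_catalog <- function(design,
                             collection = c("kegg_like", "go_like")) {
  stopifnot(inherits(design, "synthetic_design"))
  collection <- match.arg(collection)
  genes <- design_genes(design)
  module <- planted_assignment(design)$module
  n_cat <- if (collection == "kegg_like") design$n_kegg else design$n_go
  prefix <- if (collection == "kegg_like") "path" else "go"
  offset <- if (collection == "kegg_like") 1L else 2L
  with_seed(child_seed(design$seed, "catalog") + offset, {
    lo <- min(design$catalog_size_range)
    hi <- min(max(design$catalog_size_range), design$n_genes)
    sizes <- sample(seq(lo, hi), n_cat - 1L, replace = TRUE)
    cats <- lapply(sizes, function(s) sample(genes, s))
    names(cats) <- sprintf("%s%02d", prefix, seq_len(n_cat - 1L) + 1L)
    cats <- c(stats::setNames(list(module), paste0(prefix, "_module")), cats)
    annotation_catalog(cats, genes, collection = collection)
  })
}

#' Generate a qPCR plate consistent with planted expression truth
#'
#' Builds CT values such that the comparative-CT pipeline (multi-reference
#' geometric-mean normalization, then `2^-ddCT`) recovers the planted linear
#' ratios exactly at zero noise: each reference gene has a sample-invariant
#' base CT, each target gene a base CT in the control sample, and the
#' knockdown-sample CT is shifted by `-log2(effect)`.
#'
#' @param truth Truth table from [generate_expression()] (`gene_id`,
#'   `condition`, `effect`), or any data frame shaped like it.
#' @param references Character vector of reference gene names (>= 1).
#' @param seed RNG seed.
#' @param genes Target genes to plate (default: all genes in `truth`).
#' @param replicates Technical replicates per well.
#' @param noise_sd SD of Normal CT noise in cycles (0 = noiseless).
#' @param control Name of the control sample.
#' @return A [ct_table()] covering samples `control` plus one per condition.
#' @export
generate_qpcr_plate <- function(truth, references, seed = 1L, genes = NULL,
                                replicates = 3L, noise_sd = 0,
                                control = "control") {
  assert_that(length(references) >= 1, "need at least one reference gene")
  assert_that(all(c("gene_id", "condition", "effect") %in% names(truth)),
              "truth needs gene_id, condition, effect columns")
  if (is.null(genes)) genes <- unique(truth$gene_id)
  assert_that(!any(genes %in% references),
              "target genes and reference genes must not overlap")
  samples <- c(control, unique(truth$condition))
  with_seed(child_seed(seed, "qpcr"), {
    ref_base <- stats::setNames(
      seq(16, 16 + 2 * (length(references) - 1), by = 2) +
        stats::runif(length(references), -0.5, 0.5),
      references)
    gene_base <- stats::setNames(
      stats::runif(length(genes), 22, 28), genes)
    effect_lookup <- function(g, s) {
      if (s == control) return(1)
      hit <- truth$effect[truth$gene_id == g & truth$condition == s]
      if (length(hit)) hit[[1]] else 1
    }
    rows <- expand.grid(sample = samples, gene = c(genes, references),
                        replicate = seq_len(replicates),
                        stringsAsFactors = FALSE)
    rows$ct <- mapply(function(s, g) {
      base <- if (g %in% references) ref_base[[g]]
              else gene_base[[g]] - log2(effect_lookup(g, s))
      base + stats::rnorm(1, 0, noise_sd)
    }, rows$sample, rows$gene)
    ct_table(rows, references = references, control = control)
  })
}
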