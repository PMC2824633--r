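RUN_CONFIG_KEYS <- c("inputs", "threshold", "fdr_randomizations",
                     "null_replicates", "alpha", "seed", "outdir",
                     "test_form", "labels")
RUN_INPUT_KEYS <- c("expression", "probe_map", "graph", "go_catalog",
                    "kegg_catalog", "universe", "pool", "ct_table",
                    "references", "control")

#' Build and validate a pipeline run configuration
#'
#' @param inputs Named list of input paths: `expression`, `probe_map`,
#'   `graph`, `go_catalog` (GMT), `kegg_catalog` (GMT), `universe`
#'   (gene list), optionally `pool` (gene list; defaults to
#'   universe-in-graph), `ct_table` + `references` + `control` for the qPCR
#'   comparison stage.
#' @param threshold Fold-change threshold (> 1, default 2).
#' @param fdr_randomizations Randomizations for the GO-like FDR
#'   (default 1000).
#' @param null_replicates Random networks for the network null
#'   (default 1000).
#' @param alpha Significance threshold recorded in outputs (default 0.05).
#' @param seed Root RNG seed; all stochastic stages derive their streams
#'   from it.
#' @param outdir Output directory (created if missing).
#' @param test_form `"predictive"` or `"z"` for the network-null test.
#' @param labels Optional length-2 condition labels for the partition
#'   (default: first two conditions of the expression table).
#' @return Validated config of class `run_config`.
#' @export
run_config <- function(inputs, threshold = 2, fdr_randomizations = 1000,
                       null_replicates = 1000, alpha = 0.05, seed = 1L,
                       outdir = "perturbnet_out",
                       test_form = c("predictive", "z"), labels = NULL) {
  test_form <- match.arg(test_form)
  unknown <- setdiff(names(inputs), RUN_INPUT_KEYS)
  assert_that(length(unknown) == 0,
              "unknown input keys: ", paste(unknown, collapse = ", "))
  required <- c("expression", "probe_map", "graph", "go_catalog",
                "kegg_catalog", "universe")
  missing <- setdiff(required, names(inputs))
  assert_that(length(missing) == 0,
              "missing inputs: ", paste(missing, collapse = ", "))
  for (key in intersect(names(inputs), setdiff(RUN_INPUT_KEYS,
                                               c("references", "control")))) {
    assert_that(file.exists(inputs[[key]]),
                "input '", key, "' not found: ", inputs[[key]])
  }
  assert_that(threshold > 1, "threshold must exceed 1")
  assert_that(fdr_randomizations >= 1 && null_replicates >= 2,
              "need fdr_randomizations >= 1 and null_replicates >= 2")
  if (!is.null(inputs$references)) inputs$references <- unlist(inputs$references)
  structure(list(inputs = inputs, threshold = threshold,
                 fdr_randomizations = as.integer(fdr_randomizations),
                 null_replicates = as.integer(null_replicates),
                 alpha = alpha, seed = as.integer(seed), outdir = outdir,
                 test_form = test_form, labels = labels),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected before any computation.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  assert_that(file.exists(path), "config not found: ", path)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), RUN_CONFIG_KEYS)
  assert_that(length(unknown) == 0,
              "unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

stage <- function(name, quiet, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop(errorCondition(
      paste0("stage '", name, "' failed: ", conditionMessage(e)),
      class = c(class(e)[1], "perturbnet_stage_error", "error")))
  })
  if (!quiet) {
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
  }
  res
}

#' Run the full analysis pipeline
#'
#' Stage order: deregulated-gene calling and unique/common partition, then
#' per gene set (unique-A, unique-B, common) GO-like enrichment with
#' randomization FDR and fixed-collection pathway testing, then depth-1-plus
#' network expansion with the random-network null; optionally comparative-CT
#' quantification and array/qPCR comparison.  All outputs are TSV files
#' under `config$outdir`, plus a JSON manifest recording the package
#' version, seeds, input checksums and per-stage row counts.  Re-running
#' with the same config reproduces identical outputs.
#'
#' @param config A [run_config()] or path to a YAML config.
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outdir, ...)
  manifest <- list(
    package = "perturbnet",
    version = as.character(utils::packageVersion("perturbnet")),
    seed = config$seed,
    threshold = config$threshold,
    fdr_randomizations = config$fdr_randomizations,
    null_replicates = config$null_replicates,
    test_form = config$test_form,
    input_md5 = as.list(tools::md5sum(unlist(
      config$inputs[vapply(config$inputs, function(x)
        is.character(x) && length(x) == 1 && file.exists(x), logical(1))]))),
    counts = list())

  degs <- stage("degs", quiet, {
    table <- read_fold_changes(config$inputs$expression)
    probe_map <- read_probe_map(config$inputs$probe_map)
    sets <- deregulated_sets(table, probe_map, config$threshold)
    labels <- config$labels %||% names(sets$conditions)[1:2]
    assert_that(length(names(sets$conditions)) >= 2,
                "partition needs at least two conditions")
    part <- partition_sets(sets$conditions[[labels[1]]],
                           sets$conditions[[labels[2]]], labels = labels)
    write_partition_table(part, out("partition.tsv"))
    list(sets = sets, part = part, labels = labels)
  })
  part <- degs$part
  gene_sets <- list(
    unique_a = part$unique_a$gene_id,
    unique_b = part$unique_b$gene_id,
    common = part$common$gene_id)
  names(gene_sets)[1:2] <- paste0("unique_", degs$labels)
  manifest$counts$deregulated <- lapply(degs$sets$conditions,
                                        function(x) nrow(x$genes))
  manifest$counts$partition <- lapply(gene_sets, length)

  universe <- read_gene_list(config$inputs$universe)
  go_cat <- read_gmt(config$inputs$go_catalog, universe, "go_like")
  kegg_cat <- read_gmt(config$inputs$kegg_catalog, universe, "kegg_like")

  stage("enrichment", quiet, {
    for (nm in names(gene_sets)) {
      genes <- gene_sets[[nm]]
      if (!length(genes)) next
      write_gene_list(genes, out(paste0("genes_", nm, ".txt")))
      go <- randomization_fdr(genes, go_cat, R = config$fdr_randomizations,
                              seed = child_seed(config$seed, "fdr"))
      write_enrichment(go, out(paste0("enrich_go_", nm, ".tsv")))
      kegg <- kegg_collection_test(genes, kegg_cat)
      write_enrichment(kegg, out(paste0("enrich_kegg_", nm, ".tsv")))
      manifest$counts$enrichment[[nm]] <-
        list(go_categories = nrow(go), kegg_categories = nrow(kegg))
    }
  })

  stage("ppinet", quiet, {
    graph <- ppi_graph(read_edge_list(config$inputs$graph))
    pool <- if (!is.null(config$inputs$pool)) {
      read_gene_list(config$inputs$pool)
    } else {
      intersect(universe, igraph::V(graph)$name)
    }
    directions <- local({
      g <- rbind(part$unique_a[c("gene_id", "direction")],
                 part$unique_b[c("gene_id", "direction")],
                 data.frame(gene_id = part$common$gene_id,
                            direction = part$common$direction_a,
                            stringsAsFactors = FALSE))
      stats::setNames(g$direction, g$gene_id)
    })
    for (nm in names(gene_sets)) {
      seeds <- gene_sets[[nm]]
      if (!length(intersect(seeds, igraph::V(graph)$name))) next
      ne <- net_enrich(graph, seeds, pool, kegg_cat,
                       R = config$null_replicates,
                       seed = child_seed(config$seed, "null"),
                       form = config$test_form)
      write_network(ne$network, out(paste0("network_", nm)),
                    directions = directions)
      write_enrichment(ne$results, out(paste0("net_enrich_", nm, ".tsv")))
      manifest$counts$network[[nm]] <- list(
        matched_seeds = length(ne$network$matched_seeds),
        unmatched_seeds = length(ne$network$unmatched_seeds),
        nodes = length(ne$network$nodes),
        edges = igraph::ecount(ne$network$graph),
        components = ne$network$n_components)
    }
  })

  if (!is.null(config$inputs$ct_table)) {
    stage("qpcr", quiet, {
      ct <- ct_table(read_ct_table(config$inputs$ct_table),
                     references = config$inputs$references,
                     control = config$inputs$control)
      qfc <- qpcr_fold_changes(ct)
      utils::write.table(qfc, out("qpcr_fold_changes.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      # compare each gene in the sample where the array called it: unique
      # sets in their own knockdown, common genes in the first condition
      labels <- degs$labels
      array_tab <- rbind(
        data.frame(gene = part$unique_a$gene_id, sample = labels[1],
                   fold_change = part$unique_a$fold_change),
        data.frame(gene = part$unique_b$gene_id, sample = labels[2],
                   fold_change = part$unique_b$fold_change),
        data.frame(gene = part$common$gene_id, sample = labels[1],
                   fold_change = part$common$fold_change_a))
      qmatch <- qfc[match(paste(array_tab$gene, array_tab$sample),
                          paste(qfc$gene, qfc$sample)), ]
      keep <- !is.na(qmatch$fold_change)
      if (any(keep)) {
        cmp <- compare_platforms(
          array_tab[keep, c("gene", "fold_change")],
          qmatch[keep, c("gene", "fold_change")])
        utils::write.table(cmp$table, out("platform_comparison.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        manifest$counts$platform_comparison <-
          list(genes = nrow(cmp$table), rank_concordance = cmp$concordance)
      }
      manifest$counts$qpcr <- list(measurements = nrow(qfc))
    })
  }

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Side-by-side comparison of array and qPCR fold changes
#'
#' @param array_fc,qpcr_fc Data frames with columns `gene` and
#'   `fold_change` (linear scale).
#' @return List with `table` (per shared gene: both fold changes and their
#'   log2 difference) and `concordance` (Spearman rank correlation; 1 when
#'   either platform reports a single gene).
#' @export
compare_platforms <- function(array_fc, qpcr_fc) {
  fix <- function(df) {
    if ("gene_id" %in% names(df)) names(df)[names(df) == "gene_id"] <- "gene"
    assert_that(all(c("gene", "fold_change") %in% names(df)),
                "need columns gene and fold_change")
    df[!duplicated(df$gene), c("gene", "fold_change")]
  }
  a <- fix(array_fc); q <- fix(qpcr_fc)
  shared <- intersect(a$gene, q$gene)
  assert_that(length(shared) >= 1, "no shared genes between platforms")
  tab <- data.frame(
    gene = shared,
    array_fc = a$fold_change[match(shared, a$gene)],
    qpcr_fc = q$fold_change[match(shared, q$gene)],
    stringsAsFactors = FALSE)
  tab$log2_diff <- log2(tab$array_fc) - log2(tab$qpcr_fc)
  concordance <- if (nrow(tab) < 2) {
    1
  } else if (stats::sd(tab$array_fc) == 0 || stats::sd(tab$qpcr_fc) == 0) {
    # ranks are undefined for a constant platform; identical tables still
    # count as perfectly concordant
    if (all(abs(tab$log2_diff) < 1e-12)) 1 else NA_real_
  } else {
    stats::cor(tab$array_fc, tab$qpcr_fc, method = "spearman")
  }
  list(table = tab, concordance = concordance)
}

#' Write every synthetic artifact of a design to a directory
#'
#' Materializes the full file surface the pipeline consumes: expression
#' table, probe map, truth table, edge list, GO-like and KEGG-like GMT
#' catalogs, universe and pool gene lists, and a qPCR plate for the planted
#' module's deregulated genes.
#'
#' @param design A [synthetic_design()].
#' @param outdir Output directory.
#' @param qpcr_noise_sd CT noise for the generated plate (cycles).
#' @return Invisibly, a named list of the written paths.
#' @export
write_synthetic_inputs <- function(design, outdir, qpcr_noise_sd = 0) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(outdir, f)
  x <- generate_expression(design)
  graph <- generate_ppi(design)
  paths <- list(
    expression = out("expression.tsv"), probe_map = out("probe_map.tsv"),
    truth = out("truth.tsv"), graph = out("edges.tsv"),
    go_catalog = out("go.gmt"), kegg_catalog = out("kegg.gmt"),
    universe = out("universe.txt"), pool = out("pool.txt"),
    ct_table = out("ct_table.tsv"))
  write_fold_changes(x$table, paths$expression)
  utils::write.table(x$probe_map, paths$probe_map, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_edge_list(graph, paths$graph)
  write_gmt(generate_catalog(design, "go_like"), paths$go_catalog)
  write_gmt(generate_catalog(design, "kegg_like"), paths$kegg_catalog)
  genes <- design_genes(design)
  write_gene_list(genes, paths$universe)
  write_gene_list(intersect(genes, igraph::V(graph)$name), paths$pool)
  refs <- c("RPS13", "ACTB", "TBP", "B2M")
  module_dereg <- intersect(x$module_genes, unique(x$truth$gene_id))
  plate <- generate_qpcr_plate(x$truth, references = refs,
                               seed = design$seed,
                               genes = utils::head(module_dereg, 10),
                               noise_sd = qpcr_noise_sd)
  write_ct_table(plate, paths$ct_table)
  invisible(paths)
}
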