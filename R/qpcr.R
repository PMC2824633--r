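#' Construct a CT table for comparative-CT quantification
#'
#' Cycle-threshold measurements, one row per (sample, gene, replicate), with
#' a designated reference-gene panel and control sample.  Every sample must
#' contain every reference gene, and the control sample must be present.
#'
#' @param df Data frame with columns `sample`, `gene`, `replicate`, `ct`.
#' @param references Character vector of reference (housekeeping) genes.
#' @param control Name of the control sample.
#' @return The validated data frame with class `ct_table` and attributes
#'   `references`, `control`.
#' @export
ct_table <- function(df, references, control) {
  assert_that(all(c("sample", "gene", "replicate", "ct") %in% names(df)),
              "CT table needs columns sample, gene, replicate, ct")
  df <- as.data.frame(df)[c("sample", "gene", "replicate", "ct")]
  assert_that(is.numeric(df$ct) && all(is.finite(df$ct)) && all(df$ct > 0),
              "CT values must be finite and positive")
  assert_that(length(references) >= 1, "need at least one reference gene")
  assert_that(control %in% df$sample, "control sample '", control,
              "' not present")
  for (s in unique(df$sample)) {
    missing <- setdiff(references, df$gene[df$sample == s])
    assert_that(length(missing) == 0,
                "sample '", s, "' lacks reference gene(s): ",
                paste(missing, collapse = ", "))
  }
  structure(df, references = references, control = control,
            class = c("ct_table", "data.frame"))
}

mean_ct <- function(table, sample, gene) {
  ct <- table$ct[table$sample == sample & table$gene == gene]
  assert_that(length(ct) > 0, "gene '", gene, "' not measured in sample '",
              sample, "'")
  mean(ct)
}

#' Reference-normalized CT (delta-CT)
#'
#' `dCT = mean CT(gene) - geometric mean of the reference-gene CTs` in the
#' same sample; replicate CTs are averaged arithmetically first.  With a
#' single reference this is the familiar `CT(gene) - CT(reference)`.
#'
#' @param table A [ct_table()].
#' @param sample Sample name.
#' @param gene Target gene.
#' @return dCT in cycles.
#' @export
#' @examples
#' tab <- ct_table(data.frame(
#'   sample = "s", gene = c("tgt", "ref"), replicate = 1, ct = c(25, 20)),
#'   references = "ref", control = "s")
#' delta_ct(tab, "s", "tgt")  # 5
delta_ct <- function(table, sample, gene) {
  stopifnot(inherits(table, "ct_table"))
  refs <- attr(table, "references")
  ref_cts <- vapply(refs, function(r) mean_ct(table, sample, r), numeric(1))
  mean_ct(table, sample, gene) - exp(mean(log(ref_cts)))
}

#' Comparative-CT fold change
#'
#' `fold change = 2^-(dCT_sample - dCT_control)`; the classical
#' comparative-CT (ddCT) method with implicit amplification efficiency 2.
#'
#' @param dct_sample,dct_control dCT values in cycles.
#' @return Linear-scale relative expression (1 = unchanged).
#' @export
ddct_fold_change <- function(dct_sample, dct_control) {
  2^-(dct_sample - dct_control)
}

#' Fold changes for every (gene, sample) pair relative to control
#'
#' @param table A [ct_table()].
#' @param genes Target genes (default: all non-reference genes).
#' @return Data frame `sample`, `gene`, `dct`, `ddct`, `fold_change`,
#'   `ct_sd` (replicate SD of the target CT, for QC).
#' @export
qpcr_fold_changes <- function(table, genes = NULL) {
  stopifnot(inherits(table, "ct_table"))
  refs <- attr(table, "references")
  control <- attr(table, "control")
  if (is.null(genes)) genes <- setdiff(unique(table$gene), refs)
  samples <- setdiff(unique(table$sample), control)
  out <- expand.grid(sample = samples, gene = genes,
                     stringsAsFactors = FALSE)
  out$dct <- mapply(function(s, g) delta_ct(table, s, g),
                    out$sample, out$gene)
  dct_ctrl <- vapply(genes, function(g) delta_ct(table, control, g),
                     numeric(1))
  out$ddct <- out$dct - dct_ctrl[out$gene]
  out$fold_change <- 2^-out$ddct
  out$ct_sd <- mapply(function(s, g) {
    stats::sd(table$ct[table$sample == s & table$gene == g])
  }, out$sample, out$gene)
  rownames(out) <- NULL
  out
}
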