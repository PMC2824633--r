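# perturbnet

Differential functional annotation of gene-knockdown expression profiles:
fold-change deregulated-gene calling, category enrichment with a
randomization FDR, depth-1-plus expansion through a protein–protein
interaction (PPI) network, and an empirical random-network null for
network-level pathway enrichment — plus comparative-CT (ΔΔCT) qPCR
quantification for validation, and a synthetic-data module that generates
every input with known planted structure.

## Who this is for

You knocked down two related regulators (say, two D-type cyclins) in the
same cell line, profiled expression against a non-specific control, and
want to know which biological functions respond to each knockdown — which
are unique to one regulator and which are shared.  perturbnet takes
per-probe linear expression ratios, a probe→gene map, a PPI edge list and
annotation catalogs (GMT), and produces the unique/unique/common gene
partition, enrichment tables, expanded networks and network-level pathway
statistics, all as plain TSV files.

## The statistics at the core

* **Deregulation**: probe passes iff ratio ≥ *t* or ≤ 1/*t* (inclusive;
  default *t* = 2); a gene is deregulated iff any probe passes, with the
  most extreme passing ratio as representative; discordant genes are
  excluded and reported.
* **Over-representation**: enrichment = (k/n)/(m/N) with one-sided Fisher's
  exact p = P(X ≥ k), X ~ Hypergeom(N, m, n).  GO-like catalogs get a
  randomization FDR (re-draw n genes uniformly, R = 1000 times;
  FDR = E[#null p ≤ p₀] / #observed p ≤ p₀, clipped and monotonized); the
  fixed 38-pathway collection gets Bonferroni (p·38).
* **Network null**: expand seeds at *depth 1 plus* (seeds + immediate
  interactors + all interactions among them); compare each category's share
  of network nodes against R = 1000 networks grown from random seed sets of
  the same matched-seed count;
  t = (obs − mean)/(SD·√(1+1/R)), df = R−1, one-sided, Bonferroni across
  the collection.
* **qPCR**: ΔCT = CT(gene) − geometric mean of reference CTs,
  ΔΔCT = ΔCT(sample) − ΔCT(control), fold change = 2^−ΔΔCT.

## Worked example

Generate a synthetic two-knockdown world (the defaults plant 140 down / 25
up genes in KD1, 90/16 in KD2 with a 34-gene shared down core, and wire one
60-gene pathway module into the interactome), then run the stages:

```r
library(perturbnet)

design <- synthetic_design(seed = 7)
x <- generate_expression(design)
sets <- deregulated_sets(x$table, x$probe_map, threshold = 2)
sets
#> deregulated_sets (threshold 2-fold):
#>   KD1: 166 genes (140 down, 26 up)
#>   KD2: 106 genes (90 down, 16 up)

part <- partition_sets(sets$conditions$KD1, sets$conditions$KD2,
                       labels = c("KD1", "KD2"))
part
#> set_partition: 132 unique to KD1, 72 unique to KD2, 34 common
```

(At noise SD 0.25 a couple of null genes drift past the 2-fold filter —
hence 166 rather than the planted 165.)  Pathway enrichment of the
KD2-unique set finds the planted module far above the Bonferroni bar:

```r
kegg <- generate_catalog(design, "kegg_like")
head(kegg_collection_test(part$unique_b$gene_id, kegg), 3)
#>      category  k   m  n    N enrichment        p adjusted_p
#> 1 path_module 20  60 72 4000      18.52 1.84e-21   6.98e-20
#> 2      path22  5 116 72 4000       2.39 5.65e-02   1.00e+00
#> 3      path25  3  87 72 4000       1.92 2.06e-01   1.00e+00
```

Here k of the n = 72 changed genes fall in the m = 60-gene category, against
a universe of N = 4000; enrichment 18.5 means the category holds 18.5× more
changed genes than its share of the platform predicts.  The network route
tells the same story at the interactome level:

```r
graph <- generate_ppi(design)
pool <- intersect(kegg$universe, igraph::V(graph)$name)
ne <- net_enrich(graph, part$unique_b$gene_id, pool, kegg, R = 200, seed = 7)
ne$network
#> expanded_network: 281 nodes (44 seeds + 237 interactors), 596 edges, 1 component(s)
#>   unmatched seeds: g2171, g0565, ... (28 of 72 seeds have no interactome match)

head(ne$results[c("category", "observed", "null_mean", "t", "p", "adjusted_p")], 3)
#>      category observed null_mean    t        p adjusted_p
#> 1 path_module   0.1993    0.0491 6.74 8.32e-11   3.16e-09
#> 2      path22   0.0463    0.0286 1.98 2.48e-02   9.43e-01
#> 3      path27   0.0427    0.0277 1.73 4.28e-02   1.00e+00
```

19.9% of the expanded network is annotated to the planted module versus
4.9% ± SD in random same-size seed networks — adjusted p ≈ 3×10⁻⁹.

The whole analysis also runs from one YAML config
(`run_pipeline("run.yaml")`) or the CLI
(`inst/scripts/perturbnet all --config run.yaml`), with subcommands
`simulate | degs | qpcr | enrich | ppinet | compare | all` and exit codes
0/1/2 for success / user error / internal error.

## Documentation

`vignettes/perturbnet-methods.Rmd` describes the models, the estimator
choices, the synthetic world and its limits, and every numerical
convention; `?synthetic_design`, `?fisher_enrich`, `?net_enrich`,
`?run_pipeline` document the main entry points.
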