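---
title: "Methods: differential functional annotation of knockdown profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential functional annotation of knockdown profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis problem

perturbnet implements the computational arm of a common experimental design
in cancer systems biology: two related regulators (for example two D-type
cyclins) are knocked down separately in the same cell line, expression is
profiled against a non-specific control, and the question is which
*functions* respond to each knockdown — which are unique to one regulator
and which are shared.  The pipeline has four statistical stages:

1. **Deregulated-gene calling.**  Per-probe linear ratios (treated/control)
   are filtered at a fold-change threshold, collapsed to genes, and the two
   conditions' gene sets are partitioned into unique-A, unique-B and common.
2. **Category over-representation.**  Each gene set is tested against
   annotation catalogs: GO-like term collections with a randomization FDR,
   and a fixed collection of 38 pathway categories with Bonferroni
   correction.
3. **Interactome expansion and network-level enrichment.**  Each gene set is
   expanded through a protein–protein interaction graph at *depth 1 plus*
   (seeds, their immediate interactors, and every interaction among the
   resulting nodes), and each pathway's share of the expanded network is
   compared against an empirical null of networks grown from random seed
   sets of the same size.
4. **Validation-side quantification.**  Comparative-CT qPCR fold changes
   (`2^-ddCT`) with multi-reference geometric-mean normalization, compared
   per gene and condition against the array fold changes.

# Models and estimators

## Fold-change filter and collapsing

"Altered at least `t`-fold" is read inclusively: a probe passes iff its
ratio is `>= t` or `<= 1/t`.  A gene is deregulated iff any of its probes
passes; its representative fold change is the most extreme passing ratio in
the passing direction.  The threshold is on the linear ratio scale and
defaults to 2.  Two conventions here are genuinely open and are fixed as
follows: genes whose probes pass in *both* directions are excluded from both
sets and reported as discordant (exclusion is the conservative choice — an
annotation-level conflict should not silently count as evidence in either
direction), and membership in the common set requires passing in both
conditions regardless of direction agreement, with disagreements flagged in
the output rather than dropped.

## Over-representation

With `N` genes in the background universe (all genes on the platform), `m`
of them in a category, `n` changed genes of which `k` in the category, the
enrichment ratio is `(k/n)/(m/N)` and the p-value is the upper
hypergeometric tail `P(X >= k)`, i.e. the one-sided Fisher's exact test for
over-representation.  Depletion is deliberately not tested.

The randomization FDR re-draws `|changed|` genes uniformly without
replacement `R` times (default `R = 1000`) and recomputes all category
p-values per draw.  For a category with observed p-value `p0`,

```
FDR(p0) = mean over draws of  #(null p <= p0)  /  max(1, #(observed p <= p0))
```

clipped to `[0, 1]` and made monotone non-decreasing in `p0`.  Ties are
counted inclusively (`<=`) so results are reproducible to the bit.  This
ratio-of-exceedances estimator is one of several defensible readings of a
"randomization FDR"; it was chosen because it needs no distributional
assumptions, respects the discreteness of Fisher p-values, and reduces to
the intuitive "expected false positives over observed positives" at any
threshold.

For the fixed 38-pathway collection the correction is Bonferroni
(`p_adj = min(1, 38 p)`): the strictest standard reading of "corrected for
multiple testing" over a small fixed collection, and consistent with how
the network-level test is corrected.

## Network expansion and the random-network null

Depth-1-plus expansion is exactly the induced subgraph on
`matched seeds ∪ neighbors(matched seeds)`.  Seeds absent from the graph
stay visible as "unmatched" but never enter any denominator.  The observed
statistic per category is the fraction of *all* network nodes (seeds and
interactors alike) annotated to the category.

The null ensemble draws `R` seed sets of exactly `s` genes uniformly from
the candidate pool (platform genes present in the graph), where `s` is the
number of *matched seed* proteins of the observed set — not the expanded
network size, which is left free to vary.  The test statistic is

```
t = (observed − null mean) / (null SD · sqrt(1 + 1/R)) ,   df = R − 1
```

a one-sample comparison of a single new observation against a null sample —
hence the prediction-interval inflation `sqrt(1 + 1/R)`; the plain z-form
`(observed − mean)/SD` is available via `form = "z"`.  The one-sided upper
tail is reported together with the empirical percentile
`(1 + #(null >= observed))/(R + 1)`.  When the null SD is zero the result is
flagged degenerate: p is 1 if the observation does not exceed the null mean,
otherwise the empirical floor `1/(R + 1)`.  Null seeds are *not*
degree-matched; uniform sampling is the default and a degree-matched variant
is left as an extension.

## Comparative CT

`dCT = mean CT(gene) − geometric mean of reference CTs` per sample (replicate
CTs averaged arithmetically first), `ddCT = dCT(sample) − dCT(control)`,
fold change `= 2^−ddCT` with amplification efficiency 2 implicit.  The
geometric mean is taken over the reference CT *values* themselves — the
natural reading of geometric-mean normalization of `dCT`.  The alternative
(geometric mean of linearized `2^−CT` abundances, i.e. an arithmetic mean of
reference CTs) differs only when reference CTs vary across samples; with the
package's synthetic plates (sample-invariant reference CTs) the two are
identical, and both conventions cancel exactly in `ddCT` whenever the
reference panel shifts with the target.

# The synthetic world

The generator states one fixed world; its defaults are not tuning knobs.

| parameter | default | rationale |
|---|---|---|
| universe | 4000 genes, 4600 probes | scaled-down expression platform; many-to-one probe map, mean multiplicity 1.15 |
| conditions | KD1, KD2 vs implicit control | two-knockdown + non-specific-control design |
| planted deregulation | KD1: 140 down/25 up; KD2: 90 down/16 up; 34 shared down | mirrors the 165/106-gene two-knockdown structure with a 34-gene common core |
| effects | 0.25 (down), 4.0 (up), noise SD 0.25 on log2 | comfortably past the 2-fold filter in expectation; array-like noise |
| interactome | preferential attachment, m = 3, half the universe absent | scale-free degree distribution; roughly half of targets find no interactome match, as is typical |
| planted module | 60 genes, 20 deregulated in KD2, pairwise wiring p = 0.1 | a pathway-sized gene set, condition-specific signal, mean intra-module degree ~6 |
| catalogs | 60 GO-like terms; exactly 38 pathway-like categories | fixed pathway-collection size of 38; one category per collection equals the planted module |

Two sizing choices deserve explanation.  First, the interactome (2000
nodes) is large relative to a ~50-seed expansion (~10% coverage), matching
the proportions of real interactome queries; in an early trial world with a
500–1000-node graph the expansions covered a third of the graph and the
null absorbed most of the planted signal.  Second, the module's internal
wiring is moderate (`p_within = 0.1`).  A near-clique module turns out to be
*undetectable* by the network-null design: any random network that touches
one member recruits the whole module, so the null mean rises toward the
observed ceiling.  Moderate density keeps the module recruitable by its own
deregulated seeds while random networks recruit it only partially — which
is precisely the structure the random-network null is designed to detect.

What the generator does **not** emulate: probe-level intensity distributions
and normalization artifacts (the pipeline starts from ratios), correlated
noise across probes of a gene, degree-annotation correlations in real
interactomes beyond what preferential attachment induces, and amplification
efficiency variation in qPCR.  A green planted-recovery test therefore
establishes that the pipeline detects the stated structure under stated
noise — not that real arrays have this noise model.

# Numerical and reproducibility choices

* One root seed; each artifact and each stochastic stage derives an
  independent child stream, so regenerating one artifact never perturbs
  another, and identical configurations give bit-identical outputs.
* Fisher p-values use the exact hypergeometric tail (`phyper`), not a
  simulation; the test suite checks them against exhaustive enumeration of
  all draws for every configuration with `N <= 12`.
* FDR and null-ensemble counting use inclusive ties throughout.
* Enrichment tables are sorted by p (then category id) so output order is
  deterministic under ties.
* Empty intersections, seeds absent from the graph, categories emptied by
  universe restriction, and zero-SD nulls all have defined, tested
  behaviour rather than NA propagation.

# Scaling of the shipped checks

Production defaults are 1000 randomizations and 1000 null networks.  The
no-signal FDR calibration check in the acceptance suite uses 200
randomizations per run across 200 runs to stay inside its stated runtime
budget; all other acceptance checks run at their stated scales (500 oracle
graphs, 1000 calibration draws against a 1000-replicate null, 100
planted-recovery runs at 200 null networks each).

# Known limitations

* The randomization FDR is an estimator of a global error rate evaluated
  pointwise; it is not a step-up procedure and can be conservative for
  highly correlated categories.
* The network null conditions on seed count only; degree-matched or
  component-matched nulls would be stricter against hub-heavy seed sets.
* The t-form assumes the null proportions are approximately normal; for
  very small categories the empirical percentile (always reported) is the
  safer quantity.
* Common-set fold changes are carried per condition but summarized by the
  first condition where a single value is needed (platform comparison).
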