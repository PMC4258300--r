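---
title: "Methods: co-expression module discovery inside GO gene sets"
author: "comod package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression module discovery inside GO gene sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comod)
```

## The problem and the model

Genome-wide co-expression analysis of case/control microarray cohorts
tends to produce very large, hard-to-interpret modules. `comod` instead
searches for disease-associated co-expression modules *inside* Gene
Ontology biological-process (GO_BP) gene sets: within each term of 50-500
measured genes, a weighted gene co-expression network is built and
clustered, and the resulting modules are carried through a two-step
disease-association gate plus candidate-gene enrichment.

The per-term network model is standard WGCNA-style analysis. For genes
$i, j$ of a term, Pearson correlation $r_{ij}$ is soft-thresholded into an
unsigned adjacency $a_{ij} = |r_{ij}|^\beta$, and genes are clustered on
the topological overlap dissimilarity

$$d_{ij} = 1 - \mathrm{TOM}_{ij}, \qquad
\mathrm{TOM}_{ij} = \frac{\ell_{ij} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}},$$

with $\ell_{ij} = \sum_{u \neq i,j} a_{iu} a_{uj}$ and
$k_i = \sum_{u \neq i} a_{iu}$. Each module is summarized by its
*eigengene* (the first principal component of the standardized member
profiles, unit norm over samples) and each gene by its *module
membership* kME, the correlation between the gene's profile and the
eigengene. A module is therefore a one-factor model of its member genes;
`fit_modules()` returns this fit as a classed object with `summary()`,
`coef()` (the kME matrix), `predict()` (projection of the eigengene onto
new samples via its gene weights), `residuals()` and `plot()` methods.

Cross-cohort replication is quantified by the permutation
$Z_\mathrm{summary}$ statistic: density statistics (mean correlation,
mean adjacency, eigengene variance fraction, mean kME) and connectivity
statistics (cross-cohort correlations of intramodular connectivity, of
the correlation matrices, and of kME) are computed for the gene set in
the testing cohort using reference-defined structure, standardized
against the same statistics on random gene sets of equal size, and
combined as the mean of the two group medians. The conventional bands
apply: below 2, no evidence; 2-10, weak to moderate; above 10, strong
evidence of preservation.

The full pipeline (`run_pipeline()`) is: per-cohort array QC →
quantile normalization → probe filtering → gene intersection → GO-term
size filter (50-500 measured genes, inclusive) → term preservation screen
($Z_\mathrm{summary} > 5$, strict) → per-term module fitting → eigengene
versus disease status (Pearson correlation, two-sided t test, joint
BH-FDR < 0.05) → module preservation in the testing cohort
($Z_\mathrm{summary} > 5$) → hypergeometric enrichment against five
candidate-evidence categories (cis-eQTL, trans-eQTL, SCNA, somatic
mutation, prognostic; BH-FDR < 0.05 in at least two distinct categories)
→ Fisher-exact merging of overlapping candidates → TF/miRNA target-set
enrichment (FDR < 0.01, minimum two overlapping genes, top 5 reported).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `iac_z` | 5 | robust z-score (median/MAD) cut for outlier arrays, per phenotype stratum |
| `max_missing` | 0.30 | probes missing in strictly more than this fraction of samples are dropped |
| `go_min`, `go_max` | 50, 500 | inclusive measured-gene window for eligible terms |
| `power` | 6 | soft-threshold exponent; `"auto"` selects by scale-free fit ($R^2 \ge 0.8$) |
| `min_module_size` | 10 | smallest cluster accepted as a module |
| `merge_height` | 0.25 | eigengene-dissimilarity cut below which modules merge |
| `kme_cut` | 0.3 | members with kME $\le$ 0.3 are reassigned to grey (inclusive removal) |
| `term_select_cut`, `module_select_cut` | 5 | strict $Z_\mathrm{summary}$ selection thresholds |
| `trait_fdr`, `enrich_fdr` | 0.05 | BH-FDR levels for trait association and evidence enrichment |
| `min_categories` | 2 | distinct evidence categories required to call a candidate |
| `regulator_fdr` | 0.01 | BH-FDR level for regulator ranking (min overlap 2, top 5) |
| `n_perm` | 200 | permutations per preservation evaluation |

All thresholds that gate results (`> 5`, `\le 0.3`, `> 30\%` missing,
50-500 sizes) are applied with the strictness stated: a term of exactly
50 measured genes is eligible, a probe missing in exactly 30% of samples
is retained, kME of exactly 0.3 is removed, and $Z_\mathrm{summary}$ of
exactly 5 is *not* selected.

## The synthetic two-cohort generator

Because the real training/testing cohorts and candidate-gene evidence
are external downloads, every stage is exercised on a synthetic
generator (`simulate_cohorts()`, `simulate_gene_sets()`) whose planted
truth is known. Gene $g$ of planted module $m$ in sample $s$ is

$$x_{gs} = b_g + \lambda\, f_{ms} + \varepsilon_{gs}, \qquad
f_{ms} \sim N(d \cdot \mathrm{status}_s,\ 1), \quad
\varepsilon_{gs} \sim N(0, \sigma^2),$$

with a per-gene baseline $b_g \sim N(8, 1)$ shared by both cohorts,
loading $\lambda$, case shift $d$ and noise $\sigma$. Background genes
are baseline plus noise. A single latent factor per module was chosen so
that the module eigengene is the natural estimator of the factor and
recovery is analytically interpretable. Planted modules are pairwise
disjoint (one factor per gene), since overlapping factors would make the
planted "truth" ill-defined for recovery scoring.

Design choices that deserve explanation:

* **Per-gene baselines.** Inter-array correlation is computed across
  genes, so without a shared gene-level intensity profile all arrays
  would be mutually uncorrelated and IAC-based QC meaningless. The
  $N(8,1)$ baseline reproduces the strongly positive IAC (~0.7) of real
  log-intensity arrays; it cancels in all row-standardized statistics.
* **Outlier arrays.** An injected outlier receives an independent
  per-gene perturbation with mean and sd both $4\sigma$. A purely
  constant shift would be invisible to Pearson-based IAC (correlation is
  translation invariant); the random component decorrelates the array,
  which is what IAC actually detects, while the mean component mimics an
  intensity artifact.
* **Non-preserved modules.** In the testing cohort the factor of a
  non-preserved module is re-planted on a fresh random gene set drawn
  from the whole universe. Re-permuting only within the host term would
  leave an intact module inside the same term and term-level density
  preservation would stay high — the screen could then never reject such
  terms.
* **Missingness** is completely at random, matching the premise of the
  fraction-based probe filter.
* Expression is emitted directly on a log2-like scale; raw-intensity
  simulation adds nothing the QC stages can detect.

The default study design (`default_design()`): 1500 genes; training
cohort 40 tumor / 20 control, testing cohort 30 tumor / 15 control
(about half the sample sizes of the microarray cohorts this kind of
analysis targets); ten GO-like terms of 60-100 genes, each hosting one
30-gene module with $\lambda = 0.9$, $\sigma = 0.5$, $d = 1.5$; modules
1-6 preserved, 7-10 re-planted; evidence sets cover module 1 (cis-eQTL,
mutation, prognostic) and module 2 (cis-eQTL, SCNA) at 60% overlap plus
40 background genes each, module 3 only in trans-eQTL; regulators TF_A
and MIR_B cover modules 1 and 2 at 80% plus 20 decoy target sets; 2%
missingness and two outlier arrays per cohort. The designed funnel truth
is 6 screened terms → 6 trait-associated modules → 2 candidates. The
case shift $d = 1.5$ gives a population eigengene-trait correlation near
0.6, i.e. essentially unit power per module at these sample sizes; at
$d = 1.2$ the per-module miss probability is a few percent and a
20-replicate funnel check would measure sampling noise rather than the
pipeline.

What passing on this generator does *not* show about real data: the
generator has no batch effects, no platform differences between cohorts,
no correlated (non-factor) background structure, no heavy-tailed
intensity distributions and no informative missingness. Results on real
cohorts depend on upstream normalization choices the generator
deliberately idealizes.

## Numerical and algorithmic choices

* **Module detection.** The dendrogram (average linkage on $1 -
  \mathrm{TOM}$) is cut by a deterministic static-cut scan: heights from
  $0.99 \cdot h_{max}$ downward on a 0.01 grid, keeping the cut that
  maximizes the number of clusters of at least `min_module_size` genes
  (ties resolve to the highest such cut). This preserves the observable
  contract of dynamic branch cutting — minimum size, TOM dissimilarity
  input, noise stays grey because pure-noise merges concentrate above
  $0.99 \cdot h_{max}$ — while being exactly reproducible. Pipeline
  order is detect → merge → prune, and pruning is a single pass.
* **Scale-free fit.** The fit index bins $\log_{10} k$ into at most 10
  equal-width bins and regresses $\log_{10} p(k)$ on $\log_{10} \bar k$,
  signed by the negative-slope requirement. Equal-width binning is
  essential: with equal-count bins $p(k)$ is constant by construction
  and the regression is degenerate. The default is the fixed
  conventional power $\beta = 6$ for unsigned networks; automatic
  selection (smallest power with signed $R^2 \ge 0.8$, else the argmax
  with a warning) is available but noisy on 50-500-gene networks.
* **Outlier rule.** "Clear outliers" are operationalized as mean-IAC
  robust z-scores (stratum median/MAD) below -5, iterated to a fixed
  point and never shrinking a stratum below 3 arrays. Median/MAD resists
  masking when two outliers share a small stratum; the conservative cut
  reflects that well-behaved arrays reach z of -3 to -4 through ordinary
  biological heterogeneity, while injected artifacts sit below -11.
* **Eigengene conventions.** Gene profiles are standardized before the
  SVD and missing values imputed to the gene mean; the eigengene sign is
  fixed by non-negative correlation with the mean standardized module
  profile, making case/control eigengene plots reproducible. In the
  preservation statistics the reference cohort defines the gene weights,
  which are projected onto the (standardized, mean-imputed) testing
  cohort.
* **Preservation null.** Equal-size random gene sets are drawn from the
  shared gene universe (not sample permutation), 200 draws by default;
  statistics with degenerate null spread (< 1e-12) are dropped from
  their group median with a warning — this happens, for example, for
  connectivity statistics when testing a cohort against itself, where
  observed and null correlations are all exactly 1.
* **Exact tests.** Hypergeometric upper tails come from `phyper` and
  coincide with one-sided Fisher tests; candidate merging uses two-sided
  Fisher tests Bonferroni-corrected over candidate pairs at
  $\alpha = 0.01$. FDR families are: all module x category evidence
  tests in one batch; regulator sets per module; trait p-values jointly
  across all detected modules. Rankings break ties by FDR, then p, then
  name.
* **Seeds.** Every stage seed derives from the master seed by a stable
  polynomial hash of the stage label and item name (`derive_seed()`),
  so per-term results do not depend on iteration order and a rerun with
  the same master seed is identical.

## Problem sizes used by the test suite

The packaged checks run the generator at desk scale: universes of
150-1500 genes, terms of 40-100 genes, modules of 12-30 genes, cohorts
of 30-60 arrays, and 60-200 permutations per preservation evaluation;
replicated checks use 20 seeds. These sizes were chosen so that planted
effects sit clearly above sampling noise at the stated thresholds while
a full 20-replicate pipeline run stays in the minutes range on one CPU.

## Known limitations

* Unsigned networks only; signed and signed-hybrid adjacencies, and
  robust correlation variants (e.g. biweight midcorrelation), are out of
  scope.
* A gene belonging to several GO terms is analyzed independently in each
  term; no cross-term deduplication occurs before the candidate-merge
  stage.
* The static-cut scan does not implement the full adaptive "dynamic
  hybrid" branch-cutting heuristics (no PAM-like relabeling stage);
  its behavior matches on well-separated modules, which is the regime
  the GO-term-sized networks target.
* The preservation roster is fixed to 4 density + 3 connectivity
  statistics; the composite `medianRank` alternative is not provided.
* Identifier matching is exact and case-sensitive; mapping between
  annotation vocabularies is the caller's responsibility.
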