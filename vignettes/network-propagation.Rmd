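---
title: "Prioritising disease-associated m6A sites by network propagation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritising disease-associated m6A sites by network propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylwalk)
```

## The problem

N6-methyladenosine (m6A) is the most abundant internal mRNA modification,
and dysregulated methylation at individual sites is increasingly implicated
in disease. Associations between diseases and *genes* are curated at scale,
but associations between diseases and *individual m6A sites* are largely
unknown: there is no gold standard to learn from directly. methylwalk
infers them indirectly, by propagating information through a three-layer
heterogeneous network whose nodes are diseases, genes and m6A sites, and
whose edges come from data that *is* available: methylation and expression
profiles across many MeRIP-seq conditions, curated disease–gene
associations, and vocabulary-based disease similarity.

## From read counts to profiles

Inputs begin at RPKM tables (read alignment and counting are out of scope).
The methylation level of a site under one condition is the M-value

$$M = \log_2 \frac{\mathrm{RPKM}_{IP} + 0.1}{\mathrm{RPKM}_{Input} + 0.1},$$

the log2 enrichment of the immunoprecipitated library over its input
control, with a fixed pseudo-count of 0.1 that keeps the value finite and
shrinks lowly expressed sites toward 0. Biological replicates of a
condition are merged by the arithmetic mean of their RPKM values before
M-values are formed ("merged" is all the upstream convention specifies;
the mean is the least surprising choice and is exposed via
`merge_replicates()`). Matrices are then quantile-normalized so every
condition shares one value distribution; ties receive the mean of the
tied-rank reference values. Whether normalization is applied to the RPKM
matrices or to the M-value matrix is not fixed by convention; the default
(`normalize = "m_first"`) normalizes M-values, since that is the matrix
all downstream correlations are computed on, and `"rpkm_first"` is
available for sensitivity analysis.

Sites are then filtered in three ordered steps, each percentile computed
on the survivors of the previous step:

1. experimental support strictly greater than 10 reporting experiments;
2. mean M-value at or below the 70th percentile of per-site means —
   "within the 70 percentile" is ambiguous, and we read it as excluding
   the extreme-high, likely antibody-saturated sites (`level_rule =
   "ge_pct"` selects the opposite tail);
3. M-value variance at or above the 20th percentile, i.e. the top 80
   percentiles by variability: the actively regulated sites whose disease
   relevance is inferable.

Percentiles use linear interpolation between order statistics
(`quantile(type = 7)`), and ties at a threshold are kept. Note that the
percentile steps are *not* idempotent: re-filtering an already filtered
profile trims a further 30%/20%, because the thresholds are recomputed on
the survivors. That is the intended sequential-pipeline semantics, not an
accident.

## Association networks

Three of the five edge sets are correlation networks over the 38 (by
default) experimental conditions: site–site, gene–gene and gene–site. For
every pair we compute the Pearson correlation and its two-sided p-value
from the Fisher z-transformation, $z = \operatorname{atanh}(r)\sqrt{n-3}$
against the standard normal ("Fisher's asymptotic test"; the Student-t
variant is available via `method = "t"`). P-values are
Bonferroni-adjusted over the number of pairs actually tested in that
network (constant rows are skipped with a warning and reduce the
divisor). A pair becomes an edge when its adjusted p-value is below 0.05
*and* its correlation ranks in the top or bottom 10 percentile of all
tested correlations, ties at the threshold kept. The edge weight is
$|r|$: positive and negative co-methylation are deliberately not
distinguished, because the regulatory consequence of either sign is
ambiguous at the epitranscriptome layer; the sign is retained in the edge
table for the direction step.

Disease–disease similarity is the Jaccard index of MeSH term sets,
$V_{ij} = |d_i \cap d_j| / |d_i \cup d_j|$, with no cut-off (zero-weight
pairs are simply absent edges, which is equivalent under column
normalization). Ontology-aware semantic similarity is a non-goal.
Disease–gene associations are ingested as an unweighted bipartite graph;
an optional third column of over/under-expression labels is carried along
for the direction call.

## The block transition matrix

Nodes are ordered (diseases, genes, sites) and the five networks are
stacked into one sparse matrix

$$W = \begin{bmatrix}
\tfrac12 M_{DD} & \tfrac13 M_{GD} & 0 \\
\tfrac12 M_{DG} & \tfrac13 M_{GG} & \tfrac12 M_{SG} \\
0 & \tfrac13 M_{GS} & \tfrac12 M_{SS}
\end{bmatrix},$$

each block independently column-normalized, all five networks weighted
equally (learning the block weights is explicitly out of scope). The
disease–site blocks are structural zeros — that association is exactly
what is unknown. Two numerical choices matter here:

* **Missing-block redistribution** (`column_policy = "redistribute"`,
  default): if a node has no edges in one of its blocks, that block's
  weight is reassigned proportionally to its remaining blocks, so every
  non-isolated column sums to exactly 1. Without this, such columns sum
  below 1 and probability mass leaks on every iteration; the `"leak"`
  policy is kept for comparison.
* **Isolated nodes** keep an all-zero column; the restart term bounds the
  total mass regardless.

## Random walk with restart

From a seed disease $d$ with indicator vector $P_0$, iterate

$$P_{s+1} = (1 - r)\, W P_s + r\, P_0$$

with restart probability $r = 0.75$, stopping when the step difference
falls to $10^{-10}$ or below. The stopping norm is not fixed by the
recurrence itself; we use the $L_\infty$ norm of the difference vector
(an $L_1$ option exists). Because the map contracts at rate $1-r$ on
column-stochastic matrices, convergence needs at most
$\lceil \log(10^{-10}) / \log(0.25) \rceil \approx 17$ iterations; a
`max_iter` safeguard of 1000 flags rather than throws on
non-convergence. `rwr_solve()` provides the closed-form fixed point
$P = r (I - (1-r) W)^{-1} P_0$ as an exact oracle at test scale. Sites are
ranked by their stationary probability, ties broken lexicographically so
rankings are deterministic.

## Significance and direction

Empirical significance comes from degree-preserving randomization: two
edges a–b and c–d are exchanged into a–d and c–b when neither new edge
exists and no self-loop arises, attempted 10 times per edge (mixing time
is not specified upstream; 10 is configurable). Each of the five
sub-networks is randomized separately, which preserves the layer
structure, node sets and every degree exactly; for weighted within-layer
networks only the topology is swapped and each edge's weight travels with
its slot — an approximation we document rather than hide. One hundred such
networks (default) are reassembled and re-walked, and a site's empirical
p-value compares its real probability to its own null sample with the
add-one rule $p = (1 + \#\{\text{null} \ge \text{obs}\})/(K+1)$, which
keeps $p > 0$ and counts ties against the observation. A pooled-null
variant is available.

The direction call: correlate the site's M-values with each disease
gene's expression, multiply by $-1$ for genes under-expressed in the
disease, and take the median. Positive medians mean hyper-methylation
under the disease condition, negative hypo-methylation; an exact zero (or
no usable gene) yields `NA` rather than an arbitrary call.

## The hypergeometric baseline

The comparison method scores a disease–site pair by whether the two are
simultaneously linked to a significant number of genes, using only the
disease–gene and gene–site networks: with $m$ genes in total, $n$ linked
to the disease, $x$ to the site and $y$ to both, the score is the
hypergeometric upper tail $P(Y \ge y)$. (The printed formula upstream
drops a $C(x,i)$ factor from the summand; we implement the standard
distribution the test names.) No multiple-testing correction is applied
here, matching the original usage.

## Evaluation design

There is no disease–site gold standard, so cross-validation operates on
the disease–gene associations: each fold removes 10% of DG edges, the
transition matrix is rebuilt, and held-out pairs are scored as positives.
For the walk, a (disease, gene) score is the gene node's stationary
probability from that disease's walk. Negatives are the same disease's
genes never associated with it (`negatives = "all_genes"` widens this;
the original work does not state its negative set, so the choice is
explicit and configurable). For the baseline, a disease–gene pair is
scored through the only links that method may use (DG and SG): the
hypergeometric overlap between the site neighbourhood of the disease's
*training* genes and the candidate gene's own site neighbourhood. The
random control draws i.i.d. uniform scores. ROC curves use midrank tie
handling, so the AUC equals the normalized Mann–Whitney statistic; both
unweighted mean and median per-disease AUCs are reported.

`host_gene_diagnostic()` reproduces the classic sanity check that
M-values are not merely tracking host-gene expression: per-site
correlations with the host gene are compared against 1000 random
site–gene re-pairings. On data where methylation and expression are
generated independently, the two distributions coincide.

## The synthetic benchmark

`simulate_study()` generates every input the pipeline consumes, from a
transparent latent-factor model (chosen over copulas for inspectability):

* genes fall into `n_modules = 10` modules; module $k$ has a latent
  factor $f_k \sim N(0,1)$ per condition, and a member profile is
  $\sqrt{\rho} f_k + \sqrt{1-\rho}\,\varepsilon$ with
  $\rho = 0.8$ (`corr_strength`), so within-module correlation is
  $\rho$ by construction;
* RPKM values are exponentials of these Gaussian profiles scaled into a
  realistic 0–100 range, so the 0.1 pseudo-count is genuinely exercised;
* each site inherits its host gene's module; its Input RPKM is
  independent noise and its IP RPKM is chosen so the implied M-value
  equals the site's latent profile;
* support counts mix Poisson(25) (90%) and Poisson(6) (10%) so the
  strict `> 10` filter has work to do;
* each disease carries 1–2 modules and links to half of each module's
  genes (`frac_disease_genes = 0.5`), with over/under labels. Within
  each module a third of the genes are *recurrently implicated* (9-fold
  pick odds), so related diseases share specific genes and not merely a
  module — the property of curated disease–gene resources that makes the
  disease-similarity layer informative. Without it, held-out positives
  are statistically exchangeable with in-module negatives and no method
  can order them;
* MeSH terms are drawn mostly from per-module pools, so diseases sharing
  modules share terms;
* the planted truth — sites whose host-gene module matches a disease's
  modules — reaches the emitted files only through this module structure,
  never directly.

Default sizes are 50 diseases, 300 genes, 800 sites, 38 conditions, seed
7. On this benchmark the ten-fold CV yields a median per-disease AUC of
about 0.98 for the walk, with the ordering walk > hypergeometric baseline
> random (≈0.5) stable across fold seeds.

What the generator does *not* emulate: read-level MeRIP-seq artefacts
(peak shapes, antibody batch effects), heavy-tailed expression, hub genes
with pleiotropic disease links, incomplete/biased curation of the DG
resource, and MeSH's hierarchical structure. Passing the benchmark
therefore shows the machinery recovers planted multi-layer structure —
not that the published real-data AUCs are reproduced, which would require
the original external resources.

## Problem sizes and runtime choices

Unit tests run on networks of tens of nodes; oracle-equivalence checks go
up to 2000 nodes where the dense/sparse solve is still instant; the
benchmark (1150 network nodes after filtering, ~120k scored CV pairs)
runs in seconds on one core. The permutation-significance pipeline is the
only expensive stage (100 networks x one walk per disease); its inner
rewiring loop is compiled, and test configurations use smaller
`n_networks` since the statistical contract (degree preservation,
super-uniform p-values) is checked separately at scale.

## Known limitations

* Bonferroni over hundreds of thousands of pairs is deliberately severe;
  combined with the percentile band it reproduces the original edge
  selection, but it discards weak true associations.
* Edge weights in randomized within-layer networks are carried per slot,
  not resampled, so the null preserves the weight multiset but not any
  weight–degree coupling.
* The CV baseline adaptation (scoring genes through their site
  neighbourhoods) is our construction; the original work only describes
  the baseline for disease–site scoring.
* RWR scores correlate with node degree; no degree correction is applied,
  matching the original method. The permutation null absorbs part of this
  at prediction time, but CV scores are raw probabilities.
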