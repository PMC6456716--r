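# methylwalk

Prioritises disease-associated **m6A RNA methylation sites** by propagating
a random walk with restart over a three-layer heterogeneous network of
diseases, genes and m6A sites.

Individual m6A sites have no curated disease associations, but the data
around them do: MeRIP-seq methylation profiles across many experimental
conditions, matched gene expression, curated disease–gene associations,
and MeSH-based disease similarity. methylwalk stitches these into one
column-normalised block transition matrix

```
        ┌ 1/2·M_DD  1/3·M_GD     0     ┐
  W  =  │ 1/2·M_DG  1/3·M_GG  1/2·M_SG │
        └    0      1/3·M_GS  1/2·M_SS ┘
```

(disease–site blocks are structural zeros — they are what is unknown) and
ranks sites for a seed disease *d* by the stationary distribution of

```
P[s+1] = (1 − r)·W·P[s] + r·P0 ,   r = 0.75,  stop at ‖ΔP‖∞ ≤ 1e-10 .
```

Around that core it provides the full method: M-value quantification
`log2((RPKM_IP + 0.1)/(RPKM_Input + 0.1))` with replicate merging,
quantile normalization and support/level/variance site filtering;
correlation networks with Fisher-z tests, Bonferroni control and a
top/bottom-10-percentile band; Jaccard MeSH disease similarity;
degree-preserving edge-swap randomization for empirical p-values and
hyper/hypo-methylation direction calls; a hypergeometric-overlap baseline;
ten-fold cross-validated ROC/AUC evaluation; and a seeded synthetic-data
generator so everything is testable without external downloads.

Who it is for: computational biologists studying the epitranscriptome who
want site-resolution disease candidates from public MeRIP-seq compendia,
or who want a transparent, tested reference implementation of
heterogeneous-network propagation to build on.

## Worked example

Everything below is simulated — the generator plants co-methylation
modules, disease–gene links and MeSH annotations with known structure, so
the pipeline can be exercised end to end in seconds.

```r
library(methylwalk)

study <- simulate_study(synth_config(n_diseases = 10, n_genes = 100,
                                     n_sites = 250, n_modules = 5,
                                     rng_seed = 7))
nets <- build_networks(study)              # profiles -> 5 association networks
het  <- assemble_hetnet(nets$dd, nets$gg, nets$ss, nets$dg, nets$sg)
het
#> <hetnet: 10 diseases, 100 genes, 128 sites; 5520 transitions>
```

250 simulated sites enter; 128 survive the support (>10 experiments),
mean-level (≤ 70th percentile) and variance (top 80 percentiles) filters.
Now walk from a disease and rank sites:

```r
res <- rwr(het, "D01")
glance(res)
#> # A tibble: 1 × 5
#>   seed_id     r iterations converged total_mass
#>   <chr>   <dbl>      <int> <lgl>          <dbl>
#> 1 D01      0.75         12 TRUE               1

head(rank_sites(res), 5)
#> # A tibble: 5 × 3
#>   site_id probability  rank
#>   <chr>         <dbl> <int>
#> 1 S231       0.000782     1
#> 2 S205       0.000777     2
#> 3 S107       0.000676     3
#> 4 S063       0.000649     4
#> 5 S025       0.000579     5
```

The walk converged in 12 iterations (the 1 − r contraction makes that
guaranteed); probabilities over all nodes sum to 1, and the top sites are
those most visited when restarting at disease D01 — sites whose host-gene
modules the disease's genes belong to. How much do the extra network
layers buy over just counting shared genes? Cross-validate on held-out
disease–gene links:

```r
plan <- make_folds(nets$dg, k = 10, rng_seed = 1)
cv <- cross_validate(nets, plan, rng_seed = 1)
glance(cv)
#> # A tibble: 3 × 6
#>   method     auc n_pairs mean_disease_auc median_disease_auc n_diseases
#>   <chr>    <dbl>   <int>            <dbl>              <dbl>      <int>
#> 1 baseline 0.847    6890            0.843              0.886         10
#> 2 random   0.501    6890            0.505              0.528         10
#> 3 rwr      0.864    6890            0.870              0.876         10
```

The walk (AUC 0.864) beats the hypergeometric baseline (0.847), which in
turn beats the random control (~0.5). `autoplot(cv)` draws the pooled ROC
curves; `rwr_significance()` adds permutation p-values from 100
degree-preserving network randomizations, and `run_pipeline()` wires all
stages (including per-disease prediction tables with hyper/hypo direction
calls and a reproducibility manifest) behind one config. A thin CLI lives
at `inst/cli/methylwalk`.

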