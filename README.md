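# treebic

Biclustering of tree-shaped time-series single-cell gene expression data.

## The problem

Time-lapse confocal imaging of *C. elegans* embryos records, for each
labelled gene in each individual, a fluorescence time series per cell
along the invariant cell lineage — a binary tree of divisions with cells
named in Sulston nomenclature. Although samples arrive every 1.5 minutes,
homologous cells live for different durations in different individuals, so
series from different reporter *copies* are non-pairwise and cannot be
correlated point by point. `treebic` is for researchers who want to find
**biclusters** in such data: subsets of genes sharing coherent expression
dynamics within subsets of cells, with overlap between biclusters allowed.

## The method

1. **Fit.** Per copy and founder lineage (`AB`, `MS`, `E`, `C`, `D`), each
   cell's series gets its own polynomial, with value and first-derivative
   continuity imposed at every division point (equality-constrained least
   squares via null-space reparameterization). Degrees follow a cubic
   baseline growing with series length; the growth step is picked per
   subtree by BIC. The derivative F′ — the expression *rate* — is what gets
   compared across genes, avoiding the spurious correlation of
   accumulating fluorescence levels.

2. **Score.** A bicluster B = (G, C), at least 2×2, is scored

   `f(B) = α·log(mean Corr) + λ·log(mean minₘ KS-p) + β·log ES − δ·log(1 + overlap)`

   where `Corr` averages Pearson correlations of unit-interval-rescaled
   rate functions over gene pairs and cells, the KS term averages over
   cell pairs the *minimum* two-sample Kolmogorov–Smirnov p-value (on
   expression increments) across the bicluster's genes, `ES` counts
   expressed entries in the binary onset matrix, and the last term
   penalizes overlap with previously accepted biclusters. Defaults:
   α = 0.55, λ = 0.25, β = 1, δ = 0.065.

3. **Search.** An elitist genetic algorithm (population 100, 1000
   generations per bicluster by default) with expression-proportion
   pruning at 0.6 extracts biclusters sequentially; the k-th bicluster is
   accepted only if it beats the 99% quantile of 100 randomly initialized
   candidates.

A synthetic generator (`simulate_lineage_dataset()`) produces tree-shaped
datasets with known ground truth — per-individual lifetimes, smooth
trajectories continuous across divisions, missing cells, and planted
biclusters — so everything is testable without any download.

## Worked example

```r
library(treebic)

ds <- simulate_lineage_dataset(sim_config(
  n_genes = 12, n_cells = 20, seed = 1,
  planted = planted_bicluster(4, 6)
))
fits <- fit_dataset(ds)
glance(fits)
#> # A tibble: 1 × 7
#>   n_subtrees r2_mean r2_sd r2_p25 r2_p50 r2_p75 r2_max
#>        <int>   <dbl> <dbl>  <dbl>  <dbl>  <dbl>  <dbl>
#> 1         60   0.894 0.254  0.999  1.000  1.000  1.000

ctx <- bicluster_context(ds, fits)
res <- search_biclusters(ctx, search_config(num = 40, max_i = 150,
                                            max_biclusters = 1, seed = 2))
tidy(res)
#> # A tibble: 1 × 9
#>       k n_genes n_cells score correlation similarity  size overlap   q_k
#>   <int>   <int>   <int> <dbl>       <dbl>      <dbl> <dbl>   <dbl> <dbl>
#> 1     1       4       8  3.11      -0.234     -0.775  3.43       0  2.59

res$gene_labels[[1]]
#> [1] "g01_c01" "g03_c01" "g05_c01" "g11_c01"
attr(ds, "truth")$planted[[1]]$copies
#> [1] "g01_c01" "g03_c01" "g05_c01" "g11_c01"
```

The fitted subtrees track the smooth simulated trajectories closely (mean
R² 0.89; short cells fit worst). The single accepted bicluster recovers
all four planted genes exactly and its eight cells include all six planted
cells (entry-level Jaccard 0.75 at this small search budget); its score
3.11 decomposes into a mean rate-correlation of e^−0.234 ≈ 0.79, a mean
min-p of e^−0.775 ≈ 0.46, 31 expressed entries (e^3.43), no overlap
penalty, and clears the random-candidate quantile Q₁ = 2.59.

`autoplot(res)`, `plot_gene_correlation(ctx, res, 1)` and
`plot_cell_similarity(ctx, res, 1)` draw the membership and per-bicluster
heatmaps; `run_simulate()`, `run_fit()`, `run_search()` and `run_report()`
are file-based pipeline wrappers, also exposed as a command line
(`inst/cli/treebic.R`, subcommands `simulate | fit | search | report`).

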