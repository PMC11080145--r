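---
title: "Methods: biclustering tree-shaped expression time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biclustering tree-shaped expression time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The data and the problem

4D confocal imaging of *C. elegans* embryos yields, for each labelled gene
in each individual, a fluorescence intensity series per cell along the
invariant cell lineage: a binary tree in which each cell lives for some
minutes and then divides into two daughters named in Sulston nomenclature
(`Ea` and `Ep` are the daughters of `E`). Samples are taken every 1.5
minutes, but homologous cells live for different durations in different
individuals, so series from different *copies* (one gene measured in one
individual) are non-pairwise: they cannot be compared point by point.

`treebic` looks for **biclusters** in the copies-by-cells matrix of such
series: subsets of genes that share coherent expression dynamics within a
subset of cells, allowing overlap between biclusters.

## Step 1: C¹-constrained piecewise polynomial fitting

Within each founder lineage (`AB`, `MS`, `E`, `C`, `D`) and each copy, every
observed cell's series is fitted with its own polynomial, with equality of
value *and* first derivative imposed at every division point where both
parent and child were observed. The result is an expression function F that
is continuously differentiable along the lineage, and its derivative F′,
the expression *rate* function. Rates rather than levels are compared
across genes because fluorescent reporters resist degradation: levels
accumulate monotonically, and correlating two accumulating series produces
spuriously high coefficients regardless of regulation.

Numerical choices:

* **Basis.** Each cell uses a centered, lifetime-scaled monomial basis
  `u = (t - center)/halfspan`, keeping the design well conditioned for any
  lifetime.
* **Degree rule.** Series shorter than 10 points get a cubic; from 10
  points the degree grows by one immediately and by one more per `n_extra`
  additional points, capped at 8 and at `points - 1`. `n_extra` is chosen
  per subtree from {5, 10, 15, 20} by the Gaussian-error BIC
  `T log(RSS/T) + p log(T)`, where `p` counts free parameters after the
  constraints (two removed per active division constraint); ties go to the
  smallest candidate.
* **Solver.** The equality-constrained least squares problem is solved by
  null-space reparameterization (SVD of the constraint matrix, then QR on
  the projected design). A rank-deficient constrained design triggers a
  degree-by-one degrade and retry; failure is only declared at degree 1.
* **Intervals.** Lifetimes are half-open `[t_start, t_end)`: the division
  point carries the continuity constraint but belongs to the next sample
  of the daughters.
* Cells with a single sample carry no usable dynamics and are excluded
  from the fit; divisions with a missing side impose no constraint.

The per-subtree coefficient of determination R² is reported for every fit.
When the underlying truth is itself a C¹ piecewise cubic, the fit
reproduces it to numerical precision (this is a test invariant); on smooth
non-polynomial truth the fit is an approximation, and short cells are
fitted least well.

## Step 2: the four-term objective

A candidate bicluster B = (G, C) with at least 2 rows and 2 columns is
scored as

    f(B) = alpha * log( mean over gene pairs and cells of Corr )
         + lambda * log( mean over cell pairs of min-over-genes KS p )
         + beta * log( number of expressed entries )
         - delta * log( 1 + overlap count with earlier biclusters )

* **Gene correlation.** For each unordered gene pair and each cell of the
  bicluster, the Pearson correlation between the two rate functions, each
  sampled at 50 equally spaced points after mapping the cell's lifetime to
  the unit interval (translation and scaling make non-pairwise series
  comparable). Entries where a series is missing, or where a rate vector
  has zero variance, are excluded and the mean is taken over defined
  entries only.
* **Cell similarity.** Expression increments (first differences of the raw
  series) are compared between cells with the two-sample
  Kolmogorov–Smirnov test; for each cell pair the *minimum* p-value over
  the bicluster's copies is taken (one discordant gene is enough to make
  two cells dissimilar), then averaged over cell pairs. Pairs with no
  shared observed copy are excluded from the average.
* **Expression size.** The count of entries flagged expressed in the
  binary onset matrix Y, rewarding large, well-supported biclusters.
* **Overlap penalty.** The number of (copy, cell) entries already covered
  by previously accepted biclusters, counted with multiplicity. The term
  is `log(1 + count)` so that the first search and any overlap-free
  candidate score exactly 0; a bare `log(count)` would send every
  overlap-free candidate to `-Inf` reward.

Logs of non-positive quantities (negative mean correlation, zero expressed
entries) are mapped to a `-Inf` sentinel: such candidates are infeasible
and can never be selected, which preserves argmax semantics without
arbitrary clamping. Default weights are `alpha = 0.55`, `lambda = 0.25`,
`beta = 1` (fixed, for identifiability between the weights) and
`delta = 0.065`.

**KS p-values.** The default mode evaluates the Kolmogorov limiting
distribution at `sqrt(nm/(n+m)) D`, using two complementary series
expansions for numerical stability in both tails. An exact small-sample
mode (permutation distribution via `stats::psmirnov`) is also available;
at sample sizes around 4 the asymptotic p can deviate from the exact one
by up to about 0.2, which is tolerable here because p-values act as a
similarity score, not as a test decision.

**Grouped mode.** Real datasets carry several copies per gene. In grouped
mode all copies of a gene enter or leave a bicluster together: the
correlation between two genes is the average over cross-gene copy pairs,
cell similarity takes the minimum p over all member copies, and size and
overlap count all member copies. With one copy per gene this reduces
exactly to the ungrouped objective (a test invariant).

## Step 3: genetic-algorithm search

Biclusters are extracted sequentially. For the k-th bicluster:

1. **Stopping quantile.** 100 random candidates are drawn (as below) and
   scored with the current overlap penalty; `Q_k` is their 99% empirical
   quantile (linear interpolation, type-7; `-Inf` scores participate as
   order statistics).
2. **Initialization.** Each of `num` candidates samples `n_r` genes
   uniformly, then `n_c` cells from the cells with at least one expressed
   entry among those genes (all cells if fewer qualify) — sampling genes
   first biases initial candidates toward large expression size.
3. **Generations.** For `max_i` generations: random disjoint pairs
   exchange a uniform number of indices on one axis (crossover, rate 0.8);
   candidates gain or lose one uniformly chosen index on one axis
   (mutation, rate 0.3, refusing removals that would violate the 2×2
   minimum); every new candidate is pruned (below); survivors compete in
   elitist (mu+lambda) truncation back to `num` by score.
4. **Acceptance.** The best candidate is accepted only if its score
   strictly exceeds `Q_k`; otherwise it is discarded and the search stops.

**Pruning.** After crossover and mutation, the row or column with the
smallest expressed proportion is removed, repeatedly, until every row and
column is at or above the threshold 0.6 (ties: smallest proportion, then
rows before columns, then lowest index). Candidates pruned below 2×2 are
discarded. Pruning is idempotent and its fixed point is what enters the
population, so every returned bicluster satisfies the threshold.

Design choices made where the procedure was genuinely open:

* **Selection.** Elitist (mu+lambda) truncation guarantees the best score
  is non-decreasing over generations. Duplicate candidates are collapsed
  at truncation: without this, copies of the incumbent flood the
  population, starving crossover of distinct variants to recombine; with
  it, one-step variants persist long enough for their improvements to be
  combined.
* **Crossover exchange set.** Only indices *not shared* by the two
  candidates are exchanged: swapping shared members is vacuous under set
  semantics, and this makes crossover between identical candidates a
  no-op while conserving the pair's index union and both candidates'
  sizes.
* **Mutation step.** One index per candidate per generation; with the
  crossover pairing this keeps per-generation moves local so the elitist
  selection can evaluate them incrementally. Both parents and crossover
  offspring are exposed to mutation.
* **Rates.** Crossover 0.8, mutation 0.3 by default; both configurable.
* **Stopping sample.** `Q_k` is re-drawn for every k so the random
  reference includes the current overlap penalty.
* **Budget.** Exactly `max_i` generations, no early-convergence exit. A
  `max_biclusters` safety cap (default 20) bounds the sequential loop on
  data where the quantile rule is slow to trigger; an accepted-score
  trajectory approaching `Q_k` indicates exhausted signal.
* Ties everywhere break toward the lowest canonical index, and a single
  seeded generator drives all sampling, so a fixed seed reproduces the
  whole search byte for byte.

## Preprocessing conventions

* Copies, then cells, with more than 60% missing entries are removed —
  proportions are computed on the original matrix for copies and
  recomputed on the reduced matrix for cells ("strictly greater than"
  reading of the threshold; computing gene proportions first makes the
  two-pass filter deterministic).
* The binary onset matrix Y is ideally supplied from a dedicated onset
  detector. The built-in stand-in flags a present series as expressed when
  its maximum intensity reaches a cutoff; it is a placeholder, not a
  reconstruction of any published detector, and `Y` can always be given
  explicitly (`build_binary_matrix(ds, Y = ...)`). Y is 0 on missing
  entries always.
* Rows and columns are kept in a canonical lexicographic order; all index
  sets refer to that order.

## The synthetic-data generator

`simulate_lineage_dataset()` emulates the structural features the method
depends on: a binary lineage topology grown from the five founder roots;
per-individual cell lifetimes (12–30 min, multiples of the 1.5-min
sampling interval) so time grids are non-pairwise across copies; smooth
trajectories that are exact integrals of positive rate functions (sums of
2–3 Gaussian bumps, integrated in closed form via `pnorm`) and continuous
across divisions; Gaussian measurement noise (s.d. 0.1 by default, about
a tenth of a typical increment); 10% missing series; and a ground-truth
onset matrix (expressed = within-cell rise of at least 1).

A *planted bicluster* ties a gene subset to a cell subset through one
shared latent rate shape: inside the planted cells every planted gene's
rate is a positive per-gene multiple (loadings 0.7–1.3) of the latent
shape, so pairwise rate correlations are 1 by construction and increment
distributions are matched across planted cells. Background entries are
independently active (own random rate shape, amplitude 0.5–1.5, about
half of entries) or quiescent, so background correlations scatter around
zero and background cell pairs get small KS p-values.

What the generator does **not** emulate: fluorescence point-spread and
bleaching, expression onset dynamics, lineage-correlated background
expression, or real *C. elegans* lifetimes. Passing the recovery tests
therefore shows the search finds planted structure under realistic noise,
missingness and non-pairwise sampling — not that the method's biological
conclusions on real embryos are correct.

One structural note: planted rates are exactly proportional at the level
of the *true* rate functions. The fitted rates inherit some distortion
from the C¹ constraint, because a planted cell's polynomial is coupled to
its (background) parent, which differs across copies; planted
correlations measured on fits are therefore high but not 1. This mirrors
the method's behaviour on real data, where truth is never in the model
space.

## Problem sizes and runtime

The default study configuration (30 copies × ~61 cells, population 100,
1000 generations) mirrors the scale the method is designed for. The test
suite and the acceptance script run a reduced but structurally identical
setting — 30 copies × ~61 cells with a planted 10 × 15 bicluster,
population 50, 200 generations, 10 seeds — chosen so the full recovery
experiment completes in minutes on one core while leaving the search
dynamics (initialization bias, pruning, elitism, quantile stopping)
untouched.

## Known limitations

* The quantile stopping rule compares an optimized score against a
  quantile of *random* candidates; on small dense synthetic data the
  optimizer almost always clears it, so the `max_biclusters` cap, or the
  declining margin `score - Q_k`, is the practical stopping signal there.
* Short-lived cells are fitted with few points and dominate the fitting
  error.
* The onset stand-in is intensity-based only.
* The GA is stochastic; only fixed-seed runs are exactly reproducible.
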