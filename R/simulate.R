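#' Specification of a planted bicluster
#'
#' A planted bicluster ties a subset of genes to a subset of cells through
#' one shared latent rate function: within the planted cells, every planted
#' gene's expression rate is a positive multiple (the gene loading) of the
#' latent rate, so pairwise rate correlations are positive by construction
#' and increment distributions are matched across the planted cells.
#'
#' @param n_genes,n_cells Planted dimensions (>= 2 each), used when explicit
#'   sets are not given.
#' @param genes Optional character vector of gene ids to plant.
#' @param cells Optional character vector of cell names to plant.
#' @param loading_range Range of the positive per-gene loadings.
#' @return List of class `planted_bicluster`.
#' @export
planted_bicluster <- function(n_genes = 10L, n_cells = 15L, genes = NULL,
                              cells = NULL, loading_range = c(0.7, 1.3)) {
  stopifnot(n_genes >= 2, n_cells >= 2, loading_range[1] > 0,
            diff(loading_range) >= 0)
  structure(list(n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
                 genes = genes, cells = cells,
                 loading_range = loading_range),
            class = "planted_bicluster")
}

#' Simulation configuration
#'
#' Conditions of the synthetic tree-shaped datasets: binary lineage trees
#' grown from the founder roots, per-cell lifetimes drawn per individual
#' (so time grids are non-pairwise between copies), smooth per-cell
#' trajectories continuous across divisions, masked (missing) cells and
#' optional planted biclusters.
#'
#' @param n_genes Number of genes (default 30).
#' @param copies_per_gene Reporter copies per gene (default 1).
#' @param n_cells Target number of cells; random leaf splits are added until
#'   the count reaches it (with 5 roots the realized count can exceed the
#'   target by one).
#' @param roots Founder names.
#' @param lifetime_range Cell lifetime range in minutes; realized lifetimes
#'   are multiples of `interval`.
#' @param interval Sampling interval in minutes (default 1.5).
#' @param noise_sd Gaussian measurement noise s.d. on intensities.
#' @param missing_rate Probability that a (copy, cell) series is masked.
#' @param background_active_prob Probability that a background (copy, cell)
#'   entry is transcriptionally active (otherwise flat).
#' @param background_amp_range Amplitude range of active background rates.
#' @param expression_cutoff Minimum within-cell expression rise for the
#'   ground-truth onset label `y = 1` (default 1).
#' @param nondecreasing Keep trajectories non-decreasing (fluorescent
#'   reporters resist degradation); if `FALSE`, background rates may change
#'   sign.
#' @param planted List of [planted_bicluster()] specs.
#' @param seed Integer seed; everything downstream is deterministic.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genes = 30L, copies_per_gene = 1L, n_cells = 60L,
                       roots = lineage_roots(), lifetime_range = c(12, 30),
                       interval = 1.5, noise_sd = 0.1, missing_rate = 0.1,
                       background_active_prob = 0.5,
                       background_amp_range = c(0.5, 1.5),
                       expression_cutoff = 1, nondecreasing = TRUE,
                       planted = list(), seed = 1L) {
  stopifnot(interval > 0, missing_rate >= 0, missing_rate < 1,
            lifetime_range[1] >= 2 * interval, noise_sd >= 0,
            n_genes >= 1, copies_per_gene >= 1,
            n_cells >= length(roots))
  if (inherits(planted, "planted_bicluster")) planted <- list(planted)
  structure(list(
    n_genes = as.integer(n_genes),
    copies_per_gene = as.integer(copies_per_gene),
    n_cells = as.integer(n_cells), roots = roots,
    lifetime_range = lifetime_range, interval = interval,
    noise_sd = noise_sd, missing_rate = missing_rate,
    background_active_prob = background_active_prob,
    background_amp_range = background_amp_range,
    expression_cutoff = expression_cutoff,
    nondecreasing = nondecreasing, planted = planted,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Smooth positive rate shapes: 2-3 Gaussian bumps on the unit interval.
# rate(u) = sum_i a_i exp(-(u - mu_i)^2 / (2 s_i^2)); the antiderivative is
# available in closed form via pnorm, so trajectories are exact integrals.
random_bumps <- function(n_bumps = sample(2:3, 1L)) {
  list(a = stats::runif(n_bumps, 0.5, 1.5),
       mu = stats::runif(n_bumps, 0.1, 0.9),
       s = stats::runif(n_bumps, 0.1, 0.3))
}

bump_rate <- function(bumps, u) {
  out <- rep(0, length(u))
  for (i in seq_along(bumps$a)) {
    out <- out + bumps$a[i] * exp(-(u - bumps$mu[i])^2 / (2 * bumps$s[i]^2))
  }
  out
}

# integral of bump_rate over [0, u] in u-space
bump_integral <- function(bumps, u) {
  out <- rep(0, length(u))
  for (i in seq_along(bumps$a)) {
    out <- out + bumps$a[i] * bumps$s[i] * sqrt(2 * pi) *
      (stats::pnorm((u - bumps$mu[i]) / bumps$s[i]) -
         stats::pnorm((0 - bumps$mu[i]) / bumps$s[i]))
  }
  out
}

grow_topology <- function(roots, n_cells) {
  cells <- roots
  leaves <- roots
  while (length(cells) < n_cells) {
    leaf <- leaves[sample.int(length(leaves), 1L)]
    kids <- paste0(leaf, c("a", "p"))
    cells <- c(cells, kids)
    leaves <- c(setdiff(leaves, leaf), kids)
  }
  sort(cells)
}

#' Simulate a tree-shaped expression dataset with known ground truth
#'
#' Generates a binary lineage topology, then for every copy (an individual
#' embryo) draws its own per-cell lifetimes and samples each cell's
#' trajectory on the fixed interval grid, half-open at the division point.
#' Trajectories are exact integrals of smooth positive rate functions and
#' are continuous across divisions. Planted (gene, cell) entries share a
#' latent rate up to a positive per-gene loading; background entries are
#' independently active (own random rate) or quiescent (flat). Gaussian
#' noise is added and series are masked at `missing_rate`.
#'
#' @param config A [sim_config()].
#' @return A `series_dataset` with the ground-truth onset matrix attached as
#'   `$Y` and an attribute `"truth"`: list with `Y`, `planted` (per spec:
#'   `genes`, `copies`, `cells`) and the `config`.
#' @export
simulate_lineage_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  iv <- config$interval

  cells <- grow_topology(config$roots, config$n_cells)
  tree <- build_lineage_tree(cells, config$roots)
  # parents before children
  cell_order <- cells[order(nchar(cells), cells)]
  parent <- stats::setNames(tree$parent[match(cell_order, tree$cell)],
                            cell_order)

  genes <- sprintf("g%02d", seq_len(config$n_genes))
  copies <- tibble(
    gene = rep(genes, each = config$copies_per_gene),
    copy = paste0(rep(genes, each = config$copies_per_gene), "_c",
                  sprintf("%02d", seq_len(config$copies_per_gene)))
  )

  # planted membership and latent shapes
  planted <- lapply(config$planted, function(pb) {
    ng <- if (is.null(pb$genes)) pb$n_genes else length(pb$genes)
    nc <- if (is.null(pb$cells)) pb$n_cells else length(pb$cells)
    if (ng > length(genes) || nc > length(cells)) {
      abort("Planted bicluster exceeds dataset dimensions.",
            class = "treebic_sim_error")
    }
    pg <- pb$genes %||% sort(resample(genes, pb$n_genes))
    pc <- pb$cells %||% sort(resample(cells, pb$n_cells))
    loading <- stats::setNames(
      stats::runif(length(pg), pb$loading_range[1], pb$loading_range[2]), pg)
    list(genes = pg, cells = pc, loading = loading,
         latent = random_bumps())
  })
  planted_of <- function(g, cl) {
    for (p in planted) if (g %in% p$genes && cl %in% p$cells) return(p)
    NULL
  }

  lo <- ceiling(config$lifetime_range[1] / iv)
  hi <- floor(config$lifetime_range[2] / iv)

  rows <- vector("list", nrow(copies))
  truthY <- matrix(0L, nrow(copies), length(cells),
                   dimnames = list(copies$copy, cells))
  for (ci in seq_len(nrow(copies))) {
    cp <- copies$copy[ci]; g <- copies$gene[ci]
    L <- iv * sample(lo:hi, length(cell_order), replace = TRUE)
    names(L) <- cell_order
    t0 <- numeric(length(cell_order)); names(t0) <- cell_order
    v_end <- numeric(length(cell_order)); names(v_end) <- cell_order
    masked <- stats::runif(length(cell_order)) < config$missing_rate
    names(masked) <- cell_order
    cp_rows <- vector("list", length(cell_order))
    for (j in seq_along(cell_order)) {
      cl <- cell_order[j]
      pa <- parent[[cl]]
      t0[cl] <- if (is.na(pa)) 0 else t0[pa] + L[pa]
      v0 <- if (is.na(pa)) 0 else v_end[pa]
      npts <- round(L[cl] / iv)
      tt <- t0[cl] + iv * (0:(npts - 1L))
      u <- (tt - t0[cl]) / L[cl]
      p <- planted_of(g, cl)
      if (!is.null(p)) {
        scale <- p$loading[[g]]
        cum <- scale * L[cl] * bump_integral(p$latent, u)
        rise <- scale * L[cl] * bump_integral(p$latent, 1)
      } else if (stats::runif(1) < config$background_active_prob) {
        amp <- stats::runif(1, config$background_amp_range[1],
                            config$background_amp_range[2])
        if (!config$nondecreasing && stats::runif(1) < 0.5) amp <- -amp
        own <- random_bumps()
        cum <- amp * L[cl] * bump_integral(own, u)
        rise <- amp * L[cl] * bump_integral(own, 1)
      } else {
        cum <- rep(0, npts)
        rise <- 0
      }
      v_end[cl] <- v0 + rise
      truth <- v0 + cum
      if (!masked[cl]) {
        truthY[cp, cl] <- as.integer(abs(rise) >= config$expression_cutoff)
        cp_rows[[j]] <- tibble(
          gene = g, copy = cp, cell = cl, time_min = tt,
          value = truth + stats::rnorm(npts, sd = config$noise_sd)
        )
      }
    }
    rows[[ci]] <- bind_rows(cp_rows)
  }

  ds <- series_dataset(bind_rows(rows), roots = config$roots,
                       default_spacing = iv)
  truthY <- truthY[ds$copies$copy, ds$cells, drop = FALSE]
  ds <- build_binary_matrix(ds, Y = truthY)
  attr(ds, "truth") <- list(
    Y = truthY,
    planted = lapply(planted, function(p) list(
      genes = p$genes,
      copies = copies$copy[copies$gene %in% p$genes],
      cells = p$cells,
      loading = p$loading,
      latent = p$latent
    )),
    config = config
  )
  ds
}

#' Jaccard index between two biclusters on matrix entries
#'
#' Compares the (row, column) entry sets of two biclusters: the
#' intersection has one entry per shared row and shared column.
#'
#' @param genes1,cells1 First bicluster's row/column label or index sets.
#' @param genes2,cells2 Second bicluster's sets (same labelling).
#' @return Jaccard index in `[0, 1]`.
#' @export
bicluster_jaccard <- function(genes1, cells1, genes2, cells2) {
  inter <- length(intersect(genes1, genes2)) *
    length(intersect(cells1, cells2))
  uni <- length(genes1) * length(cells1) +
    length(genes2) * length(cells2) - inter
  if (uni == 0) return(0)
  inter / uni
}
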