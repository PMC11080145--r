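# Shared fixtures, all generated in code.

# Small deterministic dataset for I/O and preprocessing tests.
tiny_sim <- function(seed = 1, ...) {
  simulate_lineage_dataset(sim_config(
    n_genes = 6, n_cells = 10, seed = seed, noise_sd = 0.05,
    missing_rate = 0.1, ...
  ))
}

# A lineage subtree whose true expression function is a C1 piecewise cubic:
# the root cell gets a random cubic, each child matches value and first
# derivative at the division point and adds random quadratic/cubic terms.
# Cell lengths are kept under 10 points so the degree rule stays cubic and
# the truth lies exactly in the model space.
make_c1_cubic_subtree <- function(seed, root = "E", depth = 2,
                                  noise_sd = 0) {
  set.seed(seed)
  cells <- root
  for (d in seq_len(depth)) {
    leaves <- cells[nchar(cells) == nchar(root) + d - 1L]
    cells <- c(cells, paste0(rep(leaves, each = 2), c("a", "p")))
  }
  cells <- sort(cells)
  tree <- build_lineage_tree(cells, roots = root)
  npts <- stats::setNames(sample(4:9, length(cells), replace = TRUE), cells)
  ord <- cells[order(nchar(cells), cells)]
  t0 <- c(); t1 <- c(); coef_t <- list()   # truth coeffs in (t - t_start)
  series <- list()
  for (cl in ord) {
    pa <- tree$parent[match(cl, tree$cell)]
    t0[cl] <- if (is.na(pa) || !(pa %in% names(t1))) 0 else t1[[pa]]
    t1[cl] <- t0[[cl]] + 1.5 * npts[[cl]]
    if (is.na(pa) || !(pa %in% names(coef_t))) {
      v0 <- stats::runif(1, -1, 1); d0 <- stats::runif(1, -0.5, 0.5)
    } else {
      pc <- coef_t[[pa]]
      dt <- t1[[pa]] - t0[[pa]]
      v0 <- pc[1] + pc[2] * dt + pc[3] * dt^2 + pc[4] * dt^3
      d0 <- pc[2] + 2 * pc[3] * dt + 3 * pc[4] * dt^2
    }
    coef_t[[cl]] <- c(v0, d0, stats::runif(1, -0.05, 0.05),
                      stats::runif(1, -0.01, 0.01))
    tt <- t0[[cl]] + 1.5 * (0:(npts[[cl]] - 1L))
    s <- tt - t0[[cl]]
    vals <- coef_t[[cl]][1] + coef_t[[cl]][2] * s +
      coef_t[[cl]][3] * s^2 + coef_t[[cl]][4] * s^3
    if (noise_sd > 0) vals <- vals + stats::rnorm(length(vals), sd = noise_sd)
    series[[cl]] <- list(times = tt, values = vals,
                         t_start = t0[[cl]], t_end = t1[[cl]])
  }
  truth_at <- function(cl, tt) {
    cf <- coef_t[[cl]]; s <- tt - t0[[cl]]
    cf[1] + cf[2] * s + cf[3] * s^2 + cf[4] * s^3
  }
  list(series = series, tree = tree, truth_at = truth_at,
       t0 = t0, t1 = t1)
}

# Independent evaluation of the four-term objective, straight from the raw
# dataset, the fitted subtrees and explicit loops (no context tensors).
oracle_objective <- function(ds, fits, genes, cells, weights,
                             previous = list(), grid_points = 50) {
  copies <- ds$copies$copy
  rate_of <- function(m, n) {
    cp <- copies[m]; cl <- ds$cells[n]
    row <- fits$subtrees[fits$subtrees$copy == cp, ]
    for (i in seq_len(nrow(row))) {
      f <- row$fit[[i]]
      if (cl %in% f$cells$cell) {
        return(sample_rate_on_unit_interval(f, cl, grid_points))
      }
    }
    NULL
  }
  inc_of <- function(m, n) {
    v <- ds$series$value[ds$series$copy == copies[m] &
                           ds$series$cell == ds$cells[n]]
    if (length(v) >= 3) diff(v) else NULL
  }
  # gene correlation: average over gene pairs and cells of Pearson r
  tot <- 0; cnt <- 0
  for (a in seq_along(genes)) {
    for (b in seq_along(genes)) {
      if (b <= a) next
      for (n in cells) {
        v1 <- rate_of(genes[a], n); v2 <- rate_of(genes[b], n)
        if (is.null(v1) || is.null(v2)) next
        r <- suppressWarnings(stats::cor(v1, v2))
        if (!is.na(r)) { tot <- tot + r; cnt <- cnt + 1 }
      }
    }
  }
  corr <- if (cnt == 0 || tot / cnt <= 0) -Inf else log(tot / cnt)
  # cell similarity: per cell pair, min over copies of the KS p-value
  tot <- 0; cnt <- 0
  for (a in seq_along(cells)) {
    for (b in seq_along(cells)) {
      if (b <= a) next
      ps <- c()
      for (m in genes) {
        i1 <- inc_of(m, cells[a]); i2 <- inc_of(m, cells[b])
        if (is.null(i1) || is.null(i2)) next
        ps <- c(ps, ks_pvalue(i1, i2))
      }
      if (length(ps)) { tot <- tot + min(ps); cnt <- cnt + 1 }
    }
  }
  sim <- if (cnt == 0 || tot / cnt <= 0) -Inf else log(tot / cnt)
  es <- 0
  for (m in genes) for (n in cells) es <- es + ds$Y[m, n]
  size <- if (es == 0) -Inf else log(es)
  ov <- 0
  for (B in previous) {
    for (m in genes) for (n in cells) {
      if (m %in% B$genes && n %in% B$cells) ov <- ov + 1
    }
  }
  overlap <- log(1 + ov)
  score <- if (any(c(corr, sim, size) == -Inf)) -Inf else {
    weights$alpha * corr + weights$lambda * sim +
      weights$beta * size - weights$delta * overlap
  }
  list(score = score,
       terms = c(correlation = corr, similarity = sim, size = size,
                 overlap = overlap))
}

# access to member copies without relying on the internal helper
member_copies_test <- function(ctx, genes) {
  unlist(ctx$unit_copies[genes], use.names = FALSE)
}
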