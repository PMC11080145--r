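# Shared small context for operator tests.
ga_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- simulate_lineage_dataset(sim_config(
        n_genes = 10, n_cells = 16, seed = 13, noise_sd = 0.05,
        missing_rate = 0.1, planted = planted_bicluster(4, 6)
      ))
      fits <- fit_dataset(ds)
      cache <<- list(ds = ds, ctx = bicluster_context(ds, fits))
    }
    cache
  }
})

test_that("pruning reaches a fixed point and is idempotent on random masks", {
  fx <- ga_fixture()
  ctx <- fx$ctx
  set.seed(21)
  for (r in 1:200) {
    ctx$Y[] <- rbinom(length(ctx$Y), 1, runif(1, 0.3, 0.9))
    g <- sort(sample(length(ctx$units), 8))
    cl <- sort(sample(length(ctx$cells), 8))
    pr <- prune_low_expression(g, cl, ctx, 0.6)
    if (is.null(pr)) next
    sub <- ctx$Y[pr$genes, pr$cells, drop = FALSE]
    expect_gte(min(rowMeans(sub)), 0.6)
    expect_gte(min(colMeans(sub)), 0.6)
    pr2 <- prune_low_expression(pr$genes, pr$cells, ctx, 0.6)
    expect_identical(pr2, pr)
  }
})

test_that("pruning removes exactly the single sub-threshold row", {
  fx <- ga_fixture()
  ctx <- fx$ctx
  ctx$Y[] <- 1L
  g <- 1:4; cl <- 1:6
  expect_identical(prune_low_expression(g, cl, ctx, 0.6),
                   list(genes = g, cells = cl))
  ctx$Y[2, 1:3] <- 0L   # row 2 at proportion 0.5 within cl
  pr <- prune_low_expression(g, cl, ctx, 0.6)
  expect_identical(pr, list(genes = c(1L, 3L, 4L), cells = 1:6))
})

test_that("initial candidates avoid expression-free columns", {
  fx <- ga_fixture()
  ctx <- fx$ctx
  # zero out some columns entirely
  dead <- c(2L, 5L, 9L)
  ctx$Y[, dead] <- 0L
  cfg <- search_config(num = 20, n_r = 4, n_c = 5)
  set.seed(31)
  for (r in 1:20) {
    pop <- initialize_population(ctx, cfg, n = 5)
    for (cand in pop) {
      expect_true(!any(cand$cells %in% dead))
      sub <- ctx$Y[member_copies_test(ctx, cand$genes), cand$cells,
                   drop = FALSE]
      expect_gte(min(rowMeans(sub)), cfg$prune_threshold)
      expect_gte(min(colMeans(sub)), cfg$prune_threshold)
    }
  }
})

test_that("crossover conserves the union and isolates axes", {
  fx <- ga_fixture()
  ctx <- fx$ctx
  ctx$Y[] <- 1L   # fully expressed: pruning never fires, isolating the swap
  cfg <- search_config(num = 20, n_r = 4, n_c = 5, crossover_rate = 1,
                       prune_threshold = 0.01)
  set.seed(41)
  for (r in 1:20) {
    pop <- initialize_population(ctx, cfg, n = 2)
    if (length(pop) < 2) next
    off <- crossover(pop, ctx, cfg)
    if (length(off) < 2) next
    pg <- sort(unique(c(pop[[1]]$genes, pop[[2]]$genes)))
    og <- sort(unique(c(off[[1]]$genes, off[[2]]$genes)))
    pc <- sort(unique(c(pop[[1]]$cells, pop[[2]]$cells)))
    oc <- sort(unique(c(off[[1]]$cells, off[[2]]$cells)))
    expect_identical(og, pg)
    expect_identical(oc, pc)
    # exactly one axis changed per pair
    gene_same <- identical(off[[1]]$genes, pop[[1]]$genes) ||
      identical(off[[1]]$genes, pop[[2]]$genes)
    cell_same <- identical(off[[1]]$cells, pop[[1]]$cells) ||
      identical(off[[1]]$cells, pop[[2]]$cells)
    expect_true(gene_same || cell_same)
  }
})

test_that("crossover of identical candidates is a no-op", {
  fx <- ga_fixture()
  ctx <- fx$ctx
  ctx$Y[] <- 1L
  cfg <- search_config(num = 10, n_r = 4, n_c = 5, crossover_rate = 1,
                       prune_threshold = 0.01)
  set.seed(43)
  pop <- initialize_population(ctx, cfg, n = 1)
  twin <- list(pop[[1]], pop[[1]])
  off <- crossover(twin, ctx, cfg)
  for (o in off) expect_identical(o, pop[[1]])
})

test_that("mutation changes at most one index per candidate and respects 2x2", {
  fx <- ga_fixture()
  ctx <- fx$ctx
  ctx$Y[] <- 1L   # fully expressed: pruning never fires, isolating the move
  cfg <- search_config(num = 10, n_r = 4, n_c = 5, mutation_rate = 1,
                       prune_threshold = 0.01)
  set.seed(51)
  for (r in 1:30) {
    pop <- initialize_population(ctx, cfg, n = 3)
    mut <- mutate_population(pop, ctx, cfg)
    # with near-zero pruning, sizes change by at most 1 on one axis
    for (i in seq_along(mut)) {
      dg <- length(setdiff(mut[[i]]$genes, pop[[i]]$genes)) +
        length(setdiff(pop[[i]]$genes, mut[[i]]$genes))
      dc <- length(setdiff(mut[[i]]$cells, pop[[i]]$cells)) +
        length(setdiff(pop[[i]]$cells, mut[[i]]$cells))
      expect_lte(dg + dc, 1)
      expect_gte(length(mut[[i]]$genes), 2)
      expect_gte(length(mut[[i]]$cells), 2)
    }
  }
  # 2x2 candidates never shrink
  two <- list(list(genes = 1:2, cells = 1:2))
  for (r in 1:20) {
    mut <- mutate_population(two, ctx, cfg)
    expect_gte(length(mut[[1]]$genes), 2)
    expect_gte(length(mut[[1]]$cells), 2)
  }
  # candidate spanning all genes: add-gene is a no-op
  full <- list(list(genes = seq_along(ctx$units), cells = 1:4))
  for (r in 1:20) {
    mut <- mutate_population(full, ctx, cfg)
    expect_lte(length(mut[[1]]$genes), length(ctx$units))
  }
})

test_that("stopping quantile matches a direct sort-based recomputation", {
  fx <- ga_fixture()
  cfg <- search_config(num = 20, n_r = 4, n_c = 5, stop_samples = 50)
  w <- objective_weights()
  set.seed(61)
  qk <- stopping_quantile(fx$ctx, list(), cfg, w)
  sc <- attr(qk, "scores")
  expect_length(sc, 50)
  s <- sort(sc)
  h <- (50 - 1) * 0.99
  lo <- floor(h)
  expect_equal(as.numeric(qk),
               (1 - (h - lo)) * s[lo + 1] + (h - lo) * s[lo + 2])
  # degenerate case: all scores equal
  expect_equal(treebic:::empirical_quantile(rep(3.2, 10), 0.99), 3.2)
  # -Inf participates as an order statistic
  expect_identical(treebic:::empirical_quantile(rep(-Inf, 10), 0.99), -Inf)
  expect_identical(treebic:::empirical_quantile(c(rep(-Inf, 9), 1), 0.5),
                   -Inf)
})

test_that("best population score is non-decreasing and search is deterministic", {
  fx <- ga_fixture()
  cfg <- search_config(num = 20, max_i = 30, n_r = 4, n_c = 6,
                       max_biclusters = 2, seed = 71)
  res1 <- search_biclusters(fx$ctx, cfg)
  res2 <- search_biclusters(fx$ctx, cfg)
  expect_identical(res1, res2)
  h <- attr(res1, "history")
  for (k in unique(h$k)) {
    expect_true(all(diff(h$best[h$k == k]) >= 0))
  }
  # every returned bicluster satisfies 2x2, the prune fixed point, and
  # strictly exceeds its stopping quantile
  for (i in seq_len(nrow(res1))) {
    expect_gte(res1$n_genes[i], 2)
    expect_gte(res1$n_cells[i], 2)
    expect_gt(res1$score[i], res1$q_k[i])
    pr <- prune_low_expression(res1$genes[[i]], res1$cells[[i]], fx$ctx,
                               cfg$prune_threshold)
    expect_identical(pr, list(genes = res1$genes[[i]],
                              cells = res1$cells[[i]]))
  }
})

test_that("an expression-free dataset yields zero biclusters", {
  fx <- ga_fixture()
  ctx <- fx$ctx
  ctx$Y[] <- 0L
  res <- search_biclusters(ctx, search_config(num = 10, max_i = 5,
                                              n_r = 3, n_c = 4, seed = 1))
  expect_equal(nrow(res), 0)
})

test_that("grouped search moves whole gene groups", {
  ds <- simulate_lineage_dataset(sim_config(
    n_genes = 5, copies_per_gene = 3, n_cells = 12, seed = 17,
    noise_sd = 0.05, missing_rate = 0.05,
    planted = planted_bicluster(2, 6)
  ))
  fits <- fit_dataset(ds)
  ctxg <- bicluster_context(ds, fits, grouped = TRUE)
  expect_equal(length(ctxg$units), 5)
  expect_true(all(lengths(ctxg$unit_copies) == 3))
  cfg <- search_config(num = 15, max_i = 25, n_r = 3, n_c = 5,
                       max_biclusters = 1, seed = 3)
  res <- search_biclusters(ctxg, cfg)
  if (nrow(res)) {
    # gene labels are gene ids; member copies come in blocks of 3
    expect_true(all(res$gene_labels[[1]] %in% unique(ds$copies$gene)))
    rows <- unlist(ctxg$unit_copies[res$genes[[1]]])
    expect_equal(length(rows), 3 * res$n_genes[1])
  }
  # mutation adding a gene group grows the copy set by exactly 3
  set.seed(5)
  cand <- list(list(genes = 1:2, cells = 1:5))
  cfgm <- search_config(num = 10, n_r = 3, n_c = 5, mutation_rate = 1,
                        prune_threshold = 0.01)
  for (r in 1:20) {
    mut <- mutate_population(cand, ctxg, cfgm)
    gained <- setdiff(mut[[1]]$genes, cand[[1]]$genes)
    if (length(gained)) {
      expect_equal(length(unlist(ctxg$unit_copies[mut[[1]]$genes])),
                   3 * length(mut[[1]]$genes))
    }
  }
})

test_that("grouped search with singleton groups follows the ungrouped trajectory", {
  ds <- simulate_lineage_dataset(sim_config(
    n_genes = 8, n_cells = 12, seed = 19, noise_sd = 0.05,
    missing_rate = 0.1, planted = planted_bicluster(3, 5)
  ))
  fits <- fit_dataset(ds)
  ctx <- bicluster_context(ds, fits)
  ctxg <- bicluster_context(ds, fits, grouped = TRUE)
  cfg <- search_config(num = 12, max_i = 15, n_r = 3, n_c = 5,
                       max_biclusters = 2, seed = 23)
  r1 <- search_biclusters(ctx, cfg)
  r2 <- search_biclusters(ctxg, cfg)
  expect_equal(nrow(r1), nrow(r2))
  expect_equal(r1$score, r2$score, tolerance = 1e-12)
  for (i in seq_len(nrow(r1))) {
    expect_equal(sort(match(r1$gene_labels[[i]], ds$copies$copy)),
                 sort(unname(unlist(ctxg$unit_copies[r2$genes[[i]]]))))
    expect_identical(r1$cell_labels[[i]], r2$cell_labels[[i]])
  }
})
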