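#' Search configuration
#'
#' Hyperparameters of the genetic-algorithm bicluster search. Defaults are
#' the study settings: 1000 generations per bicluster, population 100, 10
#' genes and 15 cells sampled at initialization, pruning threshold 0.6 and
#' a 99% stopping quantile over 100 random candidates.
#'
#' @param max_i Generations per bicluster.
#' @param num Population size.
#' @param n_r Rows (genes) sampled when initializing a candidate.
#' @param n_c Cells sampled when initializing a candidate.
#' @param prune_threshold Minimum expressed proportion per bicluster row and
#'   column; lower rows/columns are iteratively removed.
#' @param stop_quantile Quantile of random-candidate scores that an accepted
#'   bicluster must strictly exceed.
#' @param stop_samples Number of random candidates used for the quantile.
#' @param crossover_rate Probability that a candidate pair exchanges indices.
#' @param mutation_rate Probability that a candidate gains or loses an index.
#' @param max_biclusters Safety cap on the number of accepted biclusters.
#' @param seed Optional integer seed; the whole search is deterministic
#'   given the seed.
#' @return List of class `search_config`.
#' @export
search_config <- function(max_i = 1000L, num = 100L, n_r = 10L, n_c = 15L,
                          prune_threshold = 0.6, stop_quantile = 0.99,
                          stop_samples = 100L, crossover_rate = 0.8,
                          mutation_rate = 0.3, max_biclusters = 20L,
                          seed = NULL) {
  stopifnot(num >= 2, n_r >= 2, n_c >= 2,
            prune_threshold > 0, prune_threshold < 1,
            stop_quantile > 0, stop_quantile < 1, stop_samples >= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1, max_i >= 1)
  structure(list(
    max_i = as.integer(max_i), num = as.integer(num),
    n_r = as.integer(n_r), n_c = as.integer(n_c),
    prune_threshold = prune_threshold, stop_quantile = stop_quantile,
    stop_samples = as.integer(stop_samples),
    crossover_rate = crossover_rate, mutation_rate = mutation_rate,
    max_biclusters = as.integer(max_biclusters), seed = seed
  ), class = "search_config")
}

# sample() without the scalar-x surprise
resample <- function(x, size = length(x)) x[sample.int(length(x), size)]

#' Prune low-expression rows and columns from a candidate
#'
#' Iteratively removes the single row or column with the smallest expressed
#' proportion within the candidate submatrix until every row and column is
#' at or above `threshold`. Ties are broken by smallest proportion, then
#' rows before columns, then lowest index. Returns `NULL` (rejection) if
#' the fixed point has fewer than 2 rows or 2 columns. In grouped contexts
#' a row is a gene group and its proportion is computed over all member
#' copies.
#'
#' @param genes,cells Integer index sets (row axis units / cells).
#' @param ctx A [bicluster_context()].
#' @param threshold Minimum expressed proportion (default 0.6).
#' @return List `(genes, cells)` or `NULL`.
#' @export
prune_low_expression <- function(genes, cells, ctx, threshold = 0.6) {
  genes <- sort(unique(as.integer(genes)))
  cells <- sort(unique(as.integer(cells)))
  Y <- ctx$Y
  repeat {
    if (length(genes) < 2L || length(cells) < 2L) return(NULL)
    rowprop <- vapply(genes, function(g)
      mean(Y[ctx$unit_copies[[g]], cells]), numeric(1))
    colprop <- colMeans(Y[member_copies(ctx, genes), cells, drop = FALSE])
    mr <- min(rowprop); mc <- min(colprop)
    if (min(mr, mc) >= threshold) break
    if (mr <= mc) {
      genes <- genes[-which.min(rowprop)]
    } else {
      cells <- cells[-which.min(colprop)]
    }
  }
  list(genes = genes, cells = cells)
}

#' Initialize a population of candidate biclusters
#'
#' Each candidate samples `n_r` rows uniformly without replacement, then
#' `n_c` cells uniformly from the cells with at least one expressed entry
#' among the chosen rows (falling back to all cells when fewer than `n_c`
#' qualify); sampling genes first biases initial candidates toward large
#' expression size. Every candidate is pruned before entering the
#' population; candidates pruned away are re-drawn (up to 100 attempts).
#'
#' @param ctx A [bicluster_context()].
#' @param config A [search_config()].
#' @param n Number of candidates (default `config$num`).
#' @return List of candidates, each a list `(genes, cells)`.
#' @export
initialize_population <- function(ctx, config = search_config(),
                                  n = config$num) {
  U <- length(ctx$units); N <- length(ctx$cells)
  if (U < 2L || N < 2L) {
    abort("Dataset smaller than 2x2 after filtering.",
          class = "treebic_data_error")
  }
  n_r <- min(config$n_r, U)
  pop <- vector("list", n)
  kept <- 0L
  for (i in seq_len(n)) {
    cand <- NULL
    for (try in 1:100) {
      genes <- sort(sample.int(U, n_r))
      rows <- member_copies(ctx, genes)
      elig <- which(colSums(ctx$Y[rows, , drop = FALSE]) > 0L)
      if (length(elig) < config$n_c) elig <- seq_len(N)
      cells <- sort(resample(elig, min(config$n_c, length(elig))))
      cand <- prune_low_expression(genes, cells, ctx,
                                   config$prune_threshold)
      if (!is.null(cand)) break
    }
    if (!is.null(cand)) {
      kept <- kept + 1L
      pop[[kept]] <- cand
    }
  }
  pop[seq_len(kept)]
}

#' Crossover: exchange indices within random candidate pairs
#'
#' Candidates are paired at random (disjoint pairs); with probability
#' `crossover_rate` a pair picks one axis (genes or cells, equal
#' probability) and swaps a uniform number (1 to the smaller axis size) of
#' uniformly chosen indices between the two candidates, with set semantics.
#' Offspring are pruned; offspring below 2x2 are discarded.
#'
#' @param pop List of candidates.
#' @param ctx A [bicluster_context()].
#' @param config A [search_config()].
#' @return List of offspring (possibly empty).
#' @export
crossover <- function(pop, ctx, config = search_config()) {
  npop <- length(pop)
  if (npop < 2L) return(list())
  perm <- sample.int(npop)
  off <- list()
  for (p in seq_len(npop %/% 2L)) {
    if (stats::runif(1) > config$crossover_rate) next
    a <- pop[[perm[2L * p - 1L]]]
    b <- pop[[perm[2L * p]]]
    axis <- if (stats::runif(1) < 0.5) "genes" else "cells"
    k <- sample.int(min(length(a[[axis]]), length(b[[axis]])), 1L)
    # exchange only non-shared indices: swapping members both candidates
    # already hold is vacuous under set semantics, and equal sets make the
    # whole operation a no-op
    only_a <- setdiff(a[[axis]], b[[axis]])
    only_b <- setdiff(b[[axis]], a[[axis]])
    k <- min(k, length(only_a), length(only_b))
    a2 <- a; b2 <- b
    if (k > 0L) {
      sa <- resample(only_a, k)
      sb <- resample(only_b, k)
      a2[[axis]] <- sort(c(setdiff(a[[axis]], sa), sb))
      b2[[axis]] <- sort(c(setdiff(b[[axis]], sb), sa))
    }
    for (child in list(a2, b2)) {
      pr <- prune_low_expression(child$genes, child$cells, ctx,
                                 config$prune_threshold)
      if (!is.null(pr)) off[[length(off) + 1L]] <- pr
    }
  }
  off
}

#' Mutation: add or remove one index per candidate
#'
#' With probability `mutation_rate`, a candidate either adds one uniformly
#' sampled outside index or removes one uniformly sampled member, on a
#' randomly chosen axis. Removals that would drop an axis below 2 are
#' refused. Mutants are pruned; mutants pruned below 2x2 are discarded.
#'
#' @inheritParams crossover
#' @return List of candidates after mutation.
#' @export
mutate_population <- function(pop, ctx, config = search_config()) {
  U <- length(ctx$units); N <- length(ctx$cells)
  out <- list()
  for (cand in pop) {
    if (stats::runif(1) < config$mutation_rate) {
      axis <- if (stats::runif(1) < 0.5) "genes" else "cells"
      add <- stats::runif(1) < 0.5
      tot <- if (axis == "genes") U else N
      if (add) {
        outside <- setdiff(seq_len(tot), cand[[axis]])
        if (length(outside)) {
          cand[[axis]] <- sort(c(cand[[axis]], resample(outside, 1L)))
        }
      } else if (length(cand[[axis]]) > 2L) {
        cand[[axis]] <- cand[[axis]][-sample.int(length(cand[[axis]]), 1L)]
      }
      cand <- prune_low_expression(cand$genes, cand$cells, ctx,
                                   config$prune_threshold)
    }
    if (!is.null(cand)) out[[length(out) + 1L]] <- cand
  }
  out
}

score_candidates <- function(pop, ctx, weights, O) {
  vapply(pop, function(cand) {
    B <- structure(list(genes = cand$genes, cells = cand$cells),
                   class = "bicluster")
    terms <- c(gene_correlation_term(B, ctx),
               cell_similarity_term(B, ctx),
               expression_size_term(B, ctx))
    if (any(terms == -Inf)) return(-Inf)
    weights$alpha * terms[1] + weights$lambda * terms[2] +
      weights$beta * terms[3] -
      weights$delta * overlap_penalty_term(B, ctx, O)
  }, numeric(1))
}

# Linear-interpolation empirical quantile (type 7), -Inf-safe.
empirical_quantile <- function(x, q) {
  s <- sort(x)
  h <- (length(s) - 1) * q
  lo <- floor(h); g <- h - lo
  if (g == 0) return(s[lo + 1])
  if (s[lo + 1] == s[lo + 2]) return(s[lo + 1])
  (1 - g) * s[lo + 1] + g * s[lo + 2]
}

#' Stopping quantile for the k-th search
#'
#' Draws `stop_samples` random candidates (as in
#' [initialize_population()]), scores them with the full objective
#' (including the overlap penalty against previously accepted biclusters)
#' and returns the `stop_quantile` empirical quantile (linear
#' interpolation). Infeasible candidates participate as `-Inf`.
#'
#' @param ctx A [bicluster_context()].
#' @param previous List of previously accepted biclusters.
#' @param config A [search_config()].
#' @param weights An [objective_weights()].
#' @return The quantile `Q_k`, with the sampled scores as attribute
#'   `"scores"`.
#' @export
stopping_quantile <- function(ctx, previous = list(),
                              config = search_config(),
                              weights = objective_weights()) {
  O <- overlap_count_matrix(previous, ctx)
  samp <- initialize_population(ctx, config, n = config$stop_samples)
  if (!length(samp)) {
    return(structure(-Inf, scores = numeric(0)))
  }
  sc <- score_candidates(samp, ctx, weights, O)
  if (length(sc) < config$stop_samples) {
    # candidates that could not be initialized are infeasible
    sc <- c(sc, rep(-Inf, config$stop_samples - length(sc)))
  }
  structure(empirical_quantile(sc, config$stop_quantile), scores = sc)
}

#' Genetic-algorithm bicluster search
#'
#' Sequentially detects biclusters maximizing the four-term objective. For
#' each k: compute the stopping quantile `Q_k` from random candidates;
#' initialize a population; run `max_i` generations of crossover, mutation
#' and elitist (mu+lambda) truncation back to `num`; take the best
#' candidate. If its score does not strictly exceed `Q_k`, it is discarded
#' and the search stops; otherwise it is accepted and the search continues
#' for k+1 with the overlap penalty updated. With a grouped context the
#' row axis moves whole gene groups (grouped search).
#'
#' @param ctx A [bicluster_context()].
#' @param config A [search_config()] (set `seed` for reproducibility).
#' @param weights An [objective_weights()].
#' @return A `bicluster_set`: tibble with one row per accepted bicluster
#'   (`k`, sizes, `score`, per-term breakdown, `q_k`, and list-columns of
#'   member indices and labels). Attributes: `history` (per-generation best
#'   and median score), `config`, `weights`, `context_info`. Zero rows is a
#'   legal outcome.
#' @export
search_biclusters <- function(ctx, config = search_config(),
                              weights = objective_weights()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  accepted <- list()
  hist_rows <- list()
  repeat {
    k <- length(accepted) + 1L
    O <- overlap_count_matrix(accepted, ctx)
    qk <- stopping_quantile(ctx, accepted, config, weights)
    pop <- initialize_population(ctx, config)
    if (length(pop) < 2L) break
    scores <- score_candidates(pop, ctx, weights, O)
    for (gen in seq_len(config$max_i)) {
      off <- crossover(pop, ctx, config)
      off <- c(mutate_population(off, ctx, config),
               mutate_population(pop, ctx, config))
      if (length(off)) {
        osc <- score_candidates(off, ctx, weights, O)
        pop <- c(pop, off)
        scores <- c(scores, osc)
      }
      # elitist (mu + lambda) truncation; duplicate candidates collapse so
      # the population keeps distinct variants for crossover to combine
      keep <- order(-scores)
      key <- vapply(pop[keep], function(b)
        paste(paste(b$genes, collapse = ","),
              paste(b$cells, collapse = ","), sep = ";"), character(1))
      keep <- keep[!duplicated(key)]
      keep <- utils::head(keep, config$num)
      pop <- pop[keep]
      scores <- scores[keep]
      hist_rows[[length(hist_rows) + 1L]] <- c(
        k = k, generation = gen, best = max(scores),
        median = stats::median(scores)
      )
    }
    best_i <- which.max(scores)
    if (!is.finite(scores[best_i]) || scores[best_i] <= qk) break
    best <- pop[[best_i]]
    B <- structure(best, class = "bicluster")
    br <- objective(B, ctx, weights, O)
    accepted[[k]] <- c(best, list(score = br$score, terms = br$terms,
                                  q_k = as.numeric(qk)))
    if (k >= config$max_biclusters) break
  }

  res <- if (length(accepted)) {
    tibble(
      k = seq_along(accepted),
      n_genes = vapply(accepted, function(b) length(b$genes), integer(1)),
      n_cells = vapply(accepted, function(b) length(b$cells), integer(1)),
      score = vapply(accepted, function(b) b$score, numeric(1)),
      correlation = vapply(accepted, function(b)
        b$terms[["correlation"]], numeric(1)),
      similarity = vapply(accepted, function(b)
        b$terms[["similarity"]], numeric(1)),
      size = vapply(accepted, function(b) b$terms[["size"]], numeric(1)),
      overlap = vapply(accepted, function(b)
        b$terms[["overlap"]], numeric(1)),
      q_k = vapply(accepted, function(b) b$q_k, numeric(1)),
      genes = lapply(accepted, function(b) b$genes),
      cells = lapply(accepted, function(b) b$cells),
      gene_labels = lapply(accepted, function(b) ctx$units[b$genes]),
      cell_labels = lapply(accepted, function(b) ctx$cells[b$cells])
    )
  } else {
    tibble(
      k = integer(), n_genes = integer(), n_cells = integer(),
      score = numeric(), correlation = numeric(), similarity = numeric(),
      size = numeric(), overlap = numeric(), q_k = numeric(),
      genes = list(), cells = list(), gene_labels = list(),
      cell_labels = list()
    )
  }
  history <- if (length(hist_rows)) {
    as_tibble(do.call(rbind, hist_rows))
  } else {
    tibble(k = numeric(), generation = numeric(), best = numeric(),
           median = numeric())
  }
  structure(res, history = history, config = config, weights = weights,
            context_info = list(grouped = ctx$grouped,
                                n_units = length(ctx$units),
                                n_cells = length(ctx$cells)),
            class = c("bicluster_set", class(res)))
}

#' @export
print.bicluster_set <- function(x, ...) {
  cat("<bicluster_set> ", nrow(x), " bicluster(s)\n", sep = "")
  NextMethod()
}

#' @rdname search_biclusters
#' @param x A `bicluster_set`.
#' @param ... Unused.
#' @export
tidy.bicluster_set <- function(x, ...) {
  out <- as_tibble(x)[, c("k", "n_genes", "n_cells", "score",
                          "correlation", "similarity", "size", "overlap",
                          "q_k")]
  out
}

#' @rdname search_biclusters
#' @export
glance.bicluster_set <- function(x, ...) {
  tibble(
    n_biclusters = nrow(x),
    best_score = if (nrow(x)) max(x$score) else NA_real_,
    total_entries = if (nrow(x)) sum(x$n_genes * x$n_cells) else 0L
  )
}
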