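#' Objective weights
#'
#' Tuning weights of the four-term bicluster objective
#' `score = alpha * correlation + lambda * similarity + beta * size -
#' delta * overlap`. `beta` is fixed to 1 by default to avoid
#' identifiability issues between the weights.
#'
#' @param alpha Weight of the gene-correlation term (default 0.55).
#' @param lambda Weight of the cell-similarity term (default 0.25).
#' @param beta Weight of the expression-size term (default 1).
#' @param delta Weight of the overlap penalty (default 0.065).
#' @return List of class `objective_weights`.
#' @export
objective_weights <- function(alpha = 0.55, lambda = 0.25, beta = 1,
                              delta = 0.065) {
  stopifnot(alpha >= 0, lambda >= 0, beta >= 0, delta >= 0)
  structure(list(alpha = alpha, lambda = lambda, beta = beta,
                 delta = delta), class = "objective_weights")
}

#' Precompute the scoring context for bicluster search
#'
#' The objective only ever needs three summaries of the data, all of which
#' are computed once here: (i) per-cell Pearson correlations between the
#' unit-interval-sampled rate functions of every pair of rows, (ii) the KS
#' p-value between the expression-increment distributions of every pair of
#' cells under every copy, and (iii) the binary expression matrix. With
#' `grouped = TRUE` the row axis is gene groups rather than individual
#' copies: all copies of a gene move together, the gene-pair correlation is
#' the average over cross-gene copy pairs, and cell similarity takes the
#' minimum p-value over all member copies.
#'
#' @param ds A `series_dataset` with `$Y` (see [build_binary_matrix()]).
#' @param fits A `tree_fit` from [fit_dataset()].
#' @param grouped Operate on gene groups instead of copies.
#' @param grid_points Samples per rate function (default from fit config).
#' @param ks_method `"asymptotic"` or `"exact"` (see [ks_pvalue()]).
#' @return List of class `bicluster_context` with unit labels, tensors
#'   `corr` (units x units x cells), `ks` (copies x cells x cells), and `Y`.
#' @export
bicluster_context <- function(ds, fits, grouped = FALSE,
                              grid_points = fits$config$grid_points,
                              ks_method = c("asymptotic", "exact")) {
  ks_method <- match.arg(ks_method)
  if (is.null(ds$Y)) {
    abort("Dataset has no binary matrix Y; call build_binary_matrix() first.",
          class = "treebic_data_error")
  }
  copies <- ds$copies$copy
  cells <- ds$cells
  M <- length(copies); N <- length(cells)

  rates <- rate_array(fits, grid_points)
  corr_copy <- array(NA_real_, c(M, M, N), dimnames = list(copies, copies, cells))
  for (n in seq_len(N)) {
    corr_copy[, , n] <- suppressWarnings(stats::cor(rates[, , n]))
  }

  # expression increments (rate data) per copy and cell, raw series
  sp <- series_split(ds)
  inc <- lapply(copies, function(cp) lapply(sp[[cp]], function(s)
    if (length(s$values) >= 3L) diff(s$values) else NULL))
  names(inc) <- copies

  ks <- array(NA_real_, c(M, N, N), dimnames = list(copies, cells, cells))
  for (m in seq_len(M)) {
    have <- which(cells %in% names(inc[[m]]))
    have <- have[!vapply(inc[[m]][cells[have]], is.null, logical(1))]
    if (length(have) < 1L) next
    for (cl in have) ks[m, cl, cl] <- 1
    if (length(have) < 2L) next
    for (a in seq_len(length(have) - 1L)) {
      for (b in (a + 1L):length(have)) {
        i <- have[a]; j <- have[b]
        p <- ks_pvalue(inc[[m]][[cells[i]]], inc[[m]][[cells[j]]],
                       method = ks_method)
        ks[m, i, j] <- p
        ks[m, j, i] <- p
      }
    }
  }

  if (grouped) {
    genes <- sort(unique(ds$copies$gene))
    unit_copies <- lapply(genes, function(g) which(ds$copies$gene == g))
    names(unit_copies) <- genes
    U <- length(genes)
    corr <- array(NA_real_, c(U, U, N), dimnames = list(genes, genes, cells))
    for (i in seq_len(U)) {
      corr[i, i, ] <- 1
      if (i == U) next
      for (j in (i + 1L):U) {
        sub <- corr_copy[unit_copies[[i]], unit_copies[[j]], , drop = FALSE]
        v <- apply(sub, 3, function(x) {
          mu <- mean(x, na.rm = TRUE)
          if (is.nan(mu)) NA_real_ else mu
        })
        corr[i, j, ] <- v
        corr[j, i, ] <- v
      }
    }
    units <- genes
  } else {
    units <- copies
    unit_copies <- as.list(seq_len(M))
    names(unit_copies) <- copies
    corr <- corr_copy
  }

  structure(list(
    units = units, unit_copies = unit_copies, copies = ds$copies,
    cells = cells, grouped = grouped, corr = corr, ks = ks, Y = ds$Y,
    grid_points = grid_points, ks_method = ks_method
  ), class = "bicluster_context")
}

#' @export
print.bicluster_context <- function(x, ...) {
  cat("<bicluster_context> ", length(x$units),
      if (x$grouped) " gene groups" else " copies", " x ",
      length(x$cells), " cells (KS: ", x$ks_method, ")\n", sep = "")
  invisible(x)
}

#' Construct a bicluster
#'
#' @param genes Integer indices on the row axis of the context (copies, or
#'   gene groups in grouped mode); at least 2, no duplicates.
#' @param cells Integer cell indices; at least 2, no duplicates.
#' @return List of class `bicluster` with sorted index sets.
#' @export
bicluster <- function(genes, cells) {
  genes <- sort(unique(as.integer(genes)))
  cells <- sort(unique(as.integer(cells)))
  if (length(genes) < 2L || length(cells) < 2L) {
    abort("A bicluster needs at least 2 rows and 2 columns.",
          class = "treebic_bicluster_error")
  }
  structure(list(genes = genes, cells = cells), class = "bicluster")
}

member_copies <- function(ctx, genes) {
  unlist(ctx$unit_copies[genes], use.names = FALSE)
}

log_or_neg_inf <- function(x) {
  if (!is.finite(x) || x <= 0) -Inf else log(x)
}

#' Gene-correlation term
#'
#' Log of the average, over unordered gene pairs and cells of the
#' bicluster, of the Pearson correlation between the two genes'
#' unit-interval rate functions in that cell. Undefined entries (missing
#' series, zero-variance rates) are excluded from the average; a
#' non-positive or empty average yields `-Inf` (infeasible candidate).
#'
#' @param B A [bicluster()].
#' @param ctx A [bicluster_context()].
#' @return Log mean correlation, or `-Inf`.
#' @export
gene_correlation_term <- function(B, ctx) {
  m <- length(B$genes); nc <- length(B$cells)
  sub <- ctx$corr[B$genes, B$genes, B$cells, drop = FALSE]
  ut <- upper.tri(matrix(0, m, m))
  vals <- sub[rep(c(ut), nc)]
  mu <- mean(vals, na.rm = TRUE)
  if (is.nan(mu)) return(-Inf)
  log_or_neg_inf(mu)
}

#' Cell-similarity term
#'
#' For each unordered cell pair, the minimum over the bicluster's copies of
#' the two-sample KS p-value between the cells' expression increments; the
#' term is the log of the average of those minima over cell pairs. Pairs
#' with no copy observed in both cells are excluded from the average.
#'
#' @inheritParams gene_correlation_term
#' @return Log mean of per-pair minimum p-values, or `-Inf`.
#' @export
cell_similarity_term <- function(B, ctx) {
  rows <- member_copies(ctx, B$genes)
  sub <- ctx$ks[rows, B$cells, B$cells, drop = FALSE]
  pm <- sub[1, , ]
  if (length(rows) > 1L) {
    for (i in 2:length(rows)) pm <- pmin(pm, sub[i, , ], na.rm = TRUE)
  }
  vals <- pm[upper.tri(pm)]
  mu <- mean(vals, na.rm = TRUE)
  if (is.nan(mu)) return(-Inf)
  log_or_neg_inf(mu)
}

#' Expression-size term
#'
#' Log of the number of expressed entries (`Y = 1`) inside the bicluster;
#' `-Inf` when none are expressed.
#'
#' @inheritParams gene_correlation_term
#' @return `log(ES)` or `-Inf`.
#' @export
expression_size_term <- function(B, ctx) {
  es <- sum(ctx$Y[member_copies(ctx, B$genes), B$cells])
  log_or_neg_inf(es)
}

#' Count matrix of previously accepted biclusters
#'
#' Entry (m, n) counts how many earlier biclusters contain copy m and cell
#' n; used by the overlap penalty.
#'
#' @param previous List of biclusters (each with `genes`, `cells` indices).
#' @param ctx A [bicluster_context()].
#' @return Integer copies x cells matrix.
#' @export
overlap_count_matrix <- function(previous, ctx) {
  O <- matrix(0L, nrow(ctx$copies), length(ctx$cells),
              dimnames = list(ctx$copies$copy, ctx$cells))
  for (B in previous) {
    O[member_copies(ctx, B$genes), B$cells] <-
      O[member_copies(ctx, B$genes), B$cells] + 1L
  }
  O
}

#' Overlap-penalty term
#'
#' Total number of (copy, cell) entries of the candidate already covered by
#' earlier biclusters (counted with multiplicity), on the log scale as
#' `log(1 + count)`, so the first search (no previous biclusters) and any
#' overlap-free candidate score exactly 0.
#'
#' @inheritParams gene_correlation_term
#' @param previous List of previously accepted biclusters, or an overlap
#'   count matrix from [overlap_count_matrix()].
#' @return `log(1 + overlap count)`.
#' @export
overlap_penalty_term <- function(B, ctx, previous = list()) {
  O <- if (is.matrix(previous)) previous else overlap_count_matrix(previous, ctx)
  log1p(sum(O[member_copies(ctx, B$genes), B$cells]))
}

#' Bicluster objective
#'
#' The weighted four-term score maximized by the search: gene correlation,
#' cell similarity, expression size, minus the overlap penalty. A `-Inf`
#' sentinel in any of the first three terms makes the whole score `-Inf`
#' (the candidate is infeasible). With a grouped context this is the
#' gene-grouped objective: with singleton copy groups it reduces exactly to
#' the ungrouped score.
#'
#' @inheritParams overlap_penalty_term
#' @param weights An [objective_weights()].
#' @return List with `score` and named `terms` (the unweighted term values).
#' @export
objective <- function(B, ctx, weights = objective_weights(),
                      previous = list()) {
  terms <- c(
    correlation = gene_correlation_term(B, ctx),
    similarity = cell_similarity_term(B, ctx),
    size = expression_size_term(B, ctx),
    overlap = overlap_penalty_term(B, ctx, previous)
  )
  score <- if (any(terms[1:3] == -Inf)) -Inf else {
    weights$alpha * terms[["correlation"]] +
      weights$lambda * terms[["similarity"]] +
      weights$beta * terms[["size"]] -
      weights$delta * terms[["overlap"]]
  }
  list(score = score, terms = terms)
}
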