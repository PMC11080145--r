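#' Gene-correlation matrix of one bicluster
#'
#' Recomputes, from the scoring context, the mean (over the bicluster's
#' cells) pairwise rate-function correlation between its genes; the matrix
#' is symmetric with unit diagonal.
#'
#' @param ctx A [bicluster_context()].
#' @param genes,cells Integer index sets of the bicluster.
#' @return Numeric matrix with unit labels as dimnames.
#' @export
bicluster_gene_correlation <- function(ctx, genes, cells) {
  sub <- ctx$corr[genes, genes, cells, drop = FALSE]
  m <- apply(sub, c(1, 2), function(v) {
    mu <- mean(v, na.rm = TRUE)
    if (is.nan(mu)) NA_real_ else mu
  })
  diag(m) <- 1
  m
}

#' Cell-similarity matrix of one bicluster
#'
#' Per cell pair, the minimum over the bicluster's copies of the KS p-value
#' between expression increments; symmetric, with unit diagonal (a cell is
#' maximally similar to itself).
#'
#' @inheritParams bicluster_gene_correlation
#' @return Numeric matrix with cell names as dimnames.
#' @export
bicluster_cell_similarity <- function(ctx, genes, cells) {
  rows <- member_copies(ctx, genes)
  sub <- ctx$ks[rows, cells, cells, drop = FALSE]
  pm <- sub[1, , ]
  if (length(rows) > 1L) {
    for (i in 2:length(rows)) pm <- pmin(pm, sub[i, , ], na.rm = TRUE)
  }
  diag(pm) <- 1
  pm
}

#' Cell-fate proportions of a bicluster
#'
#' @param cells Character vector of bicluster cell names.
#' @param fate Tibble with columns `cell`, `fate`. Bicluster cells missing
#'   from the table are counted as fate `"unknown"`; fate-table cells not
#'   in the dataset only trigger a warning upstream.
#' @return Tibble `fate`, `n` (bicluster cells with that fate), `n_total`
#'   (all cells with that fate in the table) and `prop`.
#' @export
fate_proportions <- function(cells, fate) {
  fate <- as_tibble(fate)
  f <- fate$fate[match(cells, fate$cell)]
  f[is.na(f)] <- "unknown"
  tot <- table(fate$fate)
  out <- as_tibble(table(fate = f), .name_repair = "minimal")
  names(out) <- c("fate", "n")
  out$n <- as.integer(out$n)
  out$n_total <- as.integer(tot[out$fate])
  out$prop <- out$n / length(cells)
  out
}

#' Write search results as JSON
#'
#' One record per bicluster: member labels, score, per-term breakdown and
#' the stopping quantile it beat.
#'
#' @param res A `bicluster_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_biclusters_json <- function(res, path) {
  recs <- lapply(seq_len(nrow(res)), function(i) list(
    k = res$k[i],
    genes = res$gene_labels[[i]],
    cells = res$cell_labels[[i]],
    score = res$score[i],
    terms = list(corr = res$correlation[i], sim = res$similarity[i],
                 size = res$size[i], overlap = res$overlap[i]),
    q_k = res$q_k[i]
  ))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Fit pipeline: filter, fit, export
#'
#' Runs the preprocessing and fitting steps on a series table and writes
#' the coefficient export plus an R^2 summary (mean, s.d. and the 25/50/75
#' and max percentiles) and the per-subtree R^2 values.
#'
#' @param input Path to a series-table CSV.
#' @param out_dir Output directory (created if needed).
#' @param config A [fit_config()].
#' @param max_missing Missingness threshold for [filter_missing()].
#' @return The `tree_fit`, invisibly.
#' @export
run_fit <- function(input, out_dir, config = fit_config(),
                    max_missing = 0.6) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- read_series_table(input)
  ds <- filter_missing(ds, max_missing)
  fits <- fit_dataset(ds, config)
  export_fits(fits, file.path(out_dir, "coefficients.csv"))
  readr::write_csv(glance(fits), file.path(out_dir, "r2_summary.csv"),
                   progress = FALSE)
  readr::write_csv(
    fits$subtrees[, c("copy", "subtree", "n_extra", "r_squared")],
    file.path(out_dir, "r2_values.csv"), progress = FALSE
  )
  invisible(fits)
}

#' Search pipeline: filter, fit, score, search, export
#'
#' Full end-to-end run on a series table: missingness filter, binary matrix
#' (ground-truth Y table if supplied, else the onset stand-in), subtree
#' fits, scoring context and GA search. Writes `biclusters.json`, a
#' per-bicluster membership TSV and a per-generation run log.
#'
#' @param input Path to a series-table CSV.
#' @param out_dir Output directory.
#' @param fit_cfg A [fit_config()].
#' @param search_cfg A [search_config()].
#' @param weights An [objective_weights()].
#' @param grouped Search over gene groups instead of copies.
#' @param y_table Optional path to a binary-matrix CSV.
#' @param onset_cutoff Cutoff for the default onset rule when `y_table` is
#'   not given.
#' @param max_missing Missingness threshold.
#' @return The `bicluster_set`, invisibly.
#' @export
run_search <- function(input, out_dir, fit_cfg = fit_config(),
                       search_cfg = search_config(),
                       weights = objective_weights(), grouped = FALSE,
                       y_table = NULL, onset_cutoff = 0,
                       max_missing = 0.6) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- read_series_table(input)
  ds <- filter_missing(ds, max_missing)
  Y <- if (!is.null(y_table)) read_binary_matrix(y_table) else NULL
  ds <- build_binary_matrix(ds, onset_cutoff = onset_cutoff, Y = Y)
  fits <- fit_dataset(ds, fit_cfg)
  ctx <- bicluster_context(ds, fits, grouped = grouped)
  res <- search_biclusters(ctx, search_cfg, weights)
  write_biclusters_json(res, file.path(out_dir, "biclusters.json"))
  memb <- if (nrow(res)) {
    bind_rows(lapply(seq_len(nrow(res)), function(i) tibble(
      k = res$k[i],
      axis = c(rep("gene", res$n_genes[i]), rep("cell", res$n_cells[i])),
      member = c(res$gene_labels[[i]], res$cell_labels[[i]])
    )))
  } else {
    tibble(k = integer(), axis = character(), member = character())
  }
  readr::write_tsv(memb, file.path(out_dir, "membership.tsv"),
                   progress = FALSE)
  readr::write_csv(attr(res, "history"), file.path(out_dir, "run_log.csv"),
                   progress = FALSE)
  invisible(res)
}

#' Report pipeline: per-bicluster matrices and fate table
#'
#' Recomputes, from stored membership and the scoring context, each
#' bicluster's gene-correlation matrix, cell-similarity matrix and (when a
#' fate table is given) cell-fate proportions.
#'
#' @param res A `bicluster_set`.
#' @param ctx The [bicluster_context()] used for the search.
#' @param fate Optional fate tibble (`cell`, `fate`); unknown cells in the
#'   table produce a warning, not an error.
#' @param out_dir Optional directory to write per-bicluster CSVs into.
#' @return Tibble with one row per bicluster and list-columns
#'   `gene_correlation`, `cell_similarity`, `fates`.
#' @export
run_report <- function(res, ctx, fate = NULL, out_dir = NULL) {
  if (!is.null(fate)) {
    unknown <- setdiff(fate$cell, ctx$cells)
    if (length(unknown)) {
      warn(paste0("Fate table contains unknown cells: ",
                  paste(utils::head(unknown, 5), collapse = ", ")))
    }
  }
  out <- tibble(
    k = res$k,
    gene_correlation = lapply(seq_len(nrow(res)), function(i)
      bicluster_gene_correlation(ctx, res$genes[[i]], res$cells[[i]])),
    cell_similarity = lapply(seq_len(nrow(res)), function(i)
      bicluster_cell_similarity(ctx, res$genes[[i]], res$cells[[i]])),
    fates = lapply(seq_len(nrow(res)), function(i)
      if (is.null(fate)) NULL
      else fate_proportions(res$cell_labels[[i]], fate))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(nrow(out))) {
      readr::write_csv(
        as_tibble(out$gene_correlation[[i]], rownames = "gene"),
        file.path(out_dir, sprintf("bicluster%02d_gene_correlation.csv",
                                   out$k[i])), progress = FALSE)
      readr::write_csv(
        as_tibble(out$cell_similarity[[i]], rownames = "cell"),
        file.path(out_dir, sprintf("bicluster%02d_cell_similarity.csv",
                                   out$k[i])), progress = FALSE)
      if (!is.null(out$fates[[i]])) {
        readr::write_csv(out$fates[[i]],
                         file.path(out_dir,
                                   sprintf("bicluster%02d_fates.csv",
                                           out$k[i])), progress = FALSE)
      }
    }
  }
  out
}

#' Simulation pipeline: generate and write a dataset
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory; writes `series.csv`, `Y.csv` and
#'   `truth.json`.
#' @return The `series_dataset`, invisibly.
#' @export
run_simulate <- function(config = sim_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulate_lineage_dataset(config)
  write_series_table(ds, file.path(out_dir, "series.csv"))
  write_binary_matrix(ds, file.path(out_dir, "Y.csv"))
  truth <- attr(ds, "truth")
  jsonlite::write_json(
    list(planted = truth$planted,
         n_copies = nrow(ds$copies), n_cells = length(ds$cells)),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  invisible(ds)
}

heat_df <- function(m) {
  tibble(
    row = rep(rownames(m), times = ncol(m)),
    col = rep(colnames(m), each = nrow(m)),
    value = as.vector(m)
  )
}

#' Heatmap of a bicluster's gene-correlation matrix
#' @param ctx A [bicluster_context()].
#' @param res A `bicluster_set`.
#' @param k Which bicluster.
#' @return A ggplot object.
#' @export
plot_gene_correlation <- function(ctx, res, k = 1) {
  i <- match(k, res$k)
  m <- bicluster_gene_correlation(ctx, res$genes[[i]], res$cells[[i]])
  ggplot2::ggplot(heat_df(m),
                  ggplot2::aes(x = .data$col, y = .data$row,
                               fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), name = "r") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0("Bicluster ", k, ": gene correlation")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Heatmap of a bicluster's cell-similarity matrix
#' @inheritParams plot_gene_correlation
#' @return A ggplot object.
#' @export
plot_cell_similarity <- function(ctx, res, k = 1) {
  i <- match(k, res$k)
  m <- bicluster_cell_similarity(ctx, res$genes[[i]], res$cells[[i]])
  ggplot2::ggplot(heat_df(m),
                  ggplot2::aes(x = .data$col, y = .data$row,
                               fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(limits = c(0, 1), low = "white",
                                 high = "steelblue", name = "KS p") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0("Bicluster ", k, ": cell similarity")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Fitted curves for one copy and subtree
#'
#' Observed points and the fitted C1 piecewise polynomial, one colour per
#' cell.
#'
#' @param ds The `series_dataset`.
#' @param fits The `tree_fit`.
#' @param copy Copy id.
#' @param subtree Founder name.
#' @return A ggplot object.
#' @export
plot_subtree_fit <- function(ds, fits, copy, subtree) {
  row <- fits$subtrees[fits$subtrees$copy == copy &
                         fits$subtrees$subtree == subtree, ]
  if (!nrow(row)) abort("No such fitted subtree.",
                        class = "treebic_data_error")
  f <- row$fit[[1]]
  pts <- ds$series[ds$series$copy == copy &
                     ds$series$cell %in% f$cells$cell, ]
  curves <- bind_rows(lapply(seq_len(nrow(f$cells)), function(i) {
    tt <- seq(f$cells$t_start[i], f$cells$t_end[i], length.out = 60)
    tibble(cell = f$cells$cell[i], time_min = tt,
           value = predict_subtree(f, f$cells$cell[i], tt))
  }))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$time_min, y = .data$value,
                                    colour = .data$cell)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(data = curves) +
    ggplot2::labs(x = "time (min)", y = "expression",
                  title = paste0(copy, " / ", subtree, " (R² = ",
                                 signif(row$r_squared, 3), ")")) +
    ggplot2::theme_minimal()
}

#' Membership heatmap of a bicluster set
#' @param object A `bicluster_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bicluster_set <- function(object, ...) {
  if (!nrow(object)) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "No biclusters"))
  }
  df <- bind_rows(lapply(seq_len(nrow(object)), function(i) tibble(
    k = factor(object$k[i]),
    gene = rep(object$gene_labels[[i]], times = object$n_cells[i]),
    cell = rep(object$cell_labels[[i]], each = object$n_genes[i])
  )))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell, y = .data$gene,
                                   fill = .data$k)) +
    ggplot2::geom_tile(alpha = 0.8) +
    ggplot2::labs(x = NULL, y = NULL, fill = "bicluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Histogram of per-subtree R^2
#' @param object A `tree_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tree_fit <- function(object, ...) {
  ggplot2::ggplot(object$subtrees,
                  ggplot2::aes(x = .data$r_squared)) +
    ggplot2::geom_histogram(bins = 20, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = expression(R^2), y = "subtrees") +
    ggplot2::theme_minimal()
}
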