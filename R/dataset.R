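#' Assemble a tree-shaped expression dataset from a long series table
#'
#' The central data container: per-copy, per-cell expression time series
#' measured along a cell-lineage tree. A *copy* is one fluorescent-reporter
#' measurement of a gene in one individual, so the same gene may contribute
#' several copies and homologous cells have different lifetimes across
#' copies (non-pairwise time grids). Rows and columns of all derived
#' matrices follow the canonical order: copies sorted lexicographically by
#' copy id, cells by name.
#'
#' @param series Tibble/data frame with columns `gene`, `copy`, `cell`,
#'   `time_min`, `value`; one row per observed time point. Missing
#'   (copy, cell) entries are simply absent.
#' @param roots Founder cell names (subtree roots).
#' @param fate Optional tibble with columns `cell`, `fate` (reporting only).
#' @param default_spacing Sampling interval in minutes, used to close the
#'   half-open interval of single-point series; measured series must be
#'   evenly spaced.
#' @return An object of class `series_dataset`: a list with elements
#'   `series` (canonical long tibble), `copies` (tibble `copy`, `gene`),
#'   `cells` (character), `tree` (a [build_lineage_tree()] tibble),
#'   `intervals` (per copy and cell: `t_start`, `t_end`, `spacing`,
#'   `n_points`), `present` (logical copies x cells matrix) and `Y`
#'   (binary expression matrix, `NULL` until [build_binary_matrix()]).
#' @export
series_dataset <- function(series, roots = lineage_roots(), fate = NULL,
                           default_spacing = 1.5) {
  series <- as_tibble(series)
  req <- c("gene", "copy", "cell", "time_min", "value")
  if (!all(req %in% names(series))) {
    abort(paste0("Series table must have columns ",
                 paste(req, collapse = ", ")),
          class = "treebic_parse_error")
  }
  series <- series |>
    mutate(
      gene = as.character(.data$gene),
      copy = as.character(.data$copy),
      cell = as.character(.data$cell)
    ) |>
    arrange(.data$copy, .data$cell, .data$time_min)
  if (nrow(series) > 0 && any(!is.finite(series$value))) {
    abort("Non-finite expression values in series table.",
          class = "treebic_parse_error")
  }
  validate_cell_names(series$cell, roots)

  copies <- series |>
    distinct(.data$copy, .data$gene) |>
    arrange(.data$copy)
  if (anyDuplicated(copies$copy)) {
    abort("A copy id maps to more than one gene.",
          class = "treebic_parse_error")
  }
  cells <- sort(unique(series$cell))
  tree <- build_lineage_tree(cells, roots)

  intervals <- series |>
    group_by(.data$copy, .data$cell) |>
    summarise(
      t_start = min(.data$time_min),
      t_max = max(.data$time_min),
      n_points = dplyr::n(),
      spacing = if (dplyr::n() > 1L) {
        d <- diff(.data$time_min)
        if (diff(range(d)) > 1e-9) NA_real_ else mean(d)
      } else NA_real_,
      .groups = "drop"
    )
  bad <- intervals$copy[is.na(intervals$spacing) & intervals$n_points > 1L]
  if (length(bad)) {
    bad_cell <- intervals$cell[is.na(intervals$spacing) & intervals$n_points > 1L]
    abort(paste0("Non-constant time spacing in series (copy ", bad[1],
                 ", cell ", bad_cell[1], ")."),
          class = "treebic_parse_error")
  }
  intervals$spacing[is.na(intervals$spacing)] <- default_spacing
  # half-open lifetime [t_start, t_end): last sample sits one interval
  # before the division point
  intervals$t_end <- intervals$t_max + intervals$spacing
  intervals <- intervals |> select(-"t_max")

  present <- matrix(FALSE, nrow(copies), length(cells),
                    dimnames = list(copies$copy, cells))
  present[cbind(match(intervals$copy, copies$copy),
                match(intervals$cell, cells))] <- TRUE

  out <- list(
    series = series, copies = copies, cells = cells, tree = tree,
    intervals = intervals, present = present, Y = NULL,
    fate = if (!is.null(fate)) as_tibble(fate) else NULL,
    roots = roots
  )
  class(out) <- "series_dataset"
  out
}

#' @export
print.series_dataset <- function(x, ...) {
  cat("<series_dataset> ", nrow(x$copies), " copies (",
      length(unique(x$copies$gene)), " genes) x ", length(x$cells),
      " cells; ", sum(x$present), " observed series; Y ",
      if (is.null(x$Y)) "absent" else "present", "\n", sep = "")
  invisible(x)
}

#' @export
dim.series_dataset <- function(x) c(nrow(x$copies), length(x$cells))

#' Nested list of per-copy, per-cell series
#'
#' @param ds A `series_dataset`.
#' @return List indexed by copy id; each element a list indexed by cell name
#'   with fields `times`, `values`, `t_start`, `t_end`. Missing cells absent.
#' @keywords internal
series_split <- function(ds) {
  iv <- ds$intervals
  key <- paste(ds$series$copy, ds$series$cell, sep = "\r")
  grp <- split(seq_len(nrow(ds$series)), key)
  out <- lapply(stats::setNames(ds$copies$copy, ds$copies$copy),
                function(cp) list())
  for (i in seq_len(nrow(iv))) {
    k <- paste(iv$copy[i], iv$cell[i], sep = "\r")
    idx <- grp[[k]]
    out[[iv$copy[i]]][[iv$cell[i]]] <- list(
      times = ds$series$time_min[idx],
      values = ds$series$value[idx],
      t_start = iv$t_start[i], t_end = iv$t_end[i]
    )
  }
  out
}

#' Read a long-format series table
#'
#' Expects a UTF-8 CSV (or TSV) with header `gene,copy,cell,time_min,value`;
#' missing (copy, cell) series are simply absent from the file.
#'
#' @param path File path.
#' @param roots Founder cell names.
#' @param fate Optional path to a two-column `cell,fate` CSV.
#' @return A [series_dataset()].
#' @export
read_series_table <- function(path, roots = lineage_roots(), fate = NULL) {
  if (!file.exists(path)) {
    abort(paste0("Input file not found: ", path), class = "treebic_io_error")
  }
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  # numeric columns come in as text and go through R's exact strtod, so a
  # write -> read cycle reproduces doubles bit for bit
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  tab$time_min <- as.numeric(tab$time_min)
  tab$value <- as.numeric(tab$value)
  fate_tab <- if (!is.null(fate)) {
    readr::read_csv(fate, show_col_types = FALSE, progress = FALSE)
  } else NULL
  series_dataset(tab, roots = roots, fate = fate_tab)
}

#' Write a dataset back to the long series-table format
#'
#' Inverse of [read_series_table()]: writing then reading reproduces the
#' dataset exactly (masked entries are absent from the output).
#'
#' @param ds A `series_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_series_table <- function(ds, path) {
  readr::write_csv(ds$series[, c("gene", "copy", "cell", "time_min", "value")],
                   path, progress = FALSE)
  invisible(path)
}

#' Subset a dataset to given copies and cells
#'
#' @param ds A `series_dataset`.
#' @param copies,cells Character vectors of copy ids / cell names to keep.
#' @return A new `series_dataset` (canonical order re-imposed); a supplied
#'   binary matrix `Y` is subset alongside.
#' @export
subset_dataset <- function(ds, copies = ds$copies$copy, cells = ds$cells) {
  keep <- ds$series$copy %in% copies & ds$series$cell %in% cells
  out <- series_dataset(ds$series[keep, ], roots = ds$roots, fate = ds$fate)
  if (!is.null(ds$Y)) {
    out$Y <- ds$Y[out$copies$copy, out$cells, drop = FALSE]
  }
  attr(out, "truth") <- attr(ds, "truth")
  out
}

#' Remove genes and cells with excessive missingness
#'
#' A (copy, cell) entry is missing when no series was observed for it.
#' Copies whose missing proportion strictly exceeds `max_missing` are
#' removed first; cell proportions are then recomputed on the reduced
#' matrix and cells exceeding the threshold are removed.
#'
#' @param ds A `series_dataset`.
#' @param max_missing Maximum tolerated missing proportion (default 0.6).
#' @return Filtered `series_dataset`.
#' @export
filter_missing <- function(ds, max_missing = 0.6) {
  stopifnot(max_missing > 0, max_missing < 1)
  miss <- !ds$present
  keep_copies <- ds$copies$copy[rowMeans(miss) <= max_missing]
  if (!length(keep_copies)) {
    abort("All copies exceed the missingness threshold.",
          class = "treebic_empty_error")
  }
  miss2 <- miss[keep_copies, , drop = FALSE]
  keep_cells <- ds$cells[colMeans(miss2) <= max_missing]
  if (!length(keep_cells)) {
    abort("All cells exceed the missingness threshold.",
          class = "treebic_empty_error")
  }
  subset_dataset(ds, keep_copies, keep_cells)
}

#' Attach the binary expression (onset) matrix Y
#'
#' `Y[m, n] = 1` marks gene copy `m` as expressed in cell `n`. By default a
#' simple onset rule is applied: a present series is expressed when its
#' maximum intensity reaches `onset_cutoff`. A pre-computed matrix (e.g.
#' from a dedicated onset detector) can be supplied instead and takes
#' precedence. Missing entries are always 0.
#'
#' @param ds A `series_dataset`.
#' @param onset_cutoff Intensity threshold for the default rule.
#' @param Y Optional user matrix (copies x cells, dimnames matching).
#' @return `ds` with `$Y` set.
#' @export
build_binary_matrix <- function(ds, onset_cutoff = 0, Y = NULL) {
  stopifnot(onset_cutoff >= 0)
  M <- nrow(ds$copies); N <- length(ds$cells)
  if (!is.null(Y)) {
    if (!all(dim(Y) == c(M, N))) {
      abort("Supplied Y does not match dataset dimensions.",
            class = "treebic_shape_error")
    }
    Y <- Y[ds$copies$copy, ds$cells, drop = FALSE]
    storage.mode(Y) <- "integer"
  } else {
    mx <- ds$series |>
      group_by(.data$copy, .data$cell) |>
      summarise(mx = max(.data$value), .groups = "drop")
    Y <- matrix(0L, M, N, dimnames = list(ds$copies$copy, ds$cells))
    Y[cbind(match(mx$copy, ds$copies$copy), match(mx$cell, ds$cells))] <-
      as.integer(mx$mx >= onset_cutoff)
  }
  Y[!ds$present] <- 0L
  ds$Y <- Y
  ds
}

#' Read a binary expression matrix from CSV
#'
#' Cells as columns, copies as rows (first column `copy`), entries 0/1.
#'
#' @param path CSV path.
#' @return Integer matrix with dimnames.
#' @export
read_binary_matrix <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  storage.mode(m) <- "integer"
  m
}

#' Write the binary expression matrix to CSV
#' @param ds A `series_dataset` with `$Y`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_binary_matrix <- function(ds, path) {
  stopifnot(!is.null(ds$Y))
  tab <- as_tibble(ds$Y, rownames = "copy")
  readr::write_csv(tab, path, progress = FALSE)
  invisible(path)
}

#' @rdname series_dataset
#' @param x A `series_dataset`.
#' @param ... Unused.
#' @export
tidy.series_dataset <- function(x, ...) {
  x$intervals |>
    left_join(x$copies, by = "copy") |>
    select("gene", "copy", "cell", "t_start", "t_end", "spacing", "n_points")
}
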