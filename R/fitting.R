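#' Fitting configuration
#'
#' Controls the piecewise-polynomial fit of expression trajectories along
#' each lineage subtree.
#'
#' @param base_degree Polynomial degree for short series (default 3).
#' @param min_points_for_growth Series length at which the degree starts
#'   growing (default 10).
#' @param n_extra_candidates Candidate values of the points-per-extra-degree
#'   parameter, chosen per subtree by BIC (default `c(5, 10, 15, 20)`).
#' @param max_degree Hard cap on the per-cell degree (default 8); degrees
#'   are additionally capped at `n_points - 1`.
#' @param grid_points Number of equally spaced evaluation points used when
#'   rate functions are rescaled to the unit interval (default 50).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(base_degree = 3L, min_points_for_growth = 10L,
                       n_extra_candidates = c(5L, 10L, 15L, 20L),
                       max_degree = 8L, grid_points = 50L) {
  stopifnot(base_degree >= 1, length(n_extra_candidates) >= 1,
            all(n_extra_candidates >= 1), max_degree >= base_degree,
            grid_points >= 2)
  structure(
    list(base_degree = as.integer(base_degree),
         min_points_for_growth = as.integer(min_points_for_growth),
         n_extra_candidates = sort(as.integer(n_extra_candidates)),
         max_degree = as.integer(max_degree),
         grid_points = as.integer(grid_points)),
    class = "fit_config"
  )
}

#' Polynomial degree for a series of given length
#'
#' Series shorter than `min_points_for_growth` points get the base (cubic)
#' degree; from that length on, the degree grows by one immediately and by
#' one more for every `n_extra` additional points, capped at `max_degree`
#' and at `num_points - 1`.
#'
#' @param num_points Number of time points in the series (>= 2).
#' @param n_extra Points required per extra degree (>= 1).
#' @param config A [fit_config()].
#' @return Integer degree.
#' @examples
#' select_degree(9, 5)   # 3
#' select_degree(10, 5)  # 4
#' @export
select_degree <- function(num_points, n_extra, config = fit_config()) {
  stopifnot(num_points >= 2, n_extra >= 1)
  d <- if (num_points < config$min_points_for_growth) {
    config$base_degree
  } else {
    config$base_degree + 1L +
      (num_points - config$min_points_for_growth) %/% as.integer(n_extra)
  }
  as.integer(max(1L, min(d, config$max_degree, as.integer(num_points) - 1L)))
}

# Horner evaluation; coefs ascending (c0 + c1*u + ...)
eval_poly <- function(coefs, u) {
  out <- rep(0, length(u))
  for (j in rev(seq_along(coefs))) out <- out * u + coefs[j]
  out
}

#' Coefficients of a polynomial derivative
#' @param coefs Ascending coefficients `c0..cd`.
#' @return Ascending coefficients of the derivative (length `d`, or `0`).
#' @export
poly_deriv <- function(coefs) {
  d <- length(coefs) - 1L
  if (d < 1L) return(0)
  coefs[-1] * seq_len(d)
}

#' First-order difference of a series
#'
#' Turns an expression series into expression *rate data*: the increments
#' between consecutive samples.
#'
#' @param values Numeric vector (length >= 2).
#' @return Numeric vector of length `length(values) - 1`.
#' @export
first_difference <- function(values) {
  if (length(values) < 2L) {
    abort("Series too short for first differences (need >= 2 points).",
          class = "treebic_data_error")
  }
  diff(values)
}

# Null space of a constraint matrix via SVD.
null_space <- function(C) {
  s <- svd(C, nu = 0, nv = ncol(C))
  tol <- max(dim(C)) * .Machine$double.eps * max(s$d, 0)
  rank <- sum(s$d > tol)
  if (rank >= ncol(C)) {
    matrix(0, ncol(C), 0)
  } else {
    s$v[, (rank + 1L):ncol(C), drop = FALSE]
  }
}

#' Fit a C1-constrained piecewise polynomial to one subtree
#'
#' Each observed cell in the subtree gets its own polynomial on a centered,
#' lifetime-scaled basis `u = (t - center) / halfspan`; at every division
#' point where both parent and child have data, equality of value and first
#' derivative is imposed, so the fitted expression function is continuously
#' differentiable along the lineage. The equality-constrained least-squares
#' problem is solved by null-space reparameterization. If the constrained
#' design is rank deficient, all degrees are reduced by one and the fit is
#' retried (error only once every degree is 1).
#'
#' @param cell_series Named list (cell name -> list with `times`, `values`,
#'   optionally `t_start`, `t_end`). Cells with fewer than 2 points are
#'   dropped from the fit.
#' @param tree A `lineage_tree` covering the cells.
#' @param config A [fit_config()].
#' @param n_extra Points-per-extra-degree used by [select_degree()].
#' @return A `subtree_fit`: list with `cells` (tibble of per-cell degree,
#'   basis and ascending coefficients `coefs`), `r_squared`, `rss`, `tss`,
#'   `n_points`, `n_params` (free parameters after constraints) and
#'   `constraints` (division points used).
#' @export
fit_subtree <- function(cell_series, tree, config = fit_config(),
                        n_extra = config$n_extra_candidates[1]) {
  cell_series <- cell_series[vapply(cell_series, function(s)
    length(s$values) >= 2L, logical(1))]
  if (!length(cell_series)) {
    abort("No usable series in subtree.", class = "treebic_data_error")
  }
  cells <- sort(names(cell_series))
  cell_series <- cell_series[cells]
  npts <- vapply(cell_series, function(s) length(s$times), integer(1))
  t0 <- vapply(cell_series, function(s)
    s$t_start %||% min(s$times), numeric(1))
  t1 <- vapply(cell_series, function(s)
    s$t_end %||% (max(s$times) + (if (length(s$times) > 1)
      mean(diff(s$times)) else 1.5)), numeric(1))
  ctr <- (t0 + t1) / 2
  hsp <- (t1 - t0) / 2
  degrees <- vapply(seq_along(cells), function(i)
    select_degree(npts[i], n_extra, config), integer(1))
  degrees <- pmin(degrees, npts - 1L)
  degrees <- pmax(degrees, 1L)

  parent <- stats::setNames(tree$parent[match(cells, tree$cell)], cells)
  cons_child <- cells[!is.na(parent[cells]) & parent[cells] %in% cells]

  y <- unlist(lapply(cell_series, function(s) s$values), use.names = FALSE)

  repeat {
    P <- sum(degrees + 1L)
    off <- c(0L, cumsum(degrees + 1L))[seq_along(cells)]
    names(off) <- cells
    A <- matrix(0, length(y), P)
    r0 <- 0L
    for (i in seq_along(cells)) {
      u <- (cell_series[[i]]$times - ctr[i]) / hsp[i]
      cols <- off[i] + seq_len(degrees[i] + 1L)
      A[r0 + seq_len(npts[i]), cols] <-
        outer(u, 0:degrees[i], `^`)
      r0 <- r0 + npts[i]
    }
    if (length(cons_child)) {
      C <- matrix(0, 2L * length(cons_child), P)
      for (j in seq_along(cons_child)) {
        ch <- cons_child[j]; pa <- parent[[ch]]
        tstar <- t0[ch]
        up <- (tstar - ctr[pa]) / hsp[pa]
        uc <- (tstar - ctr[ch]) / hsp[ch]
        dp <- degrees[match(pa, cells)]; dc <- degrees[match(ch, cells)]
        pc <- off[pa] + seq_len(dp + 1L); cc <- off[ch] + seq_len(dc + 1L)
        C[2L * j - 1L, pc] <- up^(0:dp)
        C[2L * j - 1L, cc] <- -(uc^(0:dc))
        # d/dt = d/du * 1/halfspan
        C[2L * j, pc] <- c(0, (1:dp) * up^(0:(dp - 1L))) / hsp[pa]
        C[2L * j, cc] <- -c(0, (1:dc) * uc^(0:(dc - 1L))) / hsp[ch]
      }
      N <- null_space(C)
    } else {
      N <- diag(P)
    }
    M <- A %*% N
    qrM <- qr(M)
    if (ncol(M) > 0L && qrM$rank == ncol(M)) break
    if (all(degrees <= 1L)) {
      abort("Singular constrained design even at degree 1.",
            class = "treebic_fit_error")
    }
    degrees <- pmax(degrees - 1L, 1L)
  }

  z <- qr.coef(qrM, y)
  theta <- as.numeric(N %*% z)
  fitted <- as.numeric(A %*% theta)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss <= 1e-300) as.numeric(rss <= 1e-12) else 1 - rss / tss

  coefs <- lapply(seq_along(cells), function(i)
    theta[off[i] + seq_len(degrees[i] + 1L)])
  out <- list(
    cells = tibble(
      cell = cells, n_points = npts, degree = degrees,
      t_start = t0, t_end = t1, center = ctr, halfspan = hsp,
      coefs = coefs
    ),
    constraints = tibble(
      child = cons_child,
      parent = unname(parent[cons_child]),
      time = unname(t0[cons_child])
    ),
    r_squared = r2, rss = rss, tss = tss,
    n_points = length(y), n_params = ncol(M), n_extra = n_extra
  )
  class(out) <- "subtree_fit"
  out
}

#' Evaluate a fitted subtree at arbitrary times
#'
#' @param fit A `subtree_fit`.
#' @param cell Cell name within the fit.
#' @param times Numeric times (minutes).
#' @param deriv If `TRUE`, evaluate the rate function F' instead of F.
#' @return Numeric vector of fitted values.
#' @export
predict_subtree <- function(fit, cell, times, deriv = FALSE) {
  i <- match(cell, fit$cells$cell)
  if (is.na(i)) abort(paste0("Cell not in fit: ", cell),
                      class = "treebic_data_error")
  u <- (times - fit$cells$center[i]) / fit$cells$halfspan[i]
  if (deriv) {
    eval_poly(poly_deriv(fit$cells$coefs[[i]]), u) / fit$cells$halfspan[i]
  } else {
    eval_poly(fit$cells$coefs[[i]], u)
  }
}

#' C1 mismatch at each constrained division point
#'
#' @param fit A `subtree_fit`.
#' @return Tibble with per-division absolute value and derivative residuals.
#' @export
constraint_residuals <- function(fit) {
  cs <- fit$constraints
  if (!nrow(cs)) {
    return(tibble(child = character(), parent = character(),
                  time = numeric(), value_gap = numeric(),
                  deriv_gap = numeric()))
  }
  vg <- abs(vapply(seq_len(nrow(cs)), function(j)
    predict_subtree(fit, cs$parent[j], cs$time[j]) -
      predict_subtree(fit, cs$child[j], cs$time[j]), numeric(1)))
  dg <- abs(vapply(seq_len(nrow(cs)), function(j)
    predict_subtree(fit, cs$parent[j], cs$time[j], deriv = TRUE) -
      predict_subtree(fit, cs$child[j], cs$time[j], deriv = TRUE),
    numeric(1)))
  tibble(child = cs$child, parent = cs$parent, time = cs$time,
         value_gap = vg, deriv_gap = dg)
}

#' Choose the points-per-extra-degree parameter by BIC
#'
#' Fits the subtree once per candidate `n_extra` and returns the candidate
#' minimizing the Gaussian-error BIC `T * log(RSS / T) + p * log(T)`, where
#' `T` is the total number of points and `p` the number of free parameters
#' after the continuity constraints. Ties go to the smallest candidate.
#'
#' @inheritParams fit_subtree
#' @return List with `n_extra` (chosen), `fit` (the winning `subtree_fit`)
#'   and `bic` (tibble of candidate scores).
#' @export
select_n_by_bic <- function(cell_series, tree, config = fit_config()) {
  cand <- config$n_extra_candidates
  fits <- lapply(cand, function(ne)
    fit_subtree(cell_series, tree, config, n_extra = ne))
  bic <- vapply(fits, function(f) {
    T_ <- f$n_points
    T_ * log(f$rss / T_) + f$n_params * log(T_)
  }, numeric(1))
  best <- which.min(bic)  # candidates ascending, first min = smallest n
  list(n_extra = cand[best], fit = fits[[best]],
       bic = tibble(n_extra = cand, bic = bic))
}

#' Fit all copies and lineage subtrees of a dataset
#'
#' For every copy and every founder lineage with observed cells, selects
#' `n_extra` by BIC and fits the C1-constrained piecewise polynomial.
#'
#' @param ds A `series_dataset`.
#' @param config A [fit_config()].
#' @return A `tree_fit` object: list with `subtrees` (tibble of per
#'   copy/subtree fits and R^2) and `cell_fits` (per copy/cell coefficient
#'   rows), plus the config.
#' @export
fit_dataset <- function(ds, config = fit_config()) {
  sp <- series_split(ds)
  rows <- list()
  for (cp in ds$copies$copy) {
    for (rt in intersect(ds$roots, unique(ds$tree$root))) {
      in_sub <- intersect(subtree_cells(ds$tree, rt), names(sp[[cp]]))
      in_sub <- in_sub[vapply(sp[[cp]][in_sub], function(s)
        length(s$values) >= 2L, logical(1))]
      if (!length(in_sub)) next
      sel <- select_n_by_bic(sp[[cp]][in_sub], ds$tree, config)
      rows[[length(rows) + 1L]] <- tibble(
        copy = cp, subtree = rt, n_extra = sel$n_extra,
        r_squared = sel$fit$r_squared, n_points = sel$fit$n_points,
        n_params = sel$fit$n_params, fit = list(sel$fit)
      )
    }
  }
  subtrees <- bind_rows(rows)
  cell_fits <- subtrees |>
    mutate(cells = purrr::map(.data$fit, "cells")) |>
    select("copy", "subtree", "r_squared", "cells") |>
    tidyr::unnest("cells")
  out <- list(subtrees = subtrees, cell_fits = cell_fits, config = config,
              copies = ds$copies, cells = ds$cells)
  class(out) <- "tree_fit"
  out
}

#' @export
print.tree_fit <- function(x, ...) {
  cat("<tree_fit> ", nrow(x$subtrees), " fitted subtrees over ",
      length(unique(x$subtrees$copy)), " copies; mean R^2 = ",
      signif(mean(x$subtrees$r_squared), 3), "\n", sep = "")
  invisible(x)
}

#' Sample a cell's rate function on the unit interval
#'
#' Evaluates the fitted rate function F' at `grid_points` equally spaced
#' times spanning the cell's lifetime, i.e. after translating and scaling
#' every lifetime to a common interval so rate functions from cells of
#' different duration become comparable.
#'
#' @param fit A `subtree_fit` containing the cell.
#' @param cell Cell name.
#' @param grid_points Number of samples (default from the fit basis, 50).
#' @return Numeric vector of length `grid_points`.
#' @export
sample_rate_on_unit_interval <- function(fit, cell, grid_points = 50L) {
  i <- match(cell, fit$cells$cell)
  if (is.na(i)) return(rep(NA_real_, grid_points))
  tt <- seq(fit$cells$t_start[i], fit$cells$t_end[i],
            length.out = grid_points)
  predict_subtree(fit, cell, tt, deriv = TRUE)
}

# grid x copies x cells array of unit-interval rate samples (NA = missing)
rate_array <- function(fits, grid_points = fits$config$grid_points) {
  copies <- fits$copies$copy; cells <- fits$cells
  arr <- array(NA_real_, c(grid_points, length(copies), length(cells)),
               dimnames = list(NULL, copies, cells))
  for (i in seq_len(nrow(fits$subtrees))) {
    f <- fits$subtrees$fit[[i]]
    cp <- fits$subtrees$copy[i]
    for (cl in f$cells$cell) {
      arr[, cp, cl] <- sample_rate_on_unit_interval(f, cl, grid_points)
    }
  }
  arr
}

#' @rdname fit_dataset
#' @param x A `tree_fit`.
#' @param ... Unused.
#' @export
tidy.tree_fit <- function(x, ...) {
  x$cell_fits |>
    mutate(coef = purrr::map(.data$coefs, function(cf)
      tibble(term = paste0("c", seq_along(cf) - 1L), estimate = cf))) |>
    select("copy", "subtree", "cell", "degree", "t_start", "t_end",
           "r_squared", "coef") |>
    tidyr::unnest("coef")
}

#' @rdname fit_dataset
#' @export
glance.tree_fit <- function(x, ...) {
  r2 <- x$subtrees$r_squared
  tibble(
    n_subtrees = nrow(x$subtrees),
    r2_mean = mean(r2), r2_sd = stats::sd(r2),
    r2_p25 = unname(stats::quantile(r2, 0.25)),
    r2_p50 = unname(stats::quantile(r2, 0.50)),
    r2_p75 = unname(stats::quantile(r2, 0.75)),
    r2_max = max(r2)
  )
}

#' Export fitted coefficients to CSV
#'
#' One row per (copy, subtree, cell): degree, ascending coefficients
#' `c0..c8` on the centered lifetime-scaled basis, subtree R^2 and the
#' cell's interval (which defines the basis).
#'
#' @param fits A `tree_fit`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_fits <- function(fits, path) {
  cf <- fits$cell_fits
  cm <- t(vapply(cf$coefs, function(x) {
    out <- rep(NA_real_, 9L); out[seq_along(x)] <- x; out
  }, numeric(9)))
  colnames(cm) <- paste0("c", 0:8)
  tab <- dplyr::bind_cols(
    cf[, c("copy", "subtree", "cell", "degree")],
    as_tibble(cm),
    cf[, c("r_squared", "t_start", "t_end")]
  )
  names(tab)[names(tab) == "r_squared"] <- "r2"
  readr::write_csv(tab, path, progress = FALSE)
  invisible(path)
}

#' Import fitted coefficients written by [export_fits()]
#'
#' @param path CSV path.
#' @return Tibble in the `cell_fits` layout (with list-column `coefs`).
#' @export
import_fits <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  cc <- as.matrix(tab[, paste0("c", 0:8)])
  tab |>
    mutate(
      coefs = purrr::map2(seq_len(nrow(tab)), .data$degree, function(i, d)
        unname(cc[i, seq_len(d + 1L)])),
      center = (.data$t_start + .data$t_end) / 2,
      halfspan = (.data$t_end - .data$t_start) / 2,
      r_squared = .data$r2
    ) |>
    select("copy", "subtree", "cell", "degree", "t_start", "t_end",
           "center", "halfspan", "coefs", "r_squared")
}
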