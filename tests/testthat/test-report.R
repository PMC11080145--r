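report_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- simulate_lineage_dataset(sim_config(
        n_genes = 8, n_cells = 12, seed = 25, noise_sd = 0.05,
        missing_rate = 0.1, planted = planted_bicluster(3, 5)
      ))
      fits <- fit_dataset(ds)
      ctx <- bicluster_context(ds, fits)
      res <- search_biclusters(ctx, search_config(
        num = 15, max_i = 25, n_r = 3, n_c = 5, max_biclusters = 2,
        seed = 9
      ))
      cache <<- list(ds = ds, fits = fits, ctx = ctx, res = res)
    }
    cache
  }
})

test_that("report matrices are symmetric with unit diagonal", {
  fx <- report_fixture()
  expect_gt(nrow(fx$res), 0)
  for (i in seq_len(nrow(fx$res))) {
    gc <- bicluster_gene_correlation(fx$ctx, fx$res$genes[[i]],
                                     fx$res$cells[[i]])
    cs <- bicluster_cell_similarity(fx$ctx, fx$res$genes[[i]],
                                    fx$res$cells[[i]])
    expect_equal(gc, t(gc))
    expect_equal(unname(diag(gc)), rep(1, nrow(gc)))
    expect_true(all(abs(gc) <= 1 + 1e-12, na.rm = TRUE))
    expect_equal(cs, t(cs))
    expect_equal(unname(diag(cs)), rep(1, nrow(cs)))
    expect_true(all(cs >= 0 & cs <= 1, na.rm = TRUE))
  }
})

test_that("stored scores are reproduced from stored membership", {
  fx <- report_fixture()
  prev <- list()
  for (i in seq_len(nrow(fx$res))) {
    B <- bicluster(fx$res$genes[[i]], fx$res$cells[[i]])
    ob <- objective(B, fx$ctx, objective_weights(), prev)
    expect_equal(ob$score, fx$res$score[i], tolerance = 1e-12)
    prev[[i]] <- list(genes = fx$res$genes[[i]], cells = fx$res$cells[[i]])
  }
})

test_that("fate proportions count bicluster and lineage totals", {
  fate <- tibble::tibble(
    cell = c("Ca", "Cp", "Da", "Dp", "Ea"),
    fate = c("muscle", "muscle", "muscle", "intestine", "intestine")
  )
  fp <- fate_proportions(c("Ca", "Cp", "Dp", "Exx"), fate)
  expect_equal(fp$n[fp$fate == "muscle"], 2L)
  expect_equal(fp$n_total[fp$fate == "muscle"], 3L)
  expect_equal(fp$n[fp$fate == "intestine"], 1L)
  expect_equal(fp$prop[fp$fate == "unknown"], 0.25)
})

test_that("run_fit writes exports consistent with recomputation", {
  fx <- report_fixture()
  dir <- withr::local_tempdir()
  input <- file.path(dir, "series.csv")
  write_series_table(fx$ds, input)
  out <- file.path(dir, "fit")
  fits <- run_fit(input, out)
  expect_true(file.exists(file.path(out, "coefficients.csv")))
  r2 <- readr::read_csv(file.path(out, "r2_values.csv"),
                        show_col_types = FALSE)
  summ <- readr::read_csv(file.path(out, "r2_summary.csv"),
                          show_col_types = FALSE)
  expect_equal(summ$r2_mean, mean(r2$r_squared), tolerance = 1e-12)
  expect_equal(summ$r2_sd, sd(r2$r_squared), tolerance = 1e-12)
  # exports agree with the in-memory fit
  expect_equal(sort(r2$r_squared), sort(fits$subtrees$r_squared),
               tolerance = 1e-12)
})

test_that("noiseless in-model data yields an R^2 summary at 1", {
  # truth exactly in the model space: C1 piecewise cubics per subtree
  rows <- list()
  for (s in 1:3) {
    sub <- make_c1_cubic_subtree(seed = 500 + s, root = c("C", "D", "E")[s])
    for (cl in names(sub$series)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene = "g1", copy = "g1_c1", cell = cl,
        time_min = sub$series[[cl]]$times,
        value = sub$series[[cl]]$values
      )
    }
  }
  dir <- withr::local_tempdir()
  input <- file.path(dir, "series.csv")
  readr::write_csv(dplyr::bind_rows(rows), input)
  fits <- run_fit(input, file.path(dir, "fit"))
  expect_gte(min(fits$subtrees$r_squared), 1 - 1e-10)
  summ <- readr::read_csv(file.path(dir, "fit", "r2_summary.csv"),
                          show_col_types = FALSE)
  expect_gte(summ$r2_p25, 1 - 1e-10)
})

test_that("run_search writes results reproducible from files", {
  fx <- report_fixture()
  dir <- withr::local_tempdir()
  input <- file.path(dir, "series.csv")
  write_series_table(fx$ds, input)
  ytab <- file.path(dir, "Y.csv")
  write_binary_matrix(fx$ds, ytab)
  out <- file.path(dir, "search")
  res <- run_search(input, out, search_cfg = search_config(
    num = 15, max_i = 25, n_r = 3, n_c = 5, max_biclusters = 2, seed = 9
  ), y_table = ytab)
  expect_identical(tidy(res), tidy(fx$res))
  expect_true(file.exists(file.path(out, "biclusters.json")))
  js <- jsonlite::read_json(file.path(out, "biclusters.json"))
  expect_length(js, nrow(res))
  expect_equal(js[[1]]$score, res$score[1], tolerance = 1e-12)
  memb <- readr::read_tsv(file.path(out, "membership.tsv"),
                          show_col_types = FALSE)
  expect_equal(sort(memb$member[memb$k == 1 & memb$axis == "cell"]),
               sort(res$cell_labels[[1]]))
  log <- readr::read_csv(file.path(out, "run_log.csv"),
                         show_col_types = FALSE)
  expect_equal(nrow(log), nrow(attr(res, "history")))
})

test_that("run_report recomputes matrices and fates, warning on unknowns", {
  fx <- report_fixture()
  fate <- tibble::tibble(cell = c(fx$ctx$cells[1:4], "ZZZ"),
                         fate = c("a", "a", "b", "b", "c"))
  expect_warning(rep <- run_report(fx$res, fx$ctx, fate), "ZZZ")
  expect_equal(nrow(rep), nrow(fx$res))
  expect_equal(rep$gene_correlation[[1]],
               bicluster_gene_correlation(fx$ctx, fx$res$genes[[1]],
                                          fx$res$cells[[1]]))
  dir <- withr::local_tempdir()
  suppressWarnings(run_report(fx$res, fx$ctx, fate, dir))
  expect_true(file.exists(file.path(dir,
                                    "bicluster01_gene_correlation.csv")))
})

test_that("plots build without error", {
  fx <- report_fixture()
  expect_s3_class(autoplot(fx$res), "ggplot")
  expect_s3_class(autoplot(fx$fits), "ggplot")
  expect_s3_class(plot_gene_correlation(fx$ctx, fx$res, 1), "ggplot")
  expect_s3_class(plot_cell_similarity(fx$ctx, fx$res, 1), "ggplot")
  sub1 <- fx$fits$subtrees[1, ]
  expect_s3_class(plot_subtree_fit(fx$ds, fx$fits, sub1$copy,
                                   sub1$subtree), "ggplot")
})

test_that("the command-line interface runs the pipeline end to end", {
  dir <- withr::local_tempdir()
  cli <- system.file("cli", "treebic.R", package = "treebic")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  libs <- paste(.libPaths(), collapse = .Platform$path.sep)
  cfg <- file.path(dir, "cfg.yaml")
  writeLines(c(
    "sim:",
    "  n_genes: 5",
    "  n_cells: 9",
    "  seed: 3",
    "search:",
    "  num: 10",
    "  max_i: 10",
    "  n_r: 3",
    "  n_c: 4",
    "  max_biclusters: 1"
  ), cfg)
  env <- c(paste0("R_LIBS=", libs), paste0("R_LIBS_USER=", libs))
  out1 <- system2(rscript, c(cli, "simulate", "--out",
                             file.path(dir, "data"), "--config", cfg),
                  env = env, stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(dir, "data", "series.csv")))
  status <- attr(out1, "status")
  expect_true(is.null(status) || status == 0)
  out2 <- system2(rscript, c(cli, "search", "--input",
                             file.path(dir, "data", "series.csv"),
                             "--out", file.path(dir, "res"),
                             "--config", cfg, "--seed", "5",
                             "--y-table", file.path(dir, "data", "Y.csv")),
                  env = env, stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(dir, "res", "biclusters.json")))
  # missing input: usage/data error exit code, not a crash
  out3 <- suppressWarnings(
    system2(rscript, c(cli, "fit", "--input", "nope.csv",
                       "--out", file.path(dir, "x")),
            env = env, stdout = TRUE, stderr = TRUE)
  )
  expect_equal(attr(out3, "status"), 3)
})
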