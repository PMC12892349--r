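# helpers shared by the engine tests
toy_paths <- function() {
  forking_paths(negative_weights = c("abs", "zero"),
                density = c(0.1, 0.2, 0.3, 0.4, 0.5))
}

abide_like_paths <- function() {
  forking_paths(
    pipeline = c("CPAC", "CCS", "DPARSF", "NIAK"),
    parcellation = c("AAL", "CC200", "Dosenbach160"),
    global_signal_regression = c(TRUE, FALSE),
    bandpass_filter = c(TRUE, FALSE),
    connectivity = c("pearson", "partial"),
    regularization = c(0.25, 1.0))
}

fixture_matrix <- function() {
  set.seed(815)
  W <- matrix(rnorm(144), 12)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

test_that("expansion counts follow the product rule", {
  expect_length(expand_universes(toy_paths()), 10L)
  expect_length(expand_universes(abide_like_paths()), 192L)
  rule <- list(list(pipeline = "NIAK", global_signal_regression = TRUE))
  expect_length(expand_universes(abide_like_paths(), rule), 168L)
})

test_that("expansion minus rules equals brute-force enumeration", {
  set.seed(81)
  for (rep in 1:5) {
    n_dec <- sample(2:4, 1)
    fp_list <- lapply(seq_len(n_dec), function(d)
      as.list(paste0("o", seq_len(sample(2:4, 1)))))
    names(fp_list) <- paste0("dec", seq_len(n_dec))
    fp <- do.call(forking_paths, fp_list)
    # random rule over two decisions
    rd <- sample(n_dec, 2)
    rule <- stats::setNames(
      list(sample(unlist(fp_list[[rd[1]]]), 1),
           sample(unlist(fp_list[[rd[2]]]), 1)),
      names(fp_list)[rd])
    got <- expand_universes(fp, list(rule))
    # oracle: full grid, filter by matching
    grid <- expand.grid(lapply(fp_list, unlist),
                        stringsAsFactors = FALSE)
    drop <- grid[[names(rule)[1]]] == rule[[1]] &
      grid[[names(rule)[2]]] == rule[[2]]
    expect_length(got, nrow(grid) - sum(drop))
  }
  expect_error(expand_universes(toy_paths(),
                                list(list(nope = "x"))), "unknown decision")
})

test_that("universe ordering is row-major over the declaration", {
  a <- expand_universes(toy_paths())
  expect_equal(a[[1]]$negative_weights, "abs")
  expect_equal(a[[1]]$density, 0.1)
  expect_equal(a[[5]]$density, 0.5)
  expect_equal(a[[6]]$negative_weights, "zero")
  expect_equal(a[[6]]$density, 0.1)
})

test_that("template rendering substitutes typed literals", {
  expect_equal(render_template("thresh(W, {{density}})",
                               list(density = 0.3)),
               "thresh(W, 0.3)")
  expect_equal(render_template("{{negative_weights}}",
                               list(negative_weights = "abs")),
               "\"abs\"")
  expect_equal(render_template("x <- {{flag}}", list(flag = TRUE)),
               "x <- TRUE")
  expect_equal(
    render_template("y <- {{f}}",
                    list(f = option_call("pearson_fc", ddof = 0))),
    "y <- pearson_fc(ddof = 0)")
  expect_error(render_template("{{typo}} {{density}}",
                               list(density = 0.3)), "typo")
})

test_that("rendered scripts are pairwise distinct across universes", {
  fp <- toy_paths()
  tpl <- "a <- {{negative_weights}}; b <- {{density}}"
  scripts <- vapply(expand_universes(fp), function(a)
    render_template(tpl, a), "")
  expect_equal(anyDuplicated(scripts), 0L)
})

test_that("create writes scripts, manifest, and is byte-identical on re-run", {
  out <- withr::local_tempdir()
  tpl <- "x <- {{negative_weights}}\ny <- {{density}}\n"
  m <- multiverse_create(toy_paths(), tpl, out_dir = out)
  expect_equal(nrow(m), 10L)
  expect_equal(m$universe_id, 1:10)
  expect_true(all(file.exists(
    file.path(out, "scripts", paste0("universe_", 1:10, ".R")))))
  expect_equal(names(m),
               c("universe_id", "negative_weights", "density",
                 "script", "status"))
  first <- readLines(file.path(out, "manifest.csv"))
  m2 <- multiverse_create(toy_paths(), tpl, out_dir = out)
  expect_identical(readLines(file.path(out, "manifest.csv")), first)
  expect_error(
    multiverse_create(toy_paths(), "only {{density}} here", out_dir = out),
    "never used")
  expect_error(
    multiverse_create(toy_paths(), paste(tpl, "{{bogus}}"), out_dir = out),
    "bogus")
})

test_that("summary and visualize agree with expansion on universe counts", {
  out <- withr::local_tempdir()
  tpl <- "x <- {{negative_weights}}; y <- {{density}}\n"
  multiverse_create(toy_paths(), tpl, out_dir = out)
  expect_equal(nrow(multiverse_summary(out)), 10L)
  v <- multiverse_visualize(toy_paths(), out_prefix = file.path(out, "g"))
  expect_equal(v$n_leaves, 10L)
  expect_true(file.exists(file.path(out, "g.dot")))
  expect_true(file.exists(file.path(out, "g.json")))
  rule <- list(list(pipeline = "NIAK", global_signal_regression = TRUE))
  v2 <- multiverse_visualize(abide_like_paths(), rule,
                             out_prefix = file.path(out, "g2"))
  expect_equal(v2$n_leaves, 168L)
  v3 <- multiverse_visualize(forking_paths(k = c("a", "b", "c")),
                             out_prefix = file.path(out, "g3"))
  expect_equal(v3$n_leaves, 3L)
  expect_equal(v3$n_nodes, 4L)  # root + one level of 3
})

toy_template <- function(fc_path) {
  paste0('
library(dfcverse)
W <- read_matrix("', fc_path, '")
g <- handle_negative(connectivity_graph(W), mode = {{negative_weights}})
g <- threshold_density(g, {{density}})
save_universe_results(list(global_efficiency = global_efficiency(g)))
')
}

test_that("run executes universes whose outcomes equal direct calls", {
  out <- withr::local_tempdir()
  W <- fixture_matrix()
  fc_path <- file.path(out, "fc.tsv")
  write_matrix(W, fc_path)
  multiverse_create(toy_paths(), toy_template(fc_path), out_dir = out)
  m <- multiverse_run(out)
  expect_true(all(m$status == "ok"))
  expect_equal(attr(m, "n_failed"), 0L)
  res <- multiverse_results(out)
  expect_equal(nrow(res), 10L)
  direct <- mapply(function(nw, d) {
    g <- handle_negative(connectivity_graph(W), nw)
    global_efficiency(threshold_density(g, as.numeric(d)))
  }, res$negative_weights, res$density)
  expect_lt(max(abs(res$global_efficiency - unname(direct))), 1e-12)
})

test_that("a failing universe is captured without aborting siblings", {
  out <- withr::local_tempdir()
  W <- fixture_matrix()
  fc_path <- file.path(out, "fc.tsv")
  write_matrix(W, fc_path)
  fp <- forking_paths(density = c(0.2, 0.4, -1))  # -1 is invalid
  tpl <- paste0('
library(dfcverse)
W <- read_matrix("', fc_path, '")
g <- threshold_density(handle_negative(connectivity_graph(W), "abs"),
                       {{density}})
save_universe_results(list(global_efficiency = global_efficiency(g)))
')
  multiverse_create(fp, tpl, out_dir = out)
  m <- multiverse_run(out)
  expect_equal(sum(m$status == "ok"), 2L)
  expect_equal(sum(m$status == "failed"), 1L)
  expect_equal(attr(m, "n_failed"), 1L)
  res <- multiverse_results(out)
  expect_equal(nrow(res), 3L)  # failure kept, not dropped
  expect_true(any(!is.na(res$error)))
})

test_that("sequential and parallel runs give identical results", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  W <- fixture_matrix()
  for (o in c(out1, out2)) {
    write_matrix(W, file.path(o, "fc.tsv"))
    multiverse_create(toy_paths(), toy_template(file.path(o, "fc.tsv")),
                      out_dir = o)
  }
  multiverse_run(out1, workers = 1)
  multiverse_run(out2, workers = 4)
  r1 <- multiverse_results(out1)
  r2 <- multiverse_results(out2)
  expect_equal(r1$global_efficiency, r2$global_efficiency)
})

test_that("results join preserves ids and flags failures", {
  out <- withr::local_tempdir()
  W <- fixture_matrix()
  fc_path <- file.path(out, "fc.tsv")
  write_matrix(W, fc_path)
  multiverse_create(toy_paths(), toy_template(fc_path), out_dir = out)
  multiverse_run(out, ids = c(1, 4, 7))
  res <- multiverse_results(out)
  expect_equal(res$universe_id, 1:10)
  expect_equal(sum(!is.na(res$global_efficiency)), 3L)
  expect_true(all(c("negative_weights", "density", "status") %in% names(res)))
})

test_that("specification curve sorts ascending with a complete indicator matrix", {
  out <- withr::local_tempdir()
  W <- fixture_matrix()
  fc_path <- file.path(out, "fc.tsv")
  write_matrix(W, fc_path)
  multiverse_create(toy_paths(), toy_template(fc_path), out_dir = out)
  multiverse_run(out)
  res <- multiverse_results(out)
  tab <- specification_curve(res, "global_efficiency",
                             out_prefix = file.path(out, "spec"))
  csv <- utils::read.csv(file.path(out, "spec.csv"))
  expect_false(is.unsorted(csv$global_efficiency))
  expect_equal(csv$rank, 1:10)
  expect_true(file.exists(file.path(out, "spec.png")))
  expect_true(file.exists(file.path(out, "spec.svg")))
  # partition property: each universe appears once per decision
  for (d in c("negative_weights", "density"))
    expect_false(anyNA(csv[[d]]))
  expect_setequal(csv$universe_id, 1:10)
  expect_error(specification_curve(res, "bogus"), "unknown outcome")
})

test_that("monotone outcomes rank universes by the driving decision", {
  out <- withr::local_tempdir()
  fp <- forking_paths(density = c(0.1, 0.2, 0.3, 0.4, 0.5))
  tpl <- '
library(dfcverse)
save_universe_results(list(outcome = {{density}}))
'
  multiverse_create(fp, tpl, out_dir = out)
  multiverse_run(out)
  res <- multiverse_results(out)
  tab <- specification_curve(res, "outcome")
  expect_equal(as.numeric(tab$density), sort(as.numeric(tab$density)))
})

test_that("save_universe_results validates outcomes and CIs", {
  out <- withr::local_tempdir()
  mv <- list(universe_id = 1L, results_dir = out)
  expect_error(save_universe_results(list(1), .mv = mv), "named")
  expect_error(save_universe_results(list(a = "x"), .mv = mv),
               "single number")
  expect_error(
    save_universe_results(list(a = 0.5), ci = list(a = c(0.6, 0.9)),
                          .mv = mv),
    "low <= estimate <= high")
  save_universe_results(list(a = 0.5), ci = list(a = c(0.2, 0.9)), .mv = mv)
  rec <- jsonlite::read_json(file.path(out, "universe_1.json"))
  expect_equal(rec$outcomes$a, 0.5)
  expect_equal(rec$ci$a$low, 0.2)
})
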