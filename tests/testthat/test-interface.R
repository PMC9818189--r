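test_that("expression TSV round-trips bit-identically", {
  at <- small_atlas(n_types = 3, n_genes = 60, n_cells = 10, seed = 3,
                    n_markers_per_type = 5)
  p1 <- tempfile(fileext = ".tsv"); p2 <- tempfile(fileext = ".tsv")
  write_expression_tsv(at$expr, p1)
  m <- read_expression_tsv(p1)
  expect_equal(m, at$expr)
  write_expression_tsv(m, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("malformed expression headers are rejected citing line 1", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("not_a_header", "g1\t3"), p)
  expect_error(read_expression_tsv(p), "line 1")
})

test_that("atlas bundles round-trip through dense TSV and sparse MTX", {
  at <- small_atlas(n_types = 3, n_genes = 50, n_cells = 8, seed = 4,
                    n_markers_per_type = 5)
  prefix <- tempfile()
  write_atlas(at, prefix)
  back <- read_atlas(prefix)
  expect_equal(back$expr, at$expr)
  expect_identical(back$labels, at$labels)
  expect_setequal(tmedeconv:::tree_leaves(back$tree), atlas_types(at))
  mtx <- tempfile(fileext = ".mtx"); gn <- tempfile(); bc <- tempfile()
  write_atlas_mtx(at, mtx, gn, bc)
  sparse <- read_atlas(mtx = mtx, genes = gn, barcodes = bc,
                       annotation = paste0(prefix, "_annotation.tsv"),
                       tree = paste0(prefix, "_tree.tsv"))
  expect_equal(sparse$expr, at$expr)
})

test_that("survival tables read back with unit conversion to months", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ttime\tevent\tunit",
               "s1\t365.25\t1\tdays",
               "s2\t2\t0\tyears"), p)
  surv <- read_survival_tsv(p)
  expect_equal(surv$time, c(12, 24))
  expect_identical(surv$event, c(TRUE, FALSE))
})

test_that("fractions and signature tables round-trip", {
  fr <- matrix(c(0.2, 0.8, 0.5, 0.5), 2, byrow = TRUE,
               dimnames = list(c("s1", "s2"), c("A", "B")))
  p <- tempfile(fileext = ".tsv")
  write_fractions_tsv(fr, p)
  expect_equal(read_fractions_tsv(p), fr)
  at <- small_atlas(n_types = 3, n_genes = 300, n_cells = 25, seed = 1)
  sig <- build_signature(at, normalize = FALSE)
  ps <- tempfile(fileext = ".tsv")
  write_signature_tsv(sig, ps)
  expect_equal(read_signature_tsv(ps)$expr, sig$expr)
})

test_that("the CLI validate stage is byte-identical across reruns", {
  wd <- tempfile(); dir.create(wd)
  old <- setwd(wd); on.exit(setwd(old))
  expect_equal(run_cli(c("simulate-atlas", "--n-types", "3",
                         "--n-genes", "400", "--n-cells", "30",
                         "--seed", "2", "--out", "atl")), 0L)
  for (run in 1:2)
    expect_equal(suppressMessages(
      run_cli(c("validate", "--atlas", "atl", "--n-mixtures", "10",
                "--method", "nnls", "--seed", "5",
                "--out", sprintf("rep%d.tsv", run)))), 0L)
  expect_identical(readLines("rep1.tsv"), readLines("rep2.tsv"))
})

test_that("the CLI pipeline runs end-to-end and fails loudly on bad input", {
  wd <- tempfile(); dir.create(wd)
  old <- setwd(wd); on.exit(setwd(old))
  steps <- list(
    c("simulate-atlas", "--n-types", "4", "--n-genes", "500",
      "--n-cells", "30", "--seed", "2", "--out", "atl"),
    c("build-signature", "--atlas", "atl", "--out", "sig.tsv"),
    c("simulate-cohort", "--atlas", "atl", "--effect-type", "type_01",
      "--log-hr", "2", "--n-patients", "60", "--seed", "4", "--out", "coh"),
    c("deconv", "--signature", "sig.tsv", "--bulk", "coh_bulk.tsv",
      "--method", "nnls", "--out", "dec"),
    c("survival", "--fractions", "dec_fractions.tsv",
      "--survival", "coh_survival.tsv", "--type", "type_01",
      "--out", "surv"))
  for (s in steps)
    expect_equal(suppressMessages(run_cli(s)), 0L)
  expect_true(all(file.exists(c("sig.tsv", "dec_fractions.tsv",
                                "surv_split.tsv", "surv_km_high.tsv",
                                "surv_km_low.tsv"))))
  # a mixture file without its header is refused, citing line 1
  writeLines(c("g1\t3\t4", "g2\t5\t6"), "broken.tsv")
  expect_message(
    status <- run_cli(c("deconv", "--signature", "sig.tsv",
                        "--bulk", "broken.tsv", "--out", "x")),
    "line 1")
  expect_equal(status, 1L)
})

test_that("a YAML config reproduces flags and conflicts are errors", {
  wd <- tempfile(); dir.create(wd)
  old <- setwd(wd); on.exit(setwd(old))
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("n-types: 3", "n-genes: 400", "n-cells: 30", "seed: 2",
               "out: atl_cfg"), cfg)
  expect_equal(suppressMessages(
    run_cli(c("simulate-atlas", "--config", cfg))), 0L)
  expect_equal(suppressMessages(
    run_cli(c("simulate-atlas", "--seed", "2", "--config", cfg))), 0L)
  expect_message(
    status <- run_cli(c("simulate-atlas", "--seed", "3", "--config", cfg)),
    "conflicts")
  expect_equal(status, 1L)
  expect_identical(
    readLines("atl_cfg_expr.tsv"),
    {
      expect_equal(suppressMessages(run_cli(
        c("simulate-atlas", "--n-types", "3", "--n-genes", "400",
          "--n-cells", "30", "--seed", "2", "--out", "atl_flag"))), 0L)
      readLines("atl_flag_expr.tsv")
    })
})

test_that("unknown flags and subcommands are rejected", {
  expect_message(status <- run_cli(c("simulate-atlas", "--bogus", "1")),
                 "unknown flag")
  expect_equal(status, 1L)
  expect_message(status2 <- run_cli("frobnicate"), "unknown subcommand")
  expect_equal(status2, 1L)
  expect_equal(suppressMessages(run_cli(character())), 1L)
})
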