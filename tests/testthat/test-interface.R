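emptyConfig <- function() {
  tf <- withr::local_tempfile(fileext = ".yaml",
                              .local_envir = parent.frame())
  writeLines("", tf)
  tf
}

test_that("an empty configuration file yields the published defaults", {
  cfg <- loadRunConfig(emptyConfig())
  expect_equal(cfg$training$learning_rate, 1e-4)
  expect_identical(cfg$training$batch_size, 32L)
  expect_equal(cfg$training$l2_lambda, 0.01)
  expect_equal(cfg$architecture$dropout_rate, 0.5)
  expect_identical(cfg$training$max_epochs, 50L)
  expect_equal(cfg$training$plateau_factor, 0.5)
  expect_identical(cfg$training$plateau_patience, 5L)
  expect_equal(cfg$training$min_lr, 1e-6)
  expect_identical(cfg$training$early_stop_patience, 15L)
  expect_equal(cfg$split$fractions, c(0.70, 0.15, 0.15))
  expect_identical(cfg$architecture$block_channels,
                   c(128L, 256L, 512L, 1024L))
})

test_that("configurations round-trip losslessly and reject bad input", {
  cfg <- loadRunConfig(emptyConfig())
  cfg$training$learning_rate <- 5e-4
  cfg$generator$image_size <- 64L
  tf <- withr::local_tempfile(fileext = ".yaml")
  saveRunConfig(cfg, tf)
  expect_identical(loadRunConfig(tf), cfg)
  # invalid value names the offending key
  tf2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("training:\n  learning_rate: -0.1", tf2)
  expect_error(loadRunConfig(tf2), "training.learning_rate")
  # unknown keys are rejected by name
  tf3 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("training:\n  warmup_epochs: 3", tf3)
  expect_error(loadRunConfig(tf3), "training.warmup_epochs")
})

test_that("summary prints the published totals and evaluate requires a
           checkpoint", {
  cfg <- loadRunConfig(emptyConfig())
  cfg$paths$run_dir <- withr::local_tempdir()
  out <- capture.output(ps <- runStage("summary", cfg))
  expect_identical(ps@trainable, 16552114)
  expect_identical(ps@nonTrainable, 8960)
  expect_identical(ps@total, 16561074)
  expect_true(any(grepl("16,552,114", out)))
  expect_error(runStage("evaluate", cfg), "prepare")
})

test_that("the full generate-prepare-train-evaluate-explain chain runs on a
           tiny configuration", {
  cfg <- loadRunConfig(emptyConfig())
  base <- withr::local_tempdir()
  cfg$paths$data_dir <- file.path(base, "data")
  cfg$paths$run_dir <- file.path(base, "run")
  cfg$generator$counts <- as.list(
    stats::setNames(rep(6L, 10), fundusnet:::fundusClassNames()))
  cfg$generator$image_size <- 32L
  cfg$architecture$input_size <- 32L
  cfg$architecture$stem_filters <- 4L
  cfg$architecture$block_channels <- c(8L, 12L, 16L, 24L)
  cfg$architecture$se_reduction <- 4L
  cfg$architecture$dense_units <- c(32L, 16L)
  cfg$smote$search_downscale <- 8L
  cfg$training$max_epochs <- 2L
  cfg$training$learning_rate <- 1e-3
  cfg$explain$num_examples <- 2L
  runStage("generate", cfg)
  expect_true(dir.exists(file.path(cfg$paths$data_dir, "Healthy")))
  prep <- runStage("prepare", cfg)
  expect_identical(as.vector(table(prep$labels)), rep(6L, 10))
  expect_true(file.exists(file.path(cfg$paths$run_dir, "split.json")))
  fit <- runStage("train", cfg)
  expect_true(file.exists(file.path(cfg$paths$run_dir, "checkpoint.rds")))
  expect_true(file.exists(file.path(cfg$paths$run_dir, "history.csv")))
  rep <- suppressWarnings(runStage("evaluate", cfg))
  expect_s4_class(rep, "MetricsReport")
  expect_true(file.exists(file.path(cfg$paths$run_dir, "metrics.json")))
  runStage("explain", cfg)
  expect_true(file.exists(file.path(cfg$paths$run_dir, "explain.json")))
  expect_gte(length(list.files(cfg$paths$run_dir, pattern = "explain_.*png")),
             1L)
  # the resolved configuration is echoed into the run directory
  expect_true(file.exists(file.path(cfg$paths$run_dir, "config.yaml")))
})

test_that("split-first mode only balances the training fold", {
  cfg <- loadRunConfig(emptyConfig())
  base <- withr::local_tempdir()
  cfg$paths$data_dir <- file.path(base, "data")
  cfg$paths$run_dir <- file.path(base, "run")
  counts <- stats::setNames(rep(6L, 10), fundusnet:::fundusClassNames())
  counts["Pterygium"] <- 4L
  cfg$generator$counts <- as.list(counts)
  cfg$generator$image_size <- 32L
  cfg$architecture$input_size <- 32L
  cfg$smote$search_downscale <- 8L
  cfg$smote$k_neighbors <- 2L
  cfg$split$split_first <- TRUE
  runStage("generate", cfg)
  prep <- suppressWarnings(runStage("prepare", cfg))
  labs <- prep$labels
  sp <- prep$split
  # training fold balanced, held-out folds untouched by synthesis
  trTab <- table(labs[sp$train])
  expect_true(length(unique(as.vector(trTab))) == 1L)
  expect_lte(length(labs[sp$test]), 10 * 1)
})
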