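test_that("scenario configs round-trip losslessly through YAML and JSON", {
  config <- scenario_config(
    design = experiment_design(cd_levels = c(0, 16), replicates = 2L,
                               seed = 99),
    dialyzer = dialyzer_params(k0a = 81.25, sieving_membrane = 0.93,
                               alpha_backfiltration = 0.85,
                               permeability_reduction = 0.05),
    pk = solute_pk(protein_binding = 0.02, vd = 21),
    assay = assay_params(extinction_coefficient = 0.77, noise_cv = 0.03),
    noise = noise_model(assay_cv = 0.03, degradation_rate = 0.01),
    output_dir = "out", log_level = "quiet"
  )
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_scenario_config(config, path)
    back <- read_scenario_config(path)
    expect_equal(back, config, tolerance = 1e-12)
  }
})

test_that("run_grid reproduces the flow-stratification structure cell by cell", {
  config <- scenario_config(dialyzer = dialyzer_params(k0a = 81),
                            log_level = "quiet")
  g <- run_grid(config)
  expect_identical(nrow(g$results), 27L)
  # equilibrated dialysate block: no change anywhere
  expect_true(all(g$summary[["cd16"]] == 16))
  # unenriched block loses, enriched block gains
  expect_true(all(g$results$percent_change[g$results$cd_mg_l == 0] < 0))
  expect_true(all(g$results$percent_change[g$results$cd_mg_l == 64] > 0))
  # composition: each cell equals a direct single_pass call
  for (i in sample(seq_len(nrow(g$results)), 6)) {
    r <- g$results[i, ]
    p <- single_pass(16, r$cd_mg_l, flow_setting(r$qb_ml_min, r$qd_ml_h),
                     config$dialyzer)
    expect_equal(r$c_rl_mg_l, p$c_rl, tolerance = 1e-12)
    expect_equal(r$clearance_ml_min, p$clearance, tolerance = 1e-12)
  }
  # pivot layout: rows Qb, columns Qd
  m <- g$summary[["cd0"]]
  expect_identical(dim(m), c(3L, 3L))
  expect_identical(m["Qb100ml_min", "Qd1000ml_h"],
                   g$results$c_rl_mg_l[g$results$cd_mg_l == 0][1])
})

test_that("run_grid logs the unit conversion once per run", {
  config <- scenario_config(dialyzer = dialyzer_params(k0a = 45))
  expect_message(run_grid(config), "unit conversion: dialysate flows")
})

test_that("run_scenario writes a reproducible output directory", {
  dir <- withr::local_tempdir()
  config <- scenario_config(dialyzer = dialyzer_params(k0a = 81),
                            output_dir = file.path(dir, "run1"),
                            log_level = "quiet")
  paths <- run_scenario(config)
  expect_true(all(file.exists(paths)))
  back <- read_scenario_config(paths[["config"]])
  expect_equal(back$dialyzer$k0a, 81)
  meta <- jsonlite::read_json(paths[["meta"]])
  expect_identical(meta$package, "dialsim")
  expect_identical(meta$seed, 1L)
  # identical config => identical measurement file
  config2 <- config; config2$output_dir <- file.path(dir, "run2")
  paths2 <- run_scenario(config2)
  expect_identical(readLines(paths[["measurements"]]),
                   readLines(paths2[["measurements"]]))
})

test_that("run_calibrate recovers the truth from a generated measurement file", {
  sc <- bench_scenario()
  ds <- generate_dataset(experiment_design(cd_levels = 0, replicates = 1L),
                         sc$params, noise = noise_model(assay_cv = 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(ds, path)
  json_out <- withr::local_tempfile(fileext = ".json")
  resid_out <- withr::local_tempfile(fileext = ".csv")
  res <- run_calibrate(path, output_json = json_out,
                       output_residuals = resid_out)
  expect_lt(abs(res$k0a_hat - sc$params$k0a) / sc$params$k0a, 1e-8)
  expect_true(file.exists(json_out))
  saved <- jsonlite::read_json(json_out)
  expect_equal(saved$k0a_hat, res$k0a_hat, tolerance = 1e-9)
  resid <- read.csv(resid_out)
  expect_identical(nrow(resid), 9L)
  expect_lt(max(abs(resid$residual)), 1e-10)
})

test_that("run_calibrate rejects empty or malformed input", {
  empty <- withr::local_tempfile(
    lines = "port,time_min,absorbance,concentration_mg_l,setting_label,replicate",
    fileext = ".csv")
  expect_error(run_calibrate(empty), "empty")
  bad <- withr::local_tempfile(lines = c("a,b", "1,2"), fileext = ".csv")
  expect_error(run_calibrate(bad), "missing columns")
})

test_that("the command-line front end runs a grid and a calibration", {
  skip_if(Sys.which("Rscript") == "", "Rscript not on PATH")
  cli <- system.file("cli", "dialsim.R", package = "dialsim")
  skip_if(cli == "", "CLI script not installed")
  dir <- withr::local_tempdir()
  env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  out <- system2("Rscript", c(cli, "grid", "--out", shQuote(dir)),
                 env = env, stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(dir, "grid_results.csv")))
  expect_true(file.exists(file.path(dir, "resolved_config.yaml")))
  grid <- read.csv(file.path(dir, "grid_results.csv"))
  expect_identical(nrow(grid), 27L)
  # calibrate subcommand on a generated file
  sc <- bench_scenario()
  ds <- generate_dataset(experiment_design(cd_levels = 0, replicates = 1L),
                         sc$params, noise = noise_model(assay_cv = 0))
  mpath <- file.path(dir, "meas.csv")
  write_measurements(ds, mpath)
  out2 <- system2("Rscript", c(cli, "calibrate", "--input", shQuote(mpath),
                               "--out", shQuote(dir)),
                  env = env, stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(dir, "calibration.json")))
  fit <- jsonlite::read_json(file.path(dir, "calibration.json"))
  expect_equal(fit$k0a_hat, sc$params$k0a, tolerance = 1e-6)
})
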