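#' Scenario configuration
#'
#' Bundles everything a reproducible run needs: design, dialyzer, solute,
#' assay and noise parameters plus output location. Round-trips losslessly
#' through YAML (or JSON) via [write_scenario_config()] /
#' [read_scenario_config()]; all units are carried in field names
#' (`qd_ml_h`, `qb_ml_min`) so unit errors stay grep-able.
#'
#' @param design An [experiment_design()].
#' @param dialyzer A [dialyzer_params()].
#' @param pk A [solute_pk()].
#' @param assay An [assay_params()].
#' @param noise A [noise_model()].
#' @param output_dir Output directory for workbench runs.
#' @param log_level `"info"` or `"quiet"`.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(design = experiment_design(),
                            dialyzer = dialyzer_params(k0a = 45),
                            pk = solute_pk(protein_binding = 0),
                            assay = assay_params(extinction_coefficient = 1),
                            noise = noise_model(),
                            output_dir = ".",
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  stopifnot(inherits(design, "experiment_design"),
            inherits(dialyzer, "dialyzer_params"),
            inherits(pk, "solute_pk"),
            inherits(assay, "assay_params"),
            inherits(noise, "noise_model"))
  structure(
    list(design = design, dialyzer = dialyzer, pk = pk, assay = assay,
         noise = noise, output_dir = output_dir, log_level = log_level),
    class = "scenario_config"
  )
}

.config_as_list <- function(config) {
  list(
    design = list(
      cd_levels_mg_l = config$design$cd_levels,
      qb_levels_ml_min = config$design$qb_levels,
      qd_levels_ml_h = config$design$qd_levels,
      replicates = config$design$replicates,
      control_times_min = config$design$control_times,
      seed = config$design$seed
    ),
    dialyzer = list(
      k0a_ml_min = config$dialyzer$k0a,
      sieving_membrane = config$dialyzer$sieving_membrane,
      alpha_backfiltration = config$dialyzer$alpha_backfiltration,
      permeability_reduction = config$dialyzer$permeability_reduction,
      geometry = config$dialyzer$geometry
    ),
    pk = list(
      molecular_weight_da = config$pk$molecular_weight,
      protein_binding = config$pk$protein_binding,
      vd_l = config$pk$vd,
      container_start_conc_mg_l = config$pk$container_start_conc
    ),
    assay = list(
      wavelength_nm = config$assay$wavelength,
      extinction_coefficient = config$assay$extinction_coefficient,
      path_length_cm = config$assay$path_length,
      noise_cv = config$assay$noise_cv
    ),
    noise = list(
      assay_cv = config$noise$assay_cv,
      degradation_rate_per_h = config$noise$degradation_rate
    ),
    output_dir = config$output_dir,
    log_level = config$log_level
  )
}

.config_from_list <- function(x) {
  scenario_config(
    design = experiment_design(
      cd_levels = as.numeric(x$design$cd_levels_mg_l),
      qb_levels = as.numeric(x$design$qb_levels_ml_min),
      qd_levels = as.numeric(x$design$qd_levels_ml_h),
      replicates = x$design$replicates,
      control_times = as.numeric(x$design$control_times_min),
      seed = x$design$seed
    ),
    dialyzer = dialyzer_params(
      k0a = x$dialyzer$k0a_ml_min,
      sieving_membrane = x$dialyzer$sieving_membrane,
      alpha_backfiltration = x$dialyzer$alpha_backfiltration,
      permeability_reduction = x$dialyzer$permeability_reduction,
      geometry = x$dialyzer$geometry
    ),
    pk = solute_pk(
      molecular_weight = x$pk$molecular_weight_da,
      protein_binding = x$pk$protein_binding,
      vd = x$pk$vd_l,
      container_start_conc = x$pk$container_start_conc_mg_l
    ),
    assay = assay_params(
      wavelength_nm = x$assay$wavelength_nm,
      extinction_coefficient = x$assay$extinction_coefficient,
      path_length_cm = x$assay$path_length_cm,
      noise_cv = x$assay$noise_cv
    ),
    noise = noise_model(
      assay_cv = x$noise$assay_cv,
      degradation_rate = x$noise$degradation_rate_per_h
    ),
    output_dir = x$output_dir,
    log_level = x$log_level
  )
}

#' Read / write a scenario configuration
#'
#' YAML by default; a path ending in `.json` uses JSON. The round trip
#' through either format is lossless.
#'
#' @param config A [scenario_config()].
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return The config (invisibly on write).
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  x <- .config_as_list(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path, precision = 15)
  }
  invisible(config)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  .config_from_list(x)
}

.log_info <- function(config, fmt, ...) {
  if (identical(config$log_level, "info")) {
    message(sprintf(fmt, ...))
  }
}

#' Run the noise-free scenario grid
#'
#' Evaluates the forward per-pass model over the full
#' (dialysate level) x (blood flow) x (dialysate flow) grid of a scenario
#' and returns the per-cell results plus a pivoted summary: for each
#' dialysate level a (blood flow) x (dialysate flow) matrix of the chosen
#' quantity, the layout of the bench study's flow-stratification figure.
#'
#' @param config A [scenario_config()].
#' @param summary_value Which quantity to pivot: `"c_rl_mg_l"` (default),
#'   `"percent_change"` or `"clearance_ml_min"`.
#' @return A list with `results` (per-cell data frame in the per-pass
#'   schema plus `percent_change`) and `summary` (named list of matrices,
#'   one per dialysate level; rows Qb, columns Qd).
#' @examples
#' g <- run_grid(scenario_config(dialyzer = dialyzer_params(k0a = 45)))
#' g$summary[["cd16"]]  # all 16: no gradient, nothing moves
#' @export
run_grid <- function(config, summary_value = c("c_rl_mg_l", "percent_change",
                                               "clearance_ml_min")) {
  stopifnot(inherits(config, "scenario_config"))
  summary_value <- match.arg(summary_value)
  d <- config$design
  .log_info(config,
            "unit conversion: dialysate flows %s ml/h -> %s ml/min",
            paste(d$qd_levels, collapse = "/"),
            paste(signif(d$qd_levels / 60, 6), collapse = "/"))
  c0 <- free_concentration(config$pk$container_start_conc, config$pk)
  rows <- list()
  for (cd in d$cd_levels) {
    for (qi in seq_along(d$qb_levels)) {
      for (qj in seq_along(d$qd_levels)) {
        fs <- flow_setting(d$qb_levels[qi], d$qd_levels[qj],
                           label = sprintf("QB%dQD%d", qi, qj))
        p <- single_pass(c0, cd, fs, config$dialyzer)
        row <- pass_results_table(list(p))
        row$percent_change <- if (c0 > 0) percent_change(p) else NA_real_
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  results <- do.call(rbind, rows)
  col <- if (summary_value == "percent_change") "percent_change" else summary_value
  summaries <- lapply(d$cd_levels, function(cd) {
    block <- results[results$cd_mg_l == cd, , drop = FALSE]
    m <- matrix(block[[col]], nrow = length(d$qb_levels),
                ncol = length(d$qd_levels), byrow = TRUE,
                dimnames = list(paste0("Qb", d$qb_levels, "ml_min"),
                                paste0("Qd", d$qd_levels, "ml_h")))
    m
  })
  names(summaries) <- paste0("cd", d$cd_levels)
  list(results = results, summary = summaries)
}

#' Run a scenario end to end and write its outputs
#'
#' Generates a synthetic dataset under the scenario, writes the
#' measurement table, the noise-free grid results, the pivoted summaries,
#' and the resolved configuration (with the package version) into
#' `config$output_dir`, so a run is reproducible from the directory
#' contents alone.
#'
#' @param config A [scenario_config()].
#' @return Paths of the files written, invisibly.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  dir <- config$output_dir
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir, call. = FALSE)
  }
  if (file.access(dir, 2) != 0) {
    stop("output directory is not writable: ", dir, call. = FALSE)
  }
  ds <- generate_dataset(config$design, config$dialyzer, config$pk,
                         config$assay, config$noise)
  grid <- run_grid(config)
  paths <- c(
    measurements = file.path(dir, "measurements.csv"),
    grid = file.path(dir, "grid_results.csv"),
    config = file.path(dir, "resolved_config.yaml"),
    meta = file.path(dir, "run_metadata.json")
  )
  write_measurements(ds, paths["measurements"])
  write.csv(grid$results, paths["grid"], row.names = FALSE, quote = FALSE)
  write_scenario_config(config, paths["config"])
  jsonlite::write_json(
    list(package = "dialsim",
         version = as.character(packageVersion("dialsim")),
         seed = config$design$seed),
    paths["meta"], auto_unbox = TRUE
  )
  invisible(paths)
}

#' Calibrate from a measurement or per-pass CSV
#'
#' Reads a table (long measurement schema or wide per-pass schema,
#' auto-detected), validates it, fits the mass-transfer coefficient with
#' [fit_k0a()], and optionally writes the result as JSON plus a residual
#' table as CSV.
#'
#' @param path Input CSV.
#' @param fit_alpha Also fit the back-filtration asymmetry.
#' @param output_json,output_residuals Optional output paths.
#' @param ... Passed on to [fit_k0a()].
#' @return The `calibration_result`, with a `residuals` data frame
#'   attached as attribute.
#' @export
run_calibrate <- function(path, fit_alpha = FALSE, output_json = NULL,
                          output_residuals = NULL, ...) {
  header <- names(read.csv(path, nrows = 1))
  passes <- if ("port" %in% header) {
    passes_from_measurements(read_measurements(path))
  } else {
    read_pass_results(path)
  }
  dots <- list(...)
  res <- fit_k0a(passes, fit_alpha = fit_alpha, ...)
  used <- passes[passes$c_al_mg_l != passes$cd_mg_l & passes$c_al_mg_l > 0, ,
                 drop = FALSE]
  alpha <- if (is.na(res$alpha_hat)) 1 else res$alpha_hat
  fitted <- .extraction_model(
    used, res$k0a_hat, alpha,
    sieving_membrane = if (is.null(dots$sieving_membrane)) 1 else dots$sieving_membrane,
    permeability_reduction = if (is.null(dots$permeability_reduction)) 0 else dots$permeability_reduction,
    geometry = if (is.null(dots$geometry)) "countercurrent" else dots$geometry
  )
  resid <- data.frame(
    setting = used$setting, cd_mg_l = used$cd_mg_l,
    extraction_obs = (used$c_rl_mg_l - used$c_al_mg_l) / used$c_al_mg_l,
    extraction_fit = fitted
  )
  resid$residual <- resid$extraction_obs - resid$extraction_fit
  if (!is.null(output_json)) {
    jsonlite::write_json(unclass(res), output_json, auto_unbox = TRUE,
                         digits = NA)
  }
  if (!is.null(output_residuals)) {
    write.csv(resid, output_residuals, row.names = FALSE, quote = FALSE)
  }
  attr(res, "residuals") <- resid
  res
}
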