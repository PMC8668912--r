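#' Spectrophotometric assay parameters
#'
#' Beer-Lambert quantification at a single wavelength (300 nm for
#' meropenem). The extinction coefficient is instrument/compound specific
#' and must be supplied; no default is asserted. `noise_cv` is the
#' coefficient of variation of the multiplicative measurement noise used
#' by the synthetic generator.
#'
#' @param extinction_coefficient Absorbance·L·mg^-1·cm^-1, `> 0`.
#' @param wavelength_nm Wavelength, nm; 300 by convention here.
#' @param path_length_cm Cuvette path length, cm; default 1.
#' @param noise_cv CV of multiplicative noise on absorbance in \[0, 1);
#'   default 0.02, typical of UV spectrophotometry.
#' @return An object of class `assay_params`.
#' @examples
#' assay_params(extinction_coefficient = 1)
#' @export
assay_params <- function(extinction_coefficient,
                         wavelength_nm = 300,
                         path_length_cm = 1,
                         noise_cv = 0.02) {
  if (missing(extinction_coefficient)) {
    stop("`extinction_coefficient` is required configuration (no default)",
         call. = FALSE)
  }
  stopifnot(extinction_coefficient > 0, path_length_cm > 0,
            noise_cv >= 0, noise_cv < 1)
  structure(
    list(
      wavelength = wavelength_nm,
      extinction_coefficient = extinction_coefficient,
      path_length = path_length_cm,
      noise_cv = noise_cv
    ),
    class = "assay_params"
  )
}

#' Beer-Lambert conversions
#'
#' `absorbance_to_concentration()` computes
#' `C = A / (extinction_coefficient * path_length)`;
#' `concentration_to_absorbance()` is its exact inverse.
#'
#' @param a Absorbance, dimensionless, `>= 0`.
#' @param conc Concentration, mg/L, `>= 0`.
#' @param assay An [assay_params()].
#' @return Concentration in mg/L, or absorbance.
#' @examples
#' ap <- assay_params(extinction_coefficient = 0.8)
#' absorbance_to_concentration(concentration_to_absorbance(16, ap), ap)
#' @export
absorbance_to_concentration <- function(a, assay) {
  stopifnot(inherits(assay, "assay_params"))
  if (any(!is.finite(a)) || any(a < 0)) {
    stop("absorbance must be finite and nonnegative", call. = FALSE)
  }
  a / (assay$extinction_coefficient * assay$path_length)
}

#' @rdname absorbance_to_concentration
#' @export
concentration_to_absorbance <- function(conc, assay) {
  stopifnot(inherits(assay, "assay_params"))
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("concentration must be finite and nonnegative", call. = FALSE)
  }
  conc * assay$extinction_coefficient * assay$path_length
}

#' Control-sample stability check
#'
#' Operationalises "no significant change" in the container controls
#' (samples at 0, 2 and 4 h) as a relative-range criterion:
#' `(max - min) / mean` of the control concentrations must not exceed
#' `tolerance`. A relative range is used rather than a hypothesis test
#' because three single measurements support nothing stronger. The
#' statistic is reported either way and is invariant to the order of the
#' inputs.
#'
#' @param controls Numeric vector of control concentrations (mg/L), or a
#'   data frame of measurement records from which rows with
#'   `port == "CONTROL"` are taken.
#' @param tolerance Relative tolerance; default 0.05.
#' @return A list with `pass` (logical), `max_relative_deviation`, `n`.
#' @examples
#' stability_check(c(16, 16.2, 15.9))
#' @export
stability_check <- function(controls, tolerance = 0.05) {
  if (is.data.frame(controls)) {
    if (!all(c("port", "concentration_mg_l") %in% names(controls))) {
      stop("data-frame input needs `port` and `concentration_mg_l` columns",
           call. = FALSE)
    }
    controls <- controls$concentration_mg_l[controls$port == "CONTROL"]
  }
  controls <- as.numeric(controls)
  if (length(controls) < 2) {
    stop("stability check needs at least 2 control measurements", call. = FALSE)
  }
  dev <- (max(controls) - min(controls)) / mean(controls)
  list(pass = dev <= tolerance, max_relative_deviation = dev,
       n = length(controls))
}

#' Build one measurement record
#'
#' One sampled observation at a port of the circuit. Either the absorbance
#' or the concentration (or both) must be present; when both are given
#' they must satisfy Beer-Lambert under `assay` to relative tolerance
#' 1e-9.
#'
#' @param port `"AL"`, `"RL"`, `"EL"` or `"CONTROL"`.
#' @param time_min Sampling time, min.
#' @param setting_label Flow-setting label.
#' @param assay An [assay_params()].
#' @param absorbance Optional absorbance.
#' @param concentration_mg_l Optional concentration, mg/L.
#' @param replicate Replicate index, `>= 1`.
#' @param cd_mg_l,qb_ml_min,qd_ml_h Scenario descriptors carried along so
#'   a record set is self-contained for calibration.
#' @return A one-row data frame.
#' @export
measurement_record <- function(port, time_min, setting_label, assay,
                               absorbance = NA_real_,
                               concentration_mg_l = NA_real_,
                               replicate = 1L,
                               cd_mg_l = NA_real_, qb_ml_min = NA_real_,
                               qd_ml_h = NA_real_) {
  port <- match.arg(port, c("AL", "RL", "EL", "CONTROL"))
  stopifnot(replicate >= 1)
  if (is.na(absorbance) && is.na(concentration_mg_l)) {
    stop("at least one of `absorbance` and `concentration_mg_l` is required",
         call. = FALSE)
  }
  if (is.na(concentration_mg_l)) {
    concentration_mg_l <- absorbance_to_concentration(absorbance, assay)
  } else if (is.na(absorbance)) {
    absorbance <- concentration_to_absorbance(concentration_mg_l, assay)
  } else {
    implied <- absorbance_to_concentration(absorbance, assay)
    if (abs(implied - concentration_mg_l) >
        1e-9 * max(1, abs(concentration_mg_l))) {
      stop("absorbance and concentration are inconsistent under Beer-Lambert",
           call. = FALSE)
    }
  }
  data.frame(port = port, time_min = time_min, absorbance = absorbance,
             concentration_mg_l = concentration_mg_l,
             setting_label = setting_label, replicate = as.integer(replicate),
             cd_mg_l = cd_mg_l, qb_ml_min = qb_ml_min, qd_ml_h = qd_ml_h,
             stringsAsFactors = FALSE)
}

#' Read / write measurement tables
#'
#' Measurement tables are CSV with columns `port, time_min, absorbance,
#' concentration_mg_l, setting_label, replicate, cd_mg_l, qb_ml_min,
#' qd_ml_h`. `read_measurements()` validates the schema and reports
#' offending rows.
#'
#' @param path CSV path.
#' @param records Data frame of measurement records.
#' @return A validated data frame (`read_measurements`); the data invisibly
#'   (`write_measurements`).
#' @export
read_measurements <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("port", "time_min", "concentration_mg_l", "setting_label",
            "replicate")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("measurement table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) stop("measurement table is empty", call. = FALSE)
  bad_port <- which(!df$port %in% c("AL", "RL", "EL", "CONTROL"))
  if (length(bad_port)) {
    stop("invalid port at row(s): ", paste(bad_port, collapse = ", "),
         call. = FALSE)
  }
  bad_conc <- which(!is.finite(df$concentration_mg_l) |
                      df$concentration_mg_l < 0)
  if (length(bad_conc)) {
    stop("invalid concentration at row(s): ", paste(bad_conc, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname read_measurements
#' @export
write_measurements <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(records)
}

#' Per-pass table from long measurement records
#'
#' Pivots AL/RL/EL measurement records into the wide per-pass schema used
#' by [fit_k0a()], one row per (setting, dialysate level, replicate, time).
#'
#' @param records Measurement data frame (see [read_measurements()]).
#' @return Data frame with columns `setting, qb_ml_min, qd_ml_h, cd_mg_l,
#'   c_al_mg_l, c_rl_mg_l, c_el_mg_l`.
#' @export
passes_from_measurements <- function(records) {
  df <- records[records$port %in% c("AL", "RL", "EL"), , drop = FALSE]
  if (nrow(df) == 0) stop("no AL/RL/EL records found", call. = FALSE)
  key <- interaction(df$setting_label, df$cd_mg_l, df$replicate, df$time_min,
                     drop = TRUE)
  out <- lapply(split(df, key), function(g) {
    grab <- function(p) {
      v <- g$concentration_mg_l[g$port == p]
      if (length(v)) v[1] else NA_real_
    }
    data.frame(
      setting = g$setting_label[1],
      qb_ml_min = g$qb_ml_min[1], qd_ml_h = g$qd_ml_h[1],
      cd_mg_l = g$cd_mg_l[1],
      c_al_mg_l = grab("AL"), c_rl_mg_l = grab("RL"), c_el_mg_l = grab("EL"),
      replicate = g$replicate[1], time_min = g$time_min[1],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$setting, out$cd_mg_l, out$replicate), , drop = FALSE]
}
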