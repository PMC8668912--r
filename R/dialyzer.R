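#' Dialyzer membrane and transport parameters
#'
#' Lumped parameters of the diffusive transport model. `k0a` is the overall
#' mass-transfer-area coefficient of the filter (ml/min), the single
#' parameter of the classical dialyzer clearance model. `sieving_membrane`
#' is the equilibrium partition of the solute across the membrane (1 for
#' unhindered passage, as observed for meropenem on an open high-flux
#' filter; 0.93 is the nominal literature value). `alpha_backfiltration`
#' multiplies clearance when the net flux runs dialysate-to-blood, a
#' one-parameter stand-in for back-filtration effects; 1 recovers a
#' symmetric membrane. `permeability_reduction` scales `k0a` down by a
#' fraction (e.g. progressive membrane fouling); the bench circuit showed
#' none, so the default is 0.
#'
#' @param k0a Mass-transfer-area coefficient, ml/min, `>= 0`.
#' @param sieving_membrane Dimensionless partition in (0, 1].
#' @param alpha_backfiltration Positive multiplier on dialysate-to-blood
#'   clearance; default 1 (symmetric).
#' @param permeability_reduction Fraction in \[0, 1) scaling `k0a` down.
#' @param geometry `"countercurrent"` (default; standard CVVHD filters) or
#'   `"cocurrent"`.
#'
#' @return An object of class `dialyzer_params`.
#' @examples
#' dialyzer_params(k0a = 45)
#' @export
dialyzer_params <- function(k0a,
                            sieving_membrane = 1,
                            alpha_backfiltration = 1,
                            permeability_reduction = 0,
                            geometry = c("countercurrent", "cocurrent")) {
  geometry <- match.arg(geometry)
  stopifnot(is.numeric(k0a), length(k0a) == 1L, is.finite(k0a), k0a >= 0)
  if (!(sieving_membrane > 0 && sieving_membrane <= 1)) {
    stop("`sieving_membrane` must lie in (0, 1]", call. = FALSE)
  }
  if (!(alpha_backfiltration > 0)) {
    stop("`alpha_backfiltration` must be positive", call. = FALSE)
  }
  if (!(permeability_reduction >= 0 && permeability_reduction < 1)) {
    stop("`permeability_reduction` must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(
      k0a = as.numeric(k0a),
      sieving_membrane = as.numeric(sieving_membrane),
      alpha_backfiltration = as.numeric(alpha_backfiltration),
      permeability_reduction = as.numeric(permeability_reduction),
      geometry = geometry
    ),
    class = "dialyzer_params"
  )
}

#' @export
print.dialyzer_params <- function(x, ...) {
  cat(sprintf(
    "<dialyzer_params> K0A = %g ml/min, sieving = %g, alpha_bf = %g, perm_red = %g, %s\n",
    x$k0a, x$sieving_membrane, x$alpha_backfiltration,
    x$permeability_reduction, x$geometry
  ))
  invisible(x)
}

# Standard single-solute exchanger clearance for streams qb*, qd (ml/min)
# and transfer coefficient A (ml/min). Countercurrent:
#   N = A/qb*, R = qb*/qd,
#   K = qb* (e^{N(1-R)} - 1) / (e^{N(1-R)} - R), K = qb* N/(1+N) at R = 1.
# Cocurrent: K = qb* (1 - e^{-N(1+R)}) / (1 + R).
# The exponent is guarded: large positive arguments hit the analytic
# saturation limit qb* instead of overflowing; large negative arguments
# underflow harmlessly to the qd limit.
.exchanger_clearance <- function(qb_star, qd, A, geometry) {
  if (A <= 0) return(0)
  N <- A / qb_star
  R <- qb_star / qd
  if (geometry == "cocurrent") {
    x <- -N * (1 + R)
    return(qb_star * (1 - exp(x)) / (1 + R))
  }
  if (abs(R - 1) <= 1e-9) {
    return(qb_star * N / (1 + N))
  }
  x <- N * (1 - R)
  if (x > 700) {           # e^x would overflow; limit of the ratio is 1
    return(qb_star)
  }
  ex <- exp(x)             # x very negative: ex underflows to 0, K -> qd
  qb_star * (ex - 1) / (ex - R)
}

#' Diffusive dialyzer clearance
#'
#' Clearance of the dialyzer under the classical K0A diffusive model,
#' purely diffusive (no convection or ultrafiltration). A membrane
#' partition (sieving) `s < 1` is handled by the equivalent-flow
#' substitution: with transmembrane flux proportional to
#' `s * C_blood - C_dialysate`, the blood stream behaves as an unhindered
#' stream of flow `qb / s`, and blood-side clearance is
#' `K = s * F(qb / s, qd, A)` with `A = k0a * (1 - permeability_reduction)`
#' and `F` the standard countercurrent (or cocurrent) exchanger solution.
#' At `s = 1` this is the textbook formula. Limits: `K -> s * A` as
#' `k0a -> 0`; `K -> min(qb, s * qd)` as `k0a -> Inf` (countercurrent).
#'
#' @param flows A [flow_setting()].
#' @param params A [dialyzer_params()].
#' @return Clearance in ml/min, in `[0, min(qb, qd)]`.
#' @examples
#' clearance(flow_setting(150, 2000), dialyzer_params(k0a = 50))
#' @export
clearance <- function(flows, params) {
  stopifnot(inherits(flows, "flow_setting"), inherits(params, "dialyzer_params"))
  s <- params$sieving_membrane
  A <- params$k0a * (1 - params$permeability_reduction)
  s * .exchanger_clearance(flows$qb / s, flows$qd, A, params$geometry)
}

#' One pass through the dialyzer
#'
#' Transforms the access-line (blood inlet) concentration into return-line
#' and effluent-line concentrations for a single transit at fixed flows.
#' The direction of net flux selects the effective clearance: loss
#' (blood-to-dialysate, `cd_in <= c_al`) uses [clearance()] directly;
#' enrichment (dialysate-to-blood) multiplies it by
#' `alpha_backfiltration`, capped at `min(qb, qd)` so concentrations stay
#' within physical bounds. Solute mass is conserved across the filter:
#' `qb * (c_al - c_rl) == qd * (c_el - cd_in)`.
#'
#' @param c_al Access-line (inlet blood) concentration, mg/L, `>= 0`.
#' @param cd_in Fresh dialysate concentration, mg/L, `>= 0`.
#' @param flows A [flow_setting()].
#' @param params A [dialyzer_params()].
#' @return An object of class `pass_result`: a list with `c_al`, `c_rl`,
#'   `c_el`, `cd_in` (mg/L), `clearance` (the direction-adjusted effective
#'   clearance, ml/min) and `extraction` (`(c_rl - c_al)/c_al`, signed;
#'   negative = loss; `NA` when `c_al == 0`).
#' @examples
#' # equal concentrations on both sides: nothing moves
#' single_pass(16, 16, flow_setting(150, 2000), dialyzer_params(k0a = 500))
#' @export
single_pass <- function(c_al, cd_in, flows, params) {
  stopifnot(inherits(flows, "flow_setting"), inherits(params, "dialyzer_params"))
  if (!is.numeric(c_al) || length(c_al) != 1L || !is.finite(c_al) || c_al < 0) {
    stop("`c_al` must be a single nonnegative concentration (mg/L)", call. = FALSE)
  }
  if (!is.numeric(cd_in) || length(cd_in) != 1L || !is.finite(cd_in) || cd_in < 0) {
    stop("`cd_in` must be a single nonnegative concentration (mg/L)", call. = FALSE)
  }
  k <- clearance(flows, params)
  k_dir <- if (cd_in <= c_al) k else min(params$alpha_backfiltration * k,
                                         min(flows$qb, flows$qd))
  grad <- c_al - cd_in
  c_rl <- c_al - (k_dir / flows$qb) * grad
  c_el <- cd_in + (k_dir / flows$qd) * grad
  extraction <- if (c_al > 0) (c_rl - c_al) / c_al else NA_real_
  structure(
    list(
      c_al = c_al, c_rl = c_rl, c_el = c_el, cd_in = cd_in,
      clearance = k_dir, extraction = extraction,
      flows = flows
    ),
    class = "pass_result"
  )
}

#' @export
print.pass_result <- function(x, ...) {
  cat(sprintf(
    "<pass_result> AL %.4g -> RL %.4g mg/L (dialysate in %.4g -> effluent %.4g); K = %.4g ml/min, extraction = %s\n",
    x$c_al, x$c_rl, x$cd_in, x$c_el, x$clearance,
    if (is.na(x$extraction)) "undefined (c_al = 0)"
    else sprintf("%+.2f%%", 100 * x$extraction)
  ))
  invisible(x)
}

#' Per-pass percent change in blood concentration
#'
#' Signed percent change between access and return lines:
#' `100 * (c_rl - c_al) / c_al`. Negative values are drug loss to the
#' dialysate; positive values are enrichment gain from a drug-loaded
#' dialysate.
#'
#' @param pass A `pass_result` from [single_pass()].
#' @return Signed percent.
#' @examples
#' p <- single_pass(16, 0, flow_setting(100, 3000), dialyzer_params(k0a = 46))
#' percent_change(p)
#' @export
percent_change <- function(pass) {
  stopifnot(inherits(pass, "pass_result"))
  if (pass$c_al <= 0) {
    stop("percent change is undefined when the access-line concentration is 0",
         call. = FALSE)
  }
  100 * (pass$c_rl - pass$c_al) / pass$c_al
}

#' Estimate the sieving coefficient from a pass
#'
#' The effluent-to-inlet concentration ratio `c_el / c_al`. In the
#' saturation regime (very large `k0a`, dialysate flow well below blood
#' flow, unenriched dialysate) the spent dialysate equilibrates with inlet
#' blood and the ratio approaches the membrane partition
#' `sieving_membrane`; an open filter with unobstructed drug movement
#' yields a ratio near 1.
#'
#' @param c_el Effluent concentration, mg/L.
#' @param c_al Access-line concentration, mg/L, `> 0`.
#' @return Dimensionless ratio.
#' @examples
#' p <- single_pass(16, 0, flow_setting(200, 1000), dialyzer_params(k0a = 1e4))
#' estimate_sieving(p$c_el, p$c_al)  # ~ 1
#' @export
estimate_sieving <- function(c_el, c_al) {
  if (!is.numeric(c_al) || length(c_al) != 1L || c_al <= 0) {
    stop("sieving estimate is undefined when `c_al` is 0", call. = FALSE)
  }
  c_el / c_al
}

#' Serialize per-pass results
#'
#' Writes a table of pass results in the package's per-pass CSV schema
#' (`setting, qb_ml_min, qd_ml_h, cd_mg_l, c_al_mg_l, c_rl_mg_l, c_el_mg_l,
#' clearance_ml_min, extraction_pct`).
#'
#' @param passes A list of `pass_result` objects or a data frame already in
#'   the schema.
#' @param path Output CSV path.
#' @return The data frame written, invisibly.
#' @export
write_pass_results <- function(passes, path) {
  df <- if (is.data.frame(passes)) passes else pass_results_table(passes)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' @rdname write_pass_results
#' @export
pass_results_table <- function(passes) {
  stopifnot(is.list(passes), length(passes) > 0)
  rows <- lapply(passes, function(p) {
    stopifnot(inherits(p, "pass_result"))
    data.frame(
      setting = p$flows$label,
      qb_ml_min = p$flows$qb,
      qd_ml_h = p$flows$qd_input,
      cd_mg_l = p$cd_in,
      c_al_mg_l = p$c_al,
      c_rl_mg_l = p$c_rl,
      c_el_mg_l = p$c_el,
      clearance_ml_min = p$clearance,
      extraction_pct = if (is.na(p$extraction)) NA_real_ else 100 * p$extraction,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Read a per-pass results table
#'
#' @param path CSV path in the schema written by [write_pass_results()].
#' @return A data frame.
#' @export
read_pass_results <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("qb_ml_min", "qd_ml_h", "cd_mg_l", "c_al_mg_l", "c_rl_mg_l")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("per-pass table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}
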