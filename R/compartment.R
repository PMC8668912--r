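#' Solute pharmacokinetic constants
#'
#' Constants of the circulating solute. Defaults are meropenem:
#' molecular weight 383.5 Da, 2% protein bound, distribution volume 21 L,
#' and 16 mg/L as the starting concentration in the bench container
#' (four-fold the MIC of the common ICU flora and the target of a
#' continuous-infusion regimen). The bench circuit uses protein binding 0
#' (the "blood" is dialysate); patient-mode simulations use the binding so
#' that only the free fraction is exposed to the membrane.
#'
#' @param molecular_weight Da.
#' @param protein_binding Bound fraction in \[0, 1).
#' @param vd Distribution volume, L.
#' @param container_start_conc Starting container concentration, mg/L.
#' @return An object of class `solute_pk`; `free_fraction` is
#'   `1 - protein_binding`.
#' @examples
#' solute_pk()           # meropenem defaults
#' solute_pk(protein_binding = 0)  # bench mode
#' @export
solute_pk <- function(molecular_weight = 383.5,
                      protein_binding = 0.02,
                      vd = 21,
                      container_start_conc = 16) {
  if (!(protein_binding >= 0 && protein_binding < 1)) {
    stop("`protein_binding` must lie in [0, 1)", call. = FALSE)
  }
  stopifnot(vd > 0, container_start_conc >= 0, molecular_weight > 0)
  structure(
    list(
      molecular_weight = molecular_weight,
      protein_binding = protein_binding,
      free_fraction = 1 - protein_binding,
      vd = vd,
      container_start_conc = container_start_conc
    ),
    class = "solute_pk"
  )
}

#' Well-mixed compartment state
#'
#' @param volume_l Compartment volume, L (25 for the bench container;
#'   patient mode uses the distribution volume). Constant over a
#'   simulation: the circuit is open, effluent goes to waste and fresh
#'   dialysate replaces it on the dialysate side only.
#' @param conc_mg_l Concentration, mg/L, `>= 0`.
#' @param time_min Clock, minutes.
#' @return An object of class `compartment_state`.
#' @export
compartment_state <- function(volume_l = 25, conc_mg_l = 16, time_min = 0) {
  stopifnot(volume_l > 0, conc_mg_l >= 0)
  structure(
    list(volume = volume_l, concentration = conc_mg_l, time = time_min),
    class = "compartment_state"
  )
}

#' Free (unbound) concentration
#'
#' Only unbound drug crosses the membrane; the transport operations see
#' `total * free_fraction` on the blood side whenever protein binding is
#' nonzero. In bench mode (binding 0) free equals total.
#'
#' @param total Total concentration, mg/L, `>= 0`.
#' @param pk A [solute_pk()].
#' @return Free concentration, mg/L.
#' @examples
#' free_concentration(16, solute_pk())  # 15.68
#' @export
free_concentration <- function(total, pk) {
  stopifnot(inherits(pk, "solute_pk"))
  if (any(total < 0)) stop("`total` must be nonnegative", call. = FALSE)
  total * pk$free_fraction
}

# Direction-resolved effective clearance for a blood-side (free)
# concentration against fresh dialysate cd, per single_pass() logic.
.k_directional <- function(c_free, cd, flows, params) {
  k <- clearance(flows, params)
  if (cd <= c_free) k else min(params$alpha_backfiltration * k,
                               min(flows$qb, flows$qd))
}

#' Simulate the open bench container
#'
#' Integrates the well-mixed container recirculated through the dialyzer:
#' `V dC/dt = -K_dir(C) * (C - cd)` with `K` in ml/min and `V` in L (hence
#' the factor 1000). When the membrane is symmetric
#' (`alpha_backfiltration = 1`) the equation is linear with constant
#' coefficient and the exact exponential solution
#' `C(t) = cd + (C0 - cd) * exp(-K t / (1000 V))` is used directly;
#' otherwise (or on request) `deSolve::lsoda` integrates numerically.
#' The trajectory relaxes monotonically toward `cd` and never crosses it.
#'
#' @param initial A [compartment_state()].
#' @param cd Fresh dialysate concentration, mg/L.
#' @param flows A [flow_setting()].
#' @param params A [dialyzer_params()].
#' @param duration Horizon, min, `>= 0`.
#' @param step Output step, min, `> 0`. A step longer than the horizon
#'   falls back to a single step with a warning.
#' @param method `"auto"` (closed form when exact, else numeric),
#'   `"closed_form"` or `"numeric"`.
#' @return A data frame with columns `time_min`, `conc_mg_l` and
#'   `cumulative_effluent_mg` (net solute mass exported to the effluent,
#'   i.e. effluent export minus dialysate import; equals the container's
#'   mass loss).
#' @examples
#' sim <- simulate_container(compartment_state(25, 16), cd = 0,
#'                           flow_setting(100, 3000),
#'                           dialyzer_params(k0a = 46), duration = 240,
#'                           step = 10)
#' tail(sim, 1)
#' @export
simulate_container <- function(initial, cd, flows, params, duration, step,
                               method = c("auto", "closed_form", "numeric")) {
  method <- match.arg(method)
  stopifnot(inherits(initial, "compartment_state"),
            inherits(flows, "flow_setting"),
            inherits(params, "dialyzer_params"),
            cd >= 0, duration >= 0)
  if (step <= 0) stop("`step` must be positive", call. = FALSE)
  if (duration == 0) {
    return(data.frame(time_min = initial$time,
                      conc_mg_l = initial$concentration,
                      cumulative_effluent_mg = 0))
  }
  if (step > duration) {
    warning("`step` exceeds `duration`; using a single step", call. = FALSE)
    step <- duration
  }
  times <- seq(0, duration, by = step)
  if (times[length(times)] < duration) times <- c(times, duration)
  V <- initial$volume        # L
  C0 <- initial$concentration

  # The gradient sign never changes (C relaxes toward cd without crossing),
  # so K_dir is constant along the whole trajectory and the closed form is
  # exact even with alpha != 1.
  k_dir <- .k_directional(C0, cd, flows, params)
  use_closed <- method == "closed_form" ||
    (method == "auto" && params$geometry %in% c("countercurrent", "cocurrent"))
  if (use_closed) {
    conc <- cd + (C0 - cd) * exp(-k_dir * times / (1000 * V))
  } else {
    rhs <- function(t, y, parms) {
      k <- .k_directional(y[1], cd, flows, params)
      list(c(-k / (1000 * V) * (y[1] - cd), k / 1000 * (y[1] - cd)))
    }
    sol <- deSolve::lsoda(c(C = C0, M = 0), times, rhs, parms = NULL,
                          rtol = 1e-10, atol = 1e-12)
    conc <- sol[, "C"]
  }
  # net mass exported equals the container's mass loss (volume constant)
  cum_effluent <- 1000 * V * (C0 - conc) / 1000  # mg: V [L] * dC [mg/L]
  data.frame(time_min = initial$time + times,
             conc_mg_l = as.numeric(conc),
             cumulative_effluent_mg = as.numeric(cum_effluent))
}

#' Simulate a one-compartment patient on CVVHD
#'
#' One-compartment kinetics with a constant-rate infusion, linear body
#' clearance, and dialytic exchange of the free drug:
#' `V dC/dt = infusion_rate/60 - (body_clearance/1000) C
#'            - (K_dir/1000) (free_fraction C - cd)`.
#' `K_dir` follows the same direction logic as [single_pass()]: loss-side
#' clearance when the free blood concentration exceeds the dialysate,
#' `alpha_backfiltration`-scaled (capped) clearance otherwise. Integration
#' uses `deSolve::lsoda`; the trajectory is monotone toward the steady
#' state from any start.
#'
#' @param pk A [solute_pk()].
#' @param infusion_rate mg/h, `>= 0`.
#' @param body_clearance Non-dialytic clearance, ml/min, `>= 0`.
#' @param cd Dialysate drug concentration, mg/L.
#' @param flows A [flow_setting()].
#' @param params A [dialyzer_params()].
#' @param duration Horizon, min.
#' @param step Output step, min.
#' @param c0 Starting total concentration, mg/L; defaults to 0.
#' @return A data frame `time_min`, `conc_mg_l`.
#' @seealso [patient_steady_state()] for the analytic fixed point.
#' @export
simulate_patient <- function(pk, infusion_rate, body_clearance, cd, flows,
                             params, duration, step = duration / 200,
                             c0 = 0) {
  stopifnot(inherits(pk, "solute_pk"), infusion_rate >= 0,
            body_clearance >= 0, cd >= 0, duration > 0, c0 >= 0)
  times <- seq(0, duration, by = step)
  if (times[length(times)] < duration) times <- c(times, duration)
  V <- pk$vd
  ff <- pk$free_fraction
  rhs <- function(t, y, parms) {
    cf <- ff * y[1]
    k <- .k_directional(cf, cd, flows, params)
    dC <- (infusion_rate / 60 - (body_clearance / 1000) * y[1] -
             (k / 1000) * (cf - cd)) / V
    list(dC)
  }
  sol <- deSolve::lsoda(c(C = c0), times, rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  data.frame(time_min = as.numeric(sol[, "time"]),
             conc_mg_l = as.numeric(sol[, "C"]))
}

#' Analytic patient steady state
#'
#' Fixed point of the patient equation for a given flux direction:
#' `C_ss = (infusion_rate/60 + (K/1000) cd) /
#'         ((body_clearance + K free_fraction)/1000)`.
#' The direction (hence which effective `K` applies) is resolved
#' self-consistently: the loss-side solution is returned when it is
#' consistent (`free_fraction * C_ss >= cd`), else the gain-side one.
#'
#' @inheritParams simulate_patient
#' @return Steady-state total concentration, mg/L.
#' @export
patient_steady_state <- function(pk, infusion_rate, body_clearance, cd,
                                 flows, params) {
  stopifnot(inherits(pk, "solute_pk"))
  ff <- pk$free_fraction
  k <- clearance(flows, params)
  k_gain <- min(params$alpha_backfiltration * k, min(flows$qb, flows$qd))
  css <- function(kd) {
    denom <- (body_clearance + kd * ff) / 1000
    if (denom == 0) {
      if (infusion_rate > 0) return(Inf)
      return(if (kd > 0) cd / ff else NA_real_)
    }
    (infusion_rate / 60 + (kd / 1000) * cd) / denom
  }
  c_loss <- css(k)
  if (is.na(c_loss) || ff * c_loss >= cd) return(c_loss)
  css(k_gain)
}
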