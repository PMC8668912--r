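#' Blood/dialysate flow setting
#'
#' Bundles one combination of blood flow and dialysate flow. Dialysate flow
#' is prescribed at the machine in ml/h while all transport arithmetic runs
#' in ml/min; the conversion happens here, exactly once, so no downstream
#' code ever divides by 60 again.
#'
#' @param qb_ml_min Blood flow, ml/min. Must be positive.
#' @param qd_ml_h Dialysate flow as prescribed, ml/h. Must be positive.
#' @param label Optional text identifier (e.g. `"QB2QD1"`). Defaults to a
#'   label built from the two flows.
#'
#' @return An object of class `flow_setting` with fields `qb` (ml/min),
#'   `qd_input` (ml/h), `qd` (ml/min, `qd_input / 60` exactly) and `label`.
#'
#' @examples
#' fs <- flow_setting(150, 2000)
#' fs$qd  # 2000/60 ml/min
#' @export
flow_setting <- function(qb_ml_min, qd_ml_h, label = NULL) {
  if (!is.numeric(qb_ml_min) || length(qb_ml_min) != 1L || !is.finite(qb_ml_min) ||
      qb_ml_min <= 0) {
    stop("`qb_ml_min` must be a single positive number (ml/min)", call. = FALSE)
  }
  if (!is.numeric(qd_ml_h) || length(qd_ml_h) != 1L || !is.finite(qd_ml_h) ||
      qd_ml_h <= 0) {
    stop("`qd_ml_h` must be a single positive number (ml/h)", call. = FALSE)
  }
  if (is.null(label)) {
    label <- sprintf("QB%gQD%g", qb_ml_min, qd_ml_h)
  }
  structure(
    list(
      qb = as.numeric(qb_ml_min),
      qd_input = as.numeric(qd_ml_h),
      qd = as.numeric(qd_ml_h) / 60,
      label = as.character(label)
    ),
    class = "flow_setting"
  )
}

#' @export
print.flow_setting <- function(x, ...) {
  cat(sprintf("<flow_setting %s> Qb = %g ml/min, Qd = %g ml/h (%.4g ml/min)\n",
              x$label, x$qb, x$qd_input, x$qd))
  invisible(x)
}

#' The bench flow grid
#'
#' The nine blood-flow/dialysate-flow combinations of the bench design:
#' blood flow 100/150/200 ml/min crossed with dialysate flow
#' 1000/2000/3000 ml/h, labelled `QB1QD1` ... `QB3QD3`.
#'
#' @param qb_levels Blood flows, ml/min.
#' @param qd_levels Dialysate flows, ml/h.
#' @return A list of [flow_setting()] objects, dialysate flow varying fastest.
#' @examples
#' length(flow_grid())  # 9
#' @export
flow_grid <- function(qb_levels = c(100, 150, 200),
                      qd_levels = c(1000, 2000, 3000)) {
  out <- list()
  for (i in seq_along(qb_levels)) {
    for (j in seq_along(qd_levels)) {
      out[[length(out) + 1L]] <- flow_setting(
        qb_levels[i], qd_levels[j],
        label = sprintf("QB%dQD%d", i, j)
      )
    }
  }
  out
}
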