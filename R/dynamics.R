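#' Nullclines of the original or N-LUT model
#'
#' The V-nullcline is `W = ADX(V) + I` (for the proposed model, the table
#' read replaces ADX, so the curve is piecewise constant between addresses);
#' the W-nullcline is `W = a (V - EL)` for both models.
#'
#' @param params an [adex_params()] object or preset name.
#' @param model `"original"` or `"proposed"`.
#' @param lut a [build_lut()] table, required for the proposed model.
#' @param v voltage grid (mV); default 400 points over the LUT range.
#' @return A data frame with columns `V`, `W_vnull`, `W_wnull`.
#' @export
adex_nullclines <- function(params, model = c("original", "proposed"),
                            lut = NULL, v = seq(-60, 10, length.out = 400)) {
  model <- match.arg(model)
  p <- .as_params(params)
  fx <- if (model == "original") {
    adx(v, p)
  } else {
    if (is.null(lut)) stop("proposed-model nullclines need a lut", call. = FALSE)
    lut_lookup(lut, v)
  }
  data.frame(V = v, W_vnull = fx + p$I, W_wnull = p$a * (v - p$EL))
}

#' Jacobian of the two-variable system at a state
#'
#' In `analytic` mode the entries are the true partial derivatives of the
#' update field: for the original model `A1 = (gL/C)(exp((V-VT)/DeltaT) - 1)`,
#' `B1 = -1/C`, `C1 = a/tau_w`, `D1 = -1/tau_w`; for the proposed model the
#' table read is piecewise constant so `A1 = 0` and the rest are unchanged.
#' `paper_table` mode reproduces the reference design's tabulated entries
#' verbatim, including its proposed-row `B1 = -1` (dimensionally
#' inconsistent with the state equation, whose coefficient is `-1/C`; both
#' behaviours are kept so neither reading is silently discarded).
#'
#' @param params an [adex_params()] object or preset name.
#' @param model `"original"` or `"proposed"`.
#' @param state a [neuron_state()] at which to evaluate.
#' @param mode `"analytic"` or `"paper_table"`.
#' @return A list of class `adex_jacobian` with entries `A1`, `B1`, `C1`,
#'   `D1` and a 2x2 `matrix`.
#' @export
adex_jacobian <- function(params, model = c("original", "proposed"), state,
                          mode = c("analytic", "paper_table")) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  p <- .as_params(params)
  A1 <- if (model == "original") {
    (p$gL / p$C) * (exp((state$V - p$VT) / p$DeltaT) - 1)
  } else 0
  B1 <- if (model == "proposed" && mode == "paper_table") -1 else -1 / p$C
  C1 <- p$a / p$tau_w
  D1 <- -1 / p$tau_w
  structure(list(A1 = A1, B1 = B1, C1 = C1, D1 = D1,
                 matrix = matrix(c(A1, B1, C1, D1), 2, 2, byrow = TRUE,
                                 dimnames = list(c("dV", "dW"),
                                                 c("V", "W")))),
            class = "adex_jacobian")
}

#' @export
print.adex_jacobian <- function(x, ...) {
  cat("ADEX Jacobian:\n"); print(x$matrix); invisible(x)
}

#' Phase portrait of a trace
#'
#' The `(V, W)` projection of a trajectory, suitable for overlay plots;
#' resets appear as horizontal jumps back to the reset potential.
#'
#' @param trace a [voltage_trace()].
#' @return A data frame with columns `V`, `W` (one row per sample).
#' @export
phase_portrait <- function(trace) {
  if (!length(trace$t)) stop("empty trace", call. = FALSE)
  data.frame(V = trace$V, W = trace$W)
}
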