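#' ADEX neuron parameters
#'
#' Bundles the ten parameters of the adaptive exponential integrate-and-fire
#' (ADEX) neuron in the unit system pF / nS / mV / pA / ms, in which the two
#' state equations are dimensionally consistent without conversion factors:
#' `C dV/dt = -gL (V - EL) + gL DeltaT exp((V - VT)/DeltaT) + I - W` and
#' `tau_w dW/dt = a (V - EL) - W`.
#'
#' @param C membrane capacitance (pF), positive.
#' @param gL leak conductance (nS).
#' @param EL effective rest potential (mV).
#' @param VT threshold potential (mV).
#' @param DeltaT threshold slope factor (mV), positive.
#' @param a subthreshold adaptation conductance (nS).
#' @param tau_w adaptation time constant (ms), positive.
#' @param b spike-triggered adaptation increment (pA).
#' @param Vr reset potential (mV), below the 0 mV spike-detection apex.
#' @param I stimulus current (pA).
#'
#' @return An object of class `adex_params` (a named list).
#' @seealso [adex_preset()] for the eight canonical firing-pattern parameter
#'   sets.
#' @export
#' @examples
#' p <- adex_params(C = 200, gL = 10, EL = -70, VT = -50, DeltaT = 2,
#'                  a = 2, tau_w = 30, b = 0, Vr = -58, I = 500)
adex_params <- function(C, gL, EL, VT, DeltaT, a, tau_w, b, Vr, I) {
  p <- list(C = C, gL = gL, EL = EL, VT = VT, DeltaT = DeltaT,
            a = a, tau_w = tau_w, b = b, Vr = Vr, I = I)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
  }
  if (C <= 0) stop("C must be positive", call. = FALSE)
  if (tau_w <= 0) stop("tau_w must be positive", call. = FALSE)
  if (DeltaT <= 0) stop("DeltaT must be positive", call. = FALSE)
  if (Vr >= 0) stop("Vr must lie below the 0 mV spike apex", call. = FALSE)
  structure(p, class = "adex_params")
}

#' @export
print.adex_params <- function(x, ...) {
  cat("ADEX parameters (pF/nS/mV/pA/ms):\n")
  print(unlist(unclass(x)))
  invisible(x)
}

# The eight canonical firing-pattern parameter rows.
.preset_table <- list(
  "Tonic spiking"        = c(C = 200, gL = 10,  EL = -70, VT = -50, DeltaT = 2,   a = 2,    tau_w = 30,  b = 0,   Vr = -58, I = 500),
  "Adaptation"           = c(C = 200, gL = 12,  EL = -70, VT = -50, DeltaT = 2,   a = 2,    tau_w = 300, b = 60,  Vr = -58, I = 500),
  "Initial bursting"     = c(C = 130, gL = 18,  EL = -58, VT = -50, DeltaT = 2,   a = 4,    tau_w = 150, b = 120, Vr = -50, I = 400),
  "Delayed accelerating" = c(C = 200, gL = 12,  EL = -70, VT = -50, DeltaT = 2,   a = -10,  tau_w = 300, b = 0,   Vr = -58, I = 300),
  "Irregular spiking"    = c(C = 100, gL = 12,  EL = -60, VT = -50, DeltaT = 2,   a = -11,  tau_w = 130, b = 30,  Vr = -48, I = 160),
  "can"                  = c(C = 59,  gL = 2.9, EL = -62, VT = -42, DeltaT = 3,   a = 1.8,  tau_w = 16,  b = 61,  Vr = -54, I = 184),
  "cAD"                  = c(C = 83,  gL = 1.7, EL = -59, VT = -56, DeltaT = 5.5, a = 2,    tau_w = 41,  b = 55,  Vr = -54, I = 116),
  "RS"                   = c(C = 104, gL = 4.3, EL = -65, VT = -52, DeltaT = 0.8, a = -0.8, tau_w = 88,  b = 65,  Vr = -53, I = 98)
)

#' Canonical firing-pattern presets
#'
#' Returns the exact parameter row for one of the eight named ADEX firing
#' patterns (tonic spiking, adaptation, initial bursting, delayed
#' accelerating, irregular spiking, "can", "cAD", "RS").
#'
#' @param name preset label; see [adex_pattern_names()].
#' @return A list with elements `name` and `params` (an [adex_params()]
#'   object), of class `adex_preset`.
#' @export
#' @examples
#' adex_preset("Tonic spiking")$params$I  # 500 pA
adex_preset <- function(name) {
  if (!is.character(name) || length(name) != 1L || !name %in% names(.preset_table))
    stop("unknown pattern '", paste(name, collapse = ","), "'; valid names: ",
         paste(names(.preset_table), collapse = ", "), call. = FALSE)
  row <- .preset_table[[name]]
  structure(list(name = name, params = do.call(adex_params, as.list(row))),
            class = "adex_preset")
}

#' @rdname adex_preset
#' @export
adex_pattern_names <- function() names(.preset_table)

#' Neuron state
#'
#' A membrane potential / adaptation current pair `(V, W)` in mV / pA.
#'
#' @param V membrane potential (mV).
#' @param W adaptation current (pA).
#' @return An object of class `neuron_state`.
#' @export
neuron_state <- function(V, W) {
  if (!is.finite(V) || !is.finite(W))
    stop("neuron state must be finite", call. = FALSE)
  structure(list(V = V, W = W), class = "neuron_state")
}

# resolve a preset name or adex_params into adex_params
.as_params <- function(p) {
  if (inherits(p, "adex_params")) return(p)
  if (inherits(p, "adex_preset")) return(p$params)
  if (is.character(p)) return(adex_preset(p)$params)
  stop("expected an adex_params object or a preset name", call. = FALSE)
}
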