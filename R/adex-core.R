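#' Voltage nonlinearity of the ADEX neuron
#'
#' Evaluates the voltage-dependent part of `dV/dt`,
#' `ADX(V) = -gL (V - EL) + gL DeltaT exp((V - VT)/DeltaT)` in pA.  This is
#' the term the lookup table replaces.  The exponent argument is clamped at
#' `exp_clamp` so the value stays finite during the single Euler step between
#' threshold crossing and reset.
#'
#' @param V membrane potential (mV); vectorised.
#' @param params an [adex_params()] object or preset name.
#' @param exp_clamp cap on the exponent argument `(V - VT)/DeltaT`
#'   (dimensionless, default 20, i.e. `exp` at most about 4.85e8).
#' @return ADX values in pA.
#' @export
#' @examples
#' p <- adex_preset("Tonic spiking")$params
#' adx(p$VT, p)  # -gL (VT - EL) + gL DeltaT = -180 pA
adx <- function(V, params, exp_clamp = 20) {
  p <- .as_params(params)
  if (any(!is.finite(V)))
    stop("invalid state: V must be finite", call. = FALSE)
  -p$gL * (V - p$EL) + p$gL * p$DeltaT * exp(pmin((V - p$VT) / p$DeltaT, exp_clamp))
}

#' Time derivatives of the ADEX state
#'
#' @param state a [neuron_state()] (or list with `V`, `W`).
#' @param params an [adex_params()] object or preset name.
#' @param exp_clamp exponent cap passed to [adx()].
#' @return Named numeric vector `c(dV = mV/ms, dW = pA/ms)`.
#' @export
adex_derivatives <- function(state, params, exp_clamp = 20) {
  p <- .as_params(params)
  dV <- (adx(state$V, p, exp_clamp) + p$I - state$W) / p$C
  dW <- (p$a * (state$V - p$EL) - state$W) / p$tau_w
  c(dV = dV, dW = dW)
}

#' Post-spike reset
#'
#' Applies the reset rule: when `V` has crossed the 0 mV apex, `V <- Vr` and
#' `W <- W + b`.
#'
#' @inheritParams adex_derivatives
#' @return The reset [neuron_state()].
#' @export
adex_reset <- function(state, params) {
  p <- .as_params(params)
  if (state$V <= 0)
    stop("reset called with V <= 0: no spike has been triggered", call. = FALSE)
  neuron_state(p$Vr, state$W + p$b)
}

#' Construct a voltage trace
#'
#' A uniformly sampled `(t, V, W)` trajectory with recorded spike times.
#' Spike times are the time stamps of samples at which `V` crossed the 0 mV
#' apex; the stored `V` at those samples is the apex value clamped at the top
#' of the operating voltage range.
#'
#' @param t time stamps (ms), uniformly spaced and strictly increasing.
#' @param V membrane potential samples (mV).
#' @param W adaptation current samples (pA).
#' @param spike_times spike time stamps (ms); each must be a member of `t`.
#' @return An object of class `voltage_trace`.
#' @export
voltage_trace <- function(t, V, W, spike_times = numeric(0)) {
  if (length(t) != length(V) || length(t) != length(W))
    stop("t, V, W must have equal length", call. = FALSE)
  if (length(t) > 1 && any(diff(t) <= 0))
    stop("t must be strictly increasing", call. = FALSE)
  if (length(spike_times) &&
      !all(spike_times %in% t))
    stop("every spike time must be a member of t", call. = FALSE)
  structure(list(t = t, V = V, W = W, spike_times = spike_times),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  dt <- if (length(x$t) > 1) x$t[2] - x$t[1] else NA_real_
  cat(sprintf("voltage_trace: %d samples, dt = %g ms, %d spikes, V in [%.2f, %.2f] mV\n",
              length(x$t), dt, length(x$spike_times), min(x$V), max(x$V)))
  invisible(x)
}

#' @export
length.voltage_trace <- function(x) length(x$t)

#' Simulate the original ADEX neuron
#'
#' Forward-Euler integration of the ADEX equations with the exact (clamped)
#' exponential nonlinearity.  At each step, if `V > 0` the spike time is
#' recorded and the reset is applied before the next step.  The trace has
#' `floor(T/dt) + 1` samples; stored `V` is clamped at `apex_clamp` so the
#' one overshooting pre-reset sample stays within the operating range.
#'
#' @param params an [adex_params()] object or preset name.
#' @param dt time step (ms), default 1/128.
#' @param T duration (ms), default 1000; must be at least `dt`.
#' @param init initial [neuron_state()]; default `(max(EL, -60), 0)`, the
#'   rest potential clamped into the operating voltage range.
#' @param exp_clamp exponent cap passed to [adx()].
#' @param apex_clamp stored-apex ceiling (mV), default +10 (top of the
#'   operating range); the dynamics are unaffected.
#' @return A [voltage_trace()].
#' @export
#' @examples
#' tr <- simulate_adex("Tonic spiking", T = 200)
#' length(tr$spike_times)
simulate_adex <- function(params, dt = 1 / 128, T = 1000, init = NULL,
                          exp_clamp = 20, apex_clamp = 10) {
  p <- .as_params(params)
  .check_sim_args(dt, T)
  init <- .default_init(init, p)
  n <- floor(T / dt)
  out <- .sim_adex_cpp(unlist(unclass(p)), dt, n, init$V, init$W,
                       exp_clamp, apex_clamp, FALSE, numeric(0), 0, 1)
  .trace_from_cpp(out, dt, n)
}

.check_sim_args <- function(dt, T) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  if (!is.numeric(T) || T < dt) stop("T must be at least dt", call. = FALSE)
}

.default_init <- function(init, p, v_min = -60) {
  if (is.null(init)) neuron_state(max(p$EL, v_min), 0) else init
}

.trace_from_cpp <- function(out, dt, n) {
  t <- (0:n) * dt
  voltage_trace(t, out$V, out$W, spike_times = t[out$spike_idx + 1L])
}

#' Write / read a voltage trace as CSV
#'
#' The dialect is `t_ms,V_mV,W_pA,spike` with `spike` a 0/1 flag marking the
#' recorded apex samples.
#'
#' @param trace a [voltage_trace()].
#' @param path file path.
#' @return `write_trace_csv` returns `path` invisibly; `read_trace_csv`
#'   returns a [voltage_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  spike <- as.integer(trace$t %in% trace$spike_times)
  df <- data.frame(t_ms = trace$t, V_mV = trace$V, W_pA = trace$W,
                   spike = spike)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("t_ms", "V_mV", "W_pA", "spike") %in% names(df)))
  voltage_trace(df$t_ms, df$V_mV, df$W_pA,
                spike_times = df$t_ms[df$spike == 1])
}
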