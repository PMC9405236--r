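#' Default ceiling for tabulated ADX values
#'
#' The table stores ADX evaluated with the same exponent-argument clamp as the
#' continuous model (default 20), so the table's limit as the point count
#' grows is exactly the simulated original nonlinearity.  A lower ceiling may
#' be supplied to model a narrower memory word; values are then saturated at
#' it.
#' @keywords internal
.default_ceiling <- function(p, exp_clamp = 20) {
  p$gL * p$DeltaT * exp(exp_clamp) + abs(p$gL * (p$VT + exp_clamp * p$DeltaT - p$EL)) + 1
}

#' Tabulate the ADX objective function on a dense grid
#'
#' Evaluates [adx()] on `n_dense` uniform points over `[v_min, v_max]`,
#' saturating each value at `ceiling`.  Used as the input to the spectral
#' bandwidth estimate.
#'
#' @param params an [adex_params()] object or preset name.
#' @param v_min,v_max voltage range (mV); defaults `-60` and `+10`, the
#'   operating range of the digital datapath.
#' @param n_dense number of grid points (at least 64).
#' @param ceiling saturation cap (pA); default `adx(VT + 5 DeltaT)`.  For the
#'   bandwidth analysis the cap bounds the spike-onset upstroke, whose exact
#'   magnitude is irrelevant to the subthreshold shape being sampled; beyond
#'   it the exponential only accelerates an already-certain spike.
#' @param exp_clamp exponent cap passed to [adx()].
#' @return Numeric vector of `n_dense` ADX values (pA).
#' @export
tabulate_objective <- function(params, v_min = -60, v_max = 10,
                               n_dense = 1024, ceiling = NULL,
                               exp_clamp = 20) {
  p <- .as_params(params)
  if (v_min >= v_max) stop("empty voltage range", call. = FALSE)
  if (n_dense < 64) stop("n_dense must be at least 64", call. = FALSE)
  if (is.null(ceiling)) ceiling <- adx(p$VT + 5 * p$DeltaT, p, exp_clamp)
  v <- seq(v_min, v_max, length.out = n_dense)
  pmin(adx(v, p, exp_clamp), ceiling)
}

#' Spectral bandwidth of a sampled objective function
#'
#' Mean-removes and amplitude-normalises the sequence, treats it as occupying
#' one normalised second (so DFT bin k corresponds to k Hz-equivalents), and
#' returns the smallest frequency at which the cumulative non-DC spectral
#' power reaches `power_fraction` of the total.
#'
#' @param values dense objective samples (at least 64).
#' @param power_fraction cumulative-power threshold in (0, 1); default 0.95.
#' @return A list of class `bandwidth_estimate` with `base_frequency`
#'   (Hz-equivalents per normalised span), `power_fraction`, `n_dense`.
#' @export
#' @examples
#' x <- sin(2 * pi * 5 * seq(0, 1, length.out = 256))
#' estimate_bandwidth(x)$base_frequency  # 5
estimate_bandwidth <- function(values, power_fraction = 0.95) {
  n <- length(values)
  if (n < 64) stop("need at least 64 samples", call. = FALSE)
  if (power_fraction <= 0 || power_fraction >= 1)
    stop("power_fraction must lie in (0, 1)", call. = FALSE)
  x <- values - mean(values)
  amp <- max(abs(x))
  base <- 0
  if (amp > 0) {
    x <- x / amp
    pw <- Mod(stats::fft(x))^2
    k <- seq(2, floor(n / 2) + 1)     # one-sided, DC excluded
    cum <- cumsum(pw[k]) / sum(pw[k])
    base <- which(cum >= power_fraction)[1]
  }
  structure(list(base_frequency = base, power_fraction = power_fraction,
                 n_dense = n),
            class = "bandwidth_estimate")
}

#' Nyquist-rate point count
#'
#' Applies the sampling theorem `fs > 2B`: the number of table points is
#' `max(ceil(2 * base_frequency), minimum)`.  The default floor of 20 is the
#' canonical table size for the ADX nonlinearity over its default range.
#'
#' @param est a `bandwidth_estimate` from [estimate_bandwidth()] (or a bare
#'   number taken as the base frequency).
#' @param minimum lower bound on the point count (default 20).
#' @return Integer point count.
#' @export
nyquist_point_count <- function(est, minimum = 20) {
  B <- if (inherits(est, "bandwidth_estimate")) est$base_frequency else est
  if (!is.numeric(B) || length(B) != 1L || !is.finite(B) || B < 0)
    stop("invalid bandwidth estimate", call. = FALSE)
  as.integer(max(ceiling(2 * B), minimum))
}

#' Build a lookup table for the ADX nonlinearity
#'
#' Samples ADX at `n_points` uniform grid points over `[v_min, v_max]`,
#' saturating at `ceiling`.
#'
#' @inheritParams tabulate_objective
#' @param n_points number of table entries (at least 2), default 20.
#' @param ceiling saturation cap (pA) for the stored values.  The runtime
#'   table defaults to the value implied by the model's own exponent clamp,
#'   so that as `n_points` grows the N-LUT dynamics converge to the simulated
#'   original model; a lower cap slows the spike upstroke and is only
#'   appropriate when modelling a narrow memory word.
#' @return An object of class `lut_spec` with fields `v_min`, `v_max`,
#'   `n_points`, `dv`, `values`, `ceiling`, `params`.
#' @export
#' @examples
#' lut <- build_lut("Tonic spiking")
#' lut$n_points  # 20
build_lut <- function(params, v_min = -60, v_max = 10, n_points = 20,
                      ceiling = NULL, exp_clamp = 20) {
  p <- .as_params(params)
  if (v_min >= v_max) stop("empty voltage range", call. = FALSE)
  if (n_points < 2) stop("n_points must be at least 2", call. = FALSE)
  if (is.null(ceiling)) ceiling <- .default_ceiling(p, exp_clamp)
  grid <- seq(v_min, v_max, length.out = n_points)
  vals <- pmin(adx(grid, p, exp_clamp), ceiling)
  structure(list(v_min = v_min, v_max = v_max, n_points = as.integer(n_points),
                 dv = (v_max - v_min) / (n_points - 1), values = vals,
                 ceiling = ceiling, params = p),
            class = "lut_spec")
}

#' @export
print.lut_spec <- function(x, ...) {
  cat(sprintf("lut_spec: %d points over [%g, %g] mV (dv = %.4g), values in [%.4g, %.4g] pA\n",
              x$n_points, x$v_min, x$v_max, x$dv, min(x$values), max(x$values)))
  invisible(x)
}

#' Read a value from the lookup table
#'
#' Nearest-index addressing with end clamping, matching a single memory read:
#' `index = round((V - v_min)/dv)` clamped to `[0, n_points - 1]`.  No
#' interpolation is performed.
#'
#' @param lut a [build_lut()] table.
#' @param V membrane potential (mV); vectorised.
#' @return Stored ADX values (pA).
#' @export
lut_lookup <- function(lut, V) {
  stopifnot(inherits(lut, "lut_spec"))
  if (any(!is.finite(V))) stop("invalid state: V must be finite", call. = FALSE)
  idx <- pmin(pmax(round((V - lut$v_min) / lut$dv), 0), lut$n_points - 1)
  lut$values[idx + 1]
}

#' Simulate the N-LUT ADEX neuron
#'
#' Identical to [simulate_adex()] except the exponential nonlinearity is
#' replaced by [lut_lookup()] reads; reset rule and spike recording are
#' unchanged.
#'
#' @inheritParams simulate_adex
#' @param lut a [build_lut()] table (built for the same parameter set).
#' @return A [voltage_trace()].
#' @export
simulate_nlut <- function(params, lut, dt = 1 / 128, T = 1000, init = NULL,
                          apex_clamp = 10) {
  p <- .as_params(params)
  stopifnot(inherits(lut, "lut_spec"))
  .check_sim_args(dt, T)
  init <- .default_init(init, p, lut$v_min)
  n <- floor(T / dt)
  out <- .sim_adex_cpp(unlist(unclass(p)), dt, n, init$V, init$W,
                       20, apex_clamp, TRUE, lut$values, lut$v_min, lut$dv)
  .trace_from_cpp(out, dt, n)
}

#' Export / import a lookup table as a plain-text memory file
#'
#' One value per line, preceded by `#`-prefixed header lines recording the
#' voltage range so the table can be reconstructed.
#'
#' @param lut a [build_lut()] table.
#' @param path file path.
#' @return `write_lut` returns `path` invisibly; `read_lut` returns a
#'   `lut_spec` (with `params` unset).
#' @export
write_lut <- function(lut, path) {
  stopifnot(inherits(lut, "lut_spec"))
  hdr <- c(sprintf("# v_min %.17g", lut$v_min),
           sprintf("# v_max %.17g", lut$v_max),
           sprintf("# ceiling %.17g", lut$ceiling))
  writeLines(c(hdr, sprintf("%.17g", lut$values)), path)
  invisible(path)
}

#' @rdname write_lut
#' @export
read_lut <- function(path) {
  ln <- readLines(path)
  hdr <- grep("^#", ln, value = TRUE)
  val <- as.numeric(grep("^#", ln, value = TRUE, invert = TRUE))
  gethdr <- function(key) {
    m <- grep(paste0("^# ", key, " "), hdr, value = TRUE)
    as.numeric(sub(paste0("^# ", key, " "), "", m[1]))
  }
  v_min <- gethdr("v_min"); v_max <- gethdr("v_max")
  structure(list(v_min = v_min, v_max = v_max, n_points = length(val),
                 dv = (v_max - v_min) / (length(val) - 1), values = val,
                 ceiling = gethdr("ceiling"), params = NULL),
            class = "lut_spec")
}
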