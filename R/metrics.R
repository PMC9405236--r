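.check_same_grid <- function(a, b) {
  if (length(a$t) != length(b$t) || !isTRUE(all.equal(a$t, b$t)))
    stop("traces are not on the same time grid", call. = FALSE)
}

#' Mean absolute voltage error between two traces
#'
#' `mean(|V_a - V_b|)` over the shared time grid, in mV.
#'
#' @param a,b [voltage_trace()] objects on identical time grids.
#' @return MAE in mV.
#' @export
trace_mae <- function(a, b) {
  .check_same_grid(a, b)
  mean(abs(a$V - b$V))
}

#' Pearson correlation of two voltage traces, in percent
#'
#' @inheritParams trace_mae
#' @return Correlation times 100 (in `[-100, 100]`).
#' @export
trace_correlation <- function(a, b) {
  .check_same_grid(a, b)
  if (stats::sd(a$V) == 0 || stats::sd(b$V) == 0)
    stop("zero-variance trace: correlation undefined", call. = FALSE)
  100 * stats::cor(a$V, b$V)
}

#' Trough error between two traces
#'
#' Absolute difference between the minima of the two voltage sequences
#' (the error at the lowest point of the curves), in mV.
#'
#' @param a,b [voltage_trace()] objects (need not share a grid).
#' @return Trough error in mV.
#' @export
trace_errp <- function(a, b) {
  if (!length(a$V) || !length(b$V)) stop("empty trace", call. = FALSE)
  abs(min(a$V) - min(b$V))
}

#' Original-versus-N-LUT error report under one protocol
#'
#' Simulates the original and the N-LUT model for one firing pattern under a
#' shared protocol (same preset, `dt`, duration, initial state) and returns
#' the trough error, MAE and correlation of the two voltage traces.
#'
#' @param pattern firing-pattern label, or vector of labels.
#' @param dt time step (ms), default 1/128.
#' @param T duration (ms), default 1000.
#' @param n_points LUT size, default 20.
#' @param v_min,v_max LUT voltage range (mV).
#' @param init initial state shared by both models (default as in
#'   [simulate_adex()]).
#' @return A data frame with columns `pattern`, `ERRp`, `MAE`,
#'   `correlation_pct`, `spikes_original`, `spikes_nlut`.
#' @export
#' @examples
#' compare_models("Tonic spiking", T = 250)
compare_models <- function(pattern, dt = 1 / 128, T = 1000, n_points = 20,
                           v_min = -60, v_max = 10, init = NULL) {
  rows <- lapply(pattern, function(nm) {
    p <- adex_preset(nm)$params
    lut <- build_lut(p, v_min, v_max, n_points)
    orig <- simulate_adex(p, dt, T, init)
    prop <- simulate_nlut(p, lut, dt, T, init)
    data.frame(pattern = nm,
               ERRp = trace_errp(orig, prop),
               MAE = trace_mae(orig, prop),
               correlation_pct = trace_correlation(orig, prop),
               spikes_original = length(orig$spike_times),
               spikes_nlut = length(prop$spike_times))
  })
  do.call(rbind, rows)
}

#' Write an error-metrics report as CSV
#'
#' Columns `pattern,ERRp,MAE,correlation_pct`.
#'
#' @param report data frame from [compare_models()].
#' @param path file path.
#' @return `path` invisibly.
#' @export
write_metrics_csv <- function(report, path) {
  utils::write.csv(report[, c("pattern", "ERRp", "MAE", "correlation_pct")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
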