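# Constructed inputs with known properties, used across the test suite and
# exportable via make_fixtures().

#' Synthetic periodic-burst raster
#'
#' Every neuron fires one spike per population burst; bursts repeat every
#' `period` ms with a small deterministic per-neuron offset, so the
#' population histogram has a spectral peak at `1000 / period` Hz.
#'
#' @param period burst period (ms).
#' @param n_neurons number of neurons.
#' @param duration raster length (ms).
#' @param spread deterministic within-burst offset span (ms).
#' @return A [raster_data()] object.
#' @export
fixture_burst_raster <- function(period = 1000 / 6, n_neurons = 50,
                                 duration = 1000, spread = 4) {
  bursts <- seq(period / 2, duration - 1, by = period)
  spikes <- lapply(seq_len(n_neurons), function(j) {
    off <- spread * (j - 1) / max(n_neurons - 1, 1)
    bursts + off
  })
  raster_data(spikes, duration)
}

#' Pair of traces offset by a constant
#'
#' Two smooth voltage traces differing by exactly `offset` mV everywhere,
#' so their MAE equals `offset` and their correlation is 100.
#'
#' @param offset voltage offset (mV).
#' @param n number of samples.
#' @param dt time step (ms).
#' @return A list with elements `a` and `b` ([voltage_trace()] objects).
#' @export
fixture_offset_traces <- function(offset = 1, n = 512, dt = 1 / 128) {
  t <- (seq_len(n) - 1) * dt
  V <- -60 + 10 * sin(2 * pi * t / (n * dt))
  W <- 5 * cos(2 * pi * t / (n * dt))
  list(a = voltage_trace(t, V, W),
       b = voltage_trace(t, V + offset, W))
}

#' Pure-sinusoid tabulation with known bandwidth
#'
#' `cycles` full periods over the span, so [estimate_bandwidth()] returns
#' exactly `cycles`.
#'
#' @param cycles number of cycles over the normalised span.
#' @param n number of samples.
#' @return Numeric vector of samples.
#' @export
fixture_sinusoid <- function(cycles = 5, n = 256) {
  sin(2 * pi * cycles * (seq_len(n) - 1) / n)
}

#' Generate the constructed fixture files
#'
#' Writes the deterministic test inputs (periodic-burst raster, offset trace
#' pair, sinusoid tabulation) under `dir`.
#'
#' @param seed RNG seed (the fixtures are deterministic; the seed is
#'   recorded in the manifest for auditability).
#' @param dir output directory (created if needed).
#' @return Named character vector of written file paths, invisibly.
#' @export
make_fixtures <- function(seed = 1, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    raster = file.path(dir, "fixture_burst_raster.csv"),
    trace_a = file.path(dir, "fixture_trace_a.csv"),
    trace_b = file.path(dir, "fixture_trace_b.csv"),
    sinusoid = file.path(dir, "fixture_sinusoid.txt"),
    manifest = file.path(dir, "fixture_manifest.txt"))
  write_raster_csv(fixture_burst_raster(), paths["raster"])
  tr <- fixture_offset_traces()
  write_trace_csv(tr$a, paths["trace_a"])
  write_trace_csv(tr$b, paths["trace_b"])
  writeLines(sprintf("%.17g", fixture_sinusoid()), paths["sinusoid"])
  writeLines(c(sprintf("seed %d", seed),
               sprintf("package nlutadex %s",
                       as.character(utils::packageVersion("nlutadex")))),
             paths["manifest"])
  invisible(paths)
}
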