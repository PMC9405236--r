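#' Population network configuration
#'
#' Describes a randomly connected excitatory/inhibitory population of ADEX
#' neurons.  All neurons share one base parameter set; heterogeneity comes
#' from a seeded jitter of the stimulus current (so a single lookup table
#' serves the whole population) and from random initial voltages.  Synapses
#' are delta pulses: the weights of neurons that spiked on the previous step
#' are summed into the postsynaptic stimulus current for one step, so a
#' weight is the current (pA) delivered for one `dt`.
#'
#' The default drive of 223 pA puts isolated neurons just above rheobase
#' (about 220 pA for the tonic parameter set), where they fire at around
#' 6 Hz — the few-hertz collective-rhythm regime of the population
#' experiment.
#'
#' @param n_neurons population size (default 2000).
#' @param exc_fraction fraction of excitatory neurons (default 0.8, the
#'   4-to-1 split).
#' @param connection_prob directed connection probability (default 0.1).
#' @param pattern base firing-pattern label (default "Tonic spiking").
#' @param I_base baseline stimulus current (pA) replacing the preset's
#'   pattern-generation drive.
#' @param I_jitter_sd s.d. of the per-neuron Gaussian jitter on the drive
#'   (pA).
#' @param w_exc_max excitatory weights drawn uniformly from
#'   `[0, w_exc_max]` (pA per step).
#' @param w_inh_max inhibitory weights drawn uniformly from
#'   `[-w_inh_max, 0]` (pA per step).
#' @param noise_sd s.d. of per-step Gaussian noise current (pA).
#' @param dt time step (ms).
#' @param duration simulated time (ms).
#' @param seed RNG seed; a fixed seed makes the network build and both
#'   simulations fully reproducible.
#' @return A list of class `network_config`.
#' @export
network_config <- function(n_neurons = 2000, exc_fraction = 0.8,
                           connection_prob = 0.1,
                           pattern = "Tonic spiking",
                           I_base = 223, I_jitter_sd = 1,
                           w_exc_max = 250, w_inh_max = 1000,
                           noise_sd = 100,
                           dt = 1 / 128, duration = 1000, seed = 1) {
  if (n_neurons < 2) stop("need at least 2 neurons", call. = FALSE)
  if (exc_fraction <= 0 || exc_fraction >= 1)
    stop("exc_fraction must lie in (0, 1)", call. = FALSE)
  if (connection_prob < 0 || connection_prob > 1)
    stop("connection_prob must lie in [0, 1]", call. = FALSE)
  structure(list(n_neurons = as.integer(n_neurons),
                 exc_fraction = exc_fraction,
                 connection_prob = connection_prob, pattern = pattern,
                 I_base = I_base, I_jitter_sd = I_jitter_sd,
                 w_exc_max = w_exc_max, w_inh_max = w_inh_max,
                 noise_sd = noise_sd, dt = dt, duration = duration,
                 seed = as.integer(seed)),
            class = "network_config")
}

#' Build a random excitatory/inhibitory network
#'
#' Seeded construction of the directed connectivity, synaptic weights,
#' per-neuron drives and initial states described by a [network_config()].
#' The first `round(exc_fraction * n)` neurons are excitatory (weights
#' `>= 0`), the rest inhibitory (`<= 0`).
#'
#' @param cfg a [network_config()].
#' @return A list of class `adex_network`: `cfg`, `params` (base
#'   [adex_params()]), `is_exc`, `I_i`, `v0`, `w0`, `edges` (data frame
#'   `pre`, `post`, `weight`).
#' @export
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  n <- cfg$n_neurons
  set.seed(cfg$seed)
  n_exc <- round(cfg$exc_fraction * n)
  is_exc <- seq_len(n) <= n_exc
  p <- adex_preset(cfg$pattern)$params
  p$I <- cfg$I_base
  I_i <- cfg$I_base + stats::rnorm(n, 0, cfg$I_jitter_sd)
  v0 <- stats::runif(n, -60, -50)
  w0 <- rep(0, n)
  # directed Erdos-Renyi edges, no self-loops
  edges <- lapply(seq_len(n), function(j) {
    deg <- stats::rbinom(1, n - 1L, cfg$connection_prob)
    if (deg == 0) return(NULL)
    post <- sample(seq_len(n)[-j], deg)
    w <- if (is_exc[j]) stats::runif(deg, 0, cfg$w_exc_max)
         else -stats::runif(deg, 0, cfg$w_inh_max)
    data.frame(pre = j, post = post, weight = w)
  })
  edges <- do.call(rbind, edges[!vapply(edges, is.null, logical(1))])
  if (is.null(edges))
    edges <- data.frame(pre = integer(0), post = integer(0),
                        weight = numeric(0))
  structure(list(cfg = cfg, params = p, is_exc = is_exc, I_i = I_i,
                 v0 = v0, w0 = w0, edges = edges),
            class = "adex_network")
}

#' @export
print.adex_network <- function(x, ...) {
  cat(sprintf("adex_network: %d neurons (%d exc / %d inh), %d edges, seed %d\n",
              x$cfg$n_neurons, sum(x$is_exc), sum(!x$is_exc),
              nrow(x$edges), x$cfg$seed))
  invisible(x)
}

#' Simulate a population under the original or N-LUT model
#'
#' Every neuron integrates its Euler update with synaptic input equal to the
#' summed weights of presynaptic neurons that spiked on the previous step,
#' plus seeded per-step noise.  Spikes are recorded at `V > 0` crossings.  A
#' diverging neuron is clamped to the reset state (and counted) and the run
#' continues.
#'
#' @param net an [build_network()] object.
#' @param model `"original"` or `"nlut"`.
#' @param lut a [build_lut()] table for the nlut model (default: built from
#'   the network's base parameters).
#' @return A list of class `raster_data`: `spikes` (per-neuron numeric
#'   vectors of spike times, ms), `duration`, `is_exc`, `n_clamped`.
#' @export
simulate_population <- function(net, model = c("original", "nlut"),
                                lut = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(net, "adex_network"))
  cfg <- net$cfg
  use_lut <- model == "nlut"
  if (use_lut && is.null(lut)) lut <- build_lut(net$params)
  n <- cfg$n_neurons
  # CSR adjacency over presynaptic index
  ord <- order(net$edges$pre)
  pre <- net$edges$pre[ord]; post <- net$edges$post[ord]
  w <- net$edges$weight[ord]
  ptr <- c(0L, cumsum(tabulate(pre, nbins = n)))
  n_steps <- floor(cfg$duration / cfg$dt)
  set.seed(cfg$seed + 1L)  # noise stream, distinct from the build stream
  out <- .sim_population_cpp(
    unlist(unclass(net$params)), net$I_i, net$v0, net$w0,
    as.integer(ptr), as.integer(post - 1L), w,
    cfg$dt, n_steps, cfg$noise_sd, 20, use_lut,
    if (use_lut) lut$values else numeric(0),
    if (use_lut) lut$v_min else 0, if (use_lut) lut$dv else 1)
  spikes <- split(out$t, factor(out$neuron, levels = seq_len(n)))
  names(spikes) <- NULL
  structure(list(spikes = spikes, duration = cfg$duration,
                 is_exc = net$is_exc, n_clamped = out$n_clamped,
                 model = model),
            class = "raster_data")
}

#' Construct raster data directly
#'
#' @param spikes list of per-neuron spike-time vectors (ms), each strictly
#'   increasing within `[0, duration]`.
#' @param duration raster duration (ms).
#' @param is_exc optional logical class labels (default all excitatory).
#' @return A `raster_data` object.
#' @export
raster_data <- function(spikes, duration, is_exc = NULL) {
  for (s in spikes) {
    if (length(s) && (any(diff(s) <= 0) || any(s < 0) || any(s > duration)))
      stop("spike times must be strictly increasing within [0, duration]",
           call. = FALSE)
  }
  if (is.null(is_exc)) is_exc <- rep(TRUE, length(spikes))
  structure(list(spikes = spikes, duration = duration, is_exc = is_exc,
                 n_clamped = 0, model = "constructed"),
            class = "raster_data")
}

#' @export
print.raster_data <- function(x, ...) {
  cat(sprintf("raster_data (%s): %d neurons, %d spikes over %g ms\n",
              x$model, length(x$spikes), sum(lengths(x$spikes)), x$duration))
  invisible(x)
}

#' Dominant population-rhythm frequency
#'
#' Bins all spikes into a population spike-count histogram, removes the
#' mean, and returns the frequency (Hz) of the largest non-DC spectral
#' peak.
#'
#' @param r a `raster_data` object with duration of at least 500 ms.
#' @param bin histogram bin width (ms), default 1.
#' @return Peak frequency in Hz.
#' @export
rhythm_frequency <- function(r, bin = 1) {
  stopifnot(inherits(r, "raster_data"))
  if (r$duration < 500) stop("need at least 500 ms of data", call. = FALSE)
  all_spk <- unlist(r$spikes)
  if (!length(all_spk)) stop("empty raster", call. = FALSE)
  nb <- floor(r$duration / bin)
  counts <- tabulate(pmin(floor(all_spk / bin) + 1L, nb), nbins = nb)
  x <- counts - mean(counts)
  pw <- Mod(stats::fft(x))^2
  k <- seq(2, floor(nb / 2) + 1)           # non-DC, one-sided
  freq_hz <- (k - 1) / (nb * bin / 1000)   # bin index -> Hz
  freq_hz[which.max(pw[k])]
}

#' Mean relative spike-time error between two rasters
#'
#' For each neuron the i-th spikes of the two rasters (within `window`) are
#' paired; with `dt_i` the proposed-minus-reference time difference and
#' `ts_i` the reference spike time, the statistic is
#' `sum(|dt_i| / |ts_i|) / N * 100` with `N` the total number of paired
#' spikes.  Surplus unpaired spikes are excluded from `N`; their count is
#' attached as attribute `"n_unpaired"`.
#'
#' @param r_ref reference (original-model) `raster_data`.
#' @param r_prop proposed-model `raster_data` with the same neuron count.
#' @param window pairing window (ms), default 1000.
#' @return MRE in percent.
#' @export
#' @examples
#' a <- raster_data(list(c(100, 200)), 1000)
#' b <- raster_data(list(c(101, 202)), 1000)
#' mre(a, b)  # 1%
mre <- function(r_ref, r_prop, window = 1000) {
  stopifnot(inherits(r_ref, "raster_data"), inherits(r_prop, "raster_data"))
  if (length(r_ref$spikes) != length(r_prop$spikes))
    stop("rasters have different neuron counts", call. = FALSE)
  tot <- 0; N <- 0L; unpaired <- 0L
  for (j in seq_along(r_ref$spikes)) {
    s1 <- r_ref$spikes[[j]]; s1 <- s1[s1 <= window & s1 > 0]
    s2 <- r_prop$spikes[[j]]; s2 <- s2[s2 <= window & s2 > 0]
    k <- min(length(s1), length(s2))
    unpaired <- unpaired + abs(length(s1) - length(s2))
    if (k == 0) next
    tot <- tot + sum(abs(s2[seq_len(k)] - s1[seq_len(k)]) / abs(s1[seq_len(k)]))
    N <- N + k
  }
  if (N == 0) stop("no paired spikes within the window", call. = FALSE)
  structure(tot / N * 100, n_unpaired = unpaired)
}

#' Write / read a raster as CSV
#'
#' Dialect `neuron_id,t_ms,class` with class `E` or `I`.
#'
#' @param r a `raster_data` object.
#' @param path file path.
#' @return `write_raster_csv` returns `path` invisibly; `read_raster_csv`
#'   returns a `raster_data` (duration taken from the header comment line).
#' @export
write_raster_csv <- function(r, path) {
  stopifnot(inherits(r, "raster_data"))
  id <- rep(seq_along(r$spikes), lengths(r$spikes))
  df <- data.frame(neuron_id = id, t_ms = unlist(r$spikes),
                   class = ifelse(r$is_exc[id], "E", "I"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# duration %g n_neurons %d", r$duration,
                     length(r$spikes)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec("# duration ([0-9.eE+-]+) n_neurons ([0-9]+)", hdr))[[1]]
  duration <- as.numeric(m[2]); n <- as.integer(m[3])
  df <- utils::read.csv(path, comment.char = "#")
  spikes <- split(df$t_ms, factor(df$neuron_id, levels = seq_len(n)))
  names(spikes) <- NULL
  is_exc <- rep(TRUE, n)
  if (nrow(df)) is_exc[df$neuron_id] <- df$class == "E"
  raster_data(spikes, duration, is_exc)
}

#' Write the network edge list for reproducibility audits
#'
#' @param net an [build_network()] object.
#' @param path file path.
#' @return `path` invisibly.
#' @export
write_network_csv <- function(net, path) {
  stopifnot(inherits(net, "adex_network"))
  utils::write.csv(net$edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
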