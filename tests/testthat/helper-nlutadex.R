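# shared shortcuts for the suite
tonic <- function() adex_preset("Tonic spiking")$params

# subthreshold parameter set with a stable fixed point (drive below rheobase)
tonic_rest <- function(I = 0) {
  p <- tonic()
  p$I <- I
  p
}

# numerically locate the stable fixed point of the continuous model
find_fixed_point <- function(p) {
  g <- function(v) adx(v, p) + p$I - p$a * (v - p$EL)
  v_star <- stats::uniroot(g, c(p$EL - 10, p$VT - 1), tol = 1e-12)$root
  neuron_state(v_star, p$a * (v_star - p$EL))
}
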