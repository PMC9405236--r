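test_that("adx matches its closed form at anchor voltages", {
  p <- tonic()
  # at threshold the exponential factor is exactly 1
  expect_equal(adx(p$VT, p), -p$gL * (p$VT - p$EL) + p$gL * p$DeltaT)
  expect_equal(adx(p$VT, p), -180)
  # at rest the leak vanishes and only the tiny exponential tail remains
  expect_equal(adx(p$EL, p), p$gL * p$DeltaT * exp((p$EL - p$VT) / p$DeltaT))
  expect_equal(adx(p$EL, p), 20 * exp(-10), tolerance = 1e-12)
  expect_error(adx(NaN, p), "finite")
  expect_error(adx(Inf, p), "finite")
})

test_that("adx exponent clamp keeps values finite far above threshold", {
  p <- tonic()
  expect_true(is.finite(adx(1e6, p)))
  # beyond the clamp the exponential factor freezes at exp(exp_clamp)
  expect_equal(adx(p$VT + 30 * p$DeltaT, p, exp_clamp = 20) +
                 p$gL * (p$VT + 30 * p$DeltaT - p$EL),
               p$gL * p$DeltaT * exp(20))
})

test_that("derivatives implement the two coupled equations", {
  p <- tonic()
  d <- adex_derivatives(neuron_state(p$VT, 0), p)
  expect_equal(unname(d["dV"]), (-180 + 500) / 200)  # 1.6 mV/ms
  # both adaptation terms vanish at (EL, 0) for any a
  for (a in c(-11, 0, 2, 7)) {
    q <- p; q$a <- a
    expect_equal(unname(adex_derivatives(neuron_state(q$EL, 0), q)["dW"]), 0)
  }
  # dW/dt = 0 exactly on the W-nullcline W = a (V - EL)
  for (v in c(-65, -58, -51)) {
    expect_equal(unname(adex_derivatives(
      neuron_state(v, p$a * (v - p$EL)), p)["dW"]), 0)
  }
})

test_that("reset rule sets V to Vr and increments W by b", {
  p <- tonic()  # Vr = -58, b = 0
  s <- adex_reset(neuron_state(1, 10), p)
  expect_equal(s$V, -58)
  expect_equal(s$W, 10)
  adapt <- adex_preset("Adaptation")$params  # b = 60
  expect_equal(adex_reset(neuron_state(5, 0), adapt)$W, 60)
  # with b = 0 the reset is idempotent in W
  s2 <- adex_reset(neuron_state(1, adex_reset(neuron_state(1, 10), p)$W + 60 - 60), p)
  expect_equal(s2$W, 10)
  expect_error(adex_reset(neuron_state(-1, 0), p), "V <= 0")
})

test_that("presets reproduce the printed parameter rows exactly", {
  expect_equal(unlist(unclass(tonic())),
               c(C = 200, gL = 10, EL = -70, VT = -50, DeltaT = 2, a = 2,
                 tau_w = 30, b = 0, Vr = -58, I = 500))
  rs <- adex_preset("RS")$params
  expect_equal(unlist(unclass(rs)),
               c(C = 104, gL = 4.3, EL = -65, VT = -52, DeltaT = 0.8,
                 a = -0.8, tau_w = 88, b = 65, Vr = -53, I = 98))
  expect_length(adex_pattern_names(), 8)
  expect_error(adex_preset("foo"), "valid names")
})

test_that("parameter validation enforces the stated invariants", {
  expect_error(adex_params(-1, 10, -70, -50, 2, 2, 30, 0, -58, 500), "C")
  expect_error(adex_params(200, 10, -70, -50, -2, 2, 30, 0, -58, 500), "DeltaT")
  expect_error(adex_params(200, 10, -70, -50, 2, 2, 0, 0, -58, 500), "tau_w")
  expect_error(adex_params(200, 10, -70, -50, 2, 2, 30, 0, 5, 500), "Vr")
  expect_error(neuron_state(Inf, 0), "finite")
})

test_that("a state on both nullclines is an Euler equilibrium", {
  p <- tonic_rest(I = 0)
  s <- find_fixed_point(p)
  tr <- simulate_adex(p, dt = 1 / 128, T = 1 / 128, init = s)
  expect_equal(tr$V[2], s$V, tolerance = 1e-9)
  expect_equal(tr$W[2], s$W, tolerance = 1e-9)
})

test_that("tonic preset fires periodically with near-constant ISI", {
  tr <- simulate_adex("Tonic spiking", T = 1000)
  expect_gt(length(tr$spike_times), 1)
  isi <- diff(tr$spike_times)
  isi <- isi[-(1:2)]  # drop the transient
  expect_lt(max(isi) - min(isi), 0.05 * mean(isi))
  expect_length(tr$t, 128000 + 1)
})

test_that("Euler integration converges at first order on smooth segments", {
  p <- tonic_rest(I = 150)  # subthreshold: no resets, smooth trajectory
  ref <- simulate_adex(p, dt = 1 / 1024, T = 20)
  err <- sapply(c(1 / 128, 1 / 256), function(dt) {
    tr <- simulate_adex(p, dt = dt, T = 20)
    abs(tr$V[length(tr$V)] - ref$V[length(ref$V)])
  })
  expect_gt(err[1] / err[2], 1.5)   # halving dt roughly halves the error
  expect_lt(err[1] / err[2], 3)
})

test_that("W evolves continuously between resets; V jumps only at resets", {
  tr <- simulate_adex("can", T = 300)
  spikes <- which(tr$t %in% tr$spike_times)
  dW <- abs(diff(tr$W))
  big <- which(dW > 30)            # b = 61 pA jumps
  expect_true(all(big %in% spikes))
  dV <- diff(tr$V)
  jumps <- which(abs(dV) > 20)     # resets and apex excursions
  expect_true(all(jumps %in% c(spikes - 1, spikes)))
})

test_that("simulation aborts with a diagnostic when the state diverges", {
  # a negative leak conductance is a runaway regime: V accelerates to -Inf
  # below rest, where no reset can intervene
  p <- adex_params(C = 200, gL = -1e5, EL = -70, VT = -50, DeltaT = 2,
                   a = 2, tau_w = 30, b = 0, Vr = -58, I = 0)
  expect_error(simulate_adex(p, T = 10, init = neuron_state(-75, 0)),
               "diverged.*step")
})

test_that("trace CSV round trip preserves samples and spike flags", {
  tr <- simulate_adex("Tonic spiking", T = 50)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  tr2 <- read_trace_csv(f)
  expect_equal(tr2$V, tr$V, tolerance = 1e-12)
  expect_equal(tr2$spike_times, tr$spike_times)
})

test_that("voltage_trace validates its invariants", {
  expect_error(voltage_trace(1:3, 1:2, 1:3), "equal length")
  expect_error(voltage_trace(c(1, 1, 2), 1:3, 1:3), "strictly increasing")
  expect_error(voltage_trace(1:3, 1:3, 1:3, spike_times = 2.5), "member")
})
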