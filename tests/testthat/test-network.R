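test_that("network build is deterministic and honours the 4:1 split", {
  cfg <- network_config(n_neurons = 2000, seed = 42)
  n1 <- build_network(cfg)
  n2 <- build_network(cfg)
  expect_identical(n1$edges, n2$edges)
  expect_identical(n1$I_i, n2$I_i)
  expect_equal(sum(n1$is_exc), 1600)
  expect_equal(sum(!n1$is_exc), 400)
  exc_w <- n1$edges$weight[n1$is_exc[n1$edges$pre]]
  inh_w <- n1$edges$weight[!n1$is_exc[n1$edges$pre]]
  expect_true(all(exc_w >= 0))
  expect_true(all(inh_w <= 0))
})

test_that("zero connection probability yields an empty edge list", {
  net <- build_network(network_config(n_neurons = 50, connection_prob = 0))
  expect_equal(nrow(net$edges), 0)
})

test_that("config validation rejects degenerate populations", {
  expect_error(network_config(n_neurons = 1), "at least 2")
  expect_error(network_config(exc_fraction = 1), "exc_fraction")
  expect_error(network_config(connection_prob = 2), "connection_prob")
})

test_that("decoupled noiseless neurons reproduce the single-neuron trace", {
  cfg <- network_config(n_neurons = 4, connection_prob = 0, noise_sd = 0,
                        I_jitter_sd = 0, duration = 250, seed = 9)
  net <- build_network(cfg)
  r <- simulate_population(net, "original")
  for (j in 1:4) {
    single <- simulate_adex(net$params, dt = cfg$dt, T = cfg$duration,
                            init = neuron_state(net$v0[j], 0))
    expect_equal(r$spikes[[j]], single$spike_times)
  }
  rl <- simulate_population(net, "nlut")
  lut <- build_lut(net$params)
  for (j in 1:4) {
    single <- simulate_nlut(net$params, lut, dt = cfg$dt, T = cfg$duration,
                            init = neuron_state(net$v0[j], 0))
    expect_equal(rl$spikes[[j]], single$spike_times)
  }
})

test_that("population simulation is reproducible under a fixed seed", {
  cfg <- network_config(n_neurons = 60, duration = 600, seed = 4)
  net <- build_network(cfg)
  r1 <- simulate_population(net, "nlut")
  r2 <- simulate_population(net, "nlut")
  expect_identical(r1$spikes, r2$spikes)
  # doubling the noise scale changes spikes but not determinism
  cfg2 <- network_config(n_neurons = 60, duration = 600, seed = 4,
                         noise_sd = 200)
  net2 <- build_network(cfg2)
  expect_identical(simulate_population(net2, "nlut")$spikes,
                   simulate_population(net2, "nlut")$spikes)
})

test_that("rhythm detector recovers constructed burst frequencies", {
  expect_equal(rhythm_frequency(fixture_burst_raster(period = 1000 / 6)), 6)
  expect_equal(rhythm_frequency(fixture_burst_raster(period = 100)), 10)
  expect_equal(rhythm_frequency(fixture_burst_raster(period = 250)), 4)
  short <- fixture_burst_raster(duration = 400)
  expect_error(rhythm_frequency(short), "500 ms")
  empty <- raster_data(rep(list(numeric(0)), 5), 1000)
  expect_error(rhythm_frequency(empty), "empty")
})

test_that("mre matches hand-computed pairings and its invariances", {
  a <- raster_data(list(c(100, 200)), 1000)
  b <- raster_data(list(c(101, 202)), 1000)
  expect_equal(as.numeric(mre(a, b)), 1)         # (1/100 + 2/200)/2 * 100
  expect_equal(as.numeric(mre(a, a)), 0)
  # adding a silent neuron changes nothing
  a2 <- raster_data(list(c(100, 200), numeric(0)), 1000)
  b2 <- raster_data(list(c(101, 202), numeric(0)), 1000)
  expect_equal(as.numeric(mre(a2, b2)), 1)
  # surplus spikes are excluded from N but reported
  b3 <- raster_data(list(c(101, 202, 300)), 1000)
  m <- mre(a, b3)
  expect_equal(as.numeric(m), 1)
  expect_equal(attr(m, "n_unpaired"), 1)
  expect_error(mre(a, raster_data(list(numeric(0)), 1000)), "paired")
  expect_error(mre(a, b2), "neuron counts")
})

test_that("raster CSV round trip preserves spikes and classes", {
  r <- fixture_burst_raster(n_neurons = 7)
  r$is_exc <- c(rep(TRUE, 5), FALSE, FALSE)
  f <- withr::local_tempfile(fileext = ".csv")
  write_raster_csv(r, f)
  r2 <- read_raster_csv(f)
  expect_equal(r2$spikes, r$spikes)
  expect_equal(r2$is_exc, r$is_exc)
  expect_equal(r2$duration, r$duration)
})

test_that("raster validation enforces ordered in-range spike times", {
  expect_error(raster_data(list(c(5, 4)), 10), "strictly increasing")
  expect_error(raster_data(list(c(5, 11)), 10), "strictly increasing")
})
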