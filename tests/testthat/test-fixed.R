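test_that("greedy signed-power decomposition is value-exact where possible", {
  for (x in c(200, 500, 61, 104, 184)) {
    d <- csd_decompose(x)
    expect_equal(d$value, x)
    expect_lte(length(d$exponents), 3)
  }
  d18 <- csd_decompose(1.8)
  expect_equal(d18$signs, c(1L, -1L))
  expect_equal(d18$exponents, c(1L, -2L))
  expect_equal(d18$value, 1.75)
  d1 <- csd_decompose(1)
  expect_equal(d1$exponents, 0L)
  expect_equal(d1$signs, 1L)
  d0 <- csd_decompose(0)
  expect_length(d0$exponents, 0)
  expect_equal(d0$value, 0)
})

test_that("decomposition terms are strictly decreasing, distinct and improving", {
  set.seed(7)
  for (i in 1:200) {
    x <- stats::runif(1, -600, 600)
    if (x == 0) next
    d <- csd_decompose(x, max_terms = 4, min_exponent = -6)
    if (length(d$exponents) > 1) expect_true(all(diff(d$exponents) < 0))
    expect_equal(anyDuplicated(d$exponents), 0L)
    expect_lte(abs(d$value - x), abs(x))
    expect_equal(d$value, sum(d$signs * 2^d$exponents))
  }
})

test_that("fixed-point conversion is exact at powers and bounded in general", {
  fmt <- fixed_format(28, 20)
  expect_equal(to_fixed(1, fmt), 2^20)
  expect_equal(to_fixed(0, fmt), 0)
  expect_equal(from_fixed(to_fixed(-1, fmt), fmt), -1)
  set.seed(11)
  x <- stats::runif(1000, -100, 100)
  err <- abs(from_fixed(to_fixed(x, fmt), fmt) - x)
  expect_true(all(err <= 2^(-21)))
  expect_warning(to_fixed(1e9, fmt), "saturated")
})

test_that("fixed_format rejects degenerate layouts", {
  expect_error(fixed_format(20, 20), "word_bits")
  expect_error(fixed_format(64, 20), "word_bits")
  expect_error(fixed_format(10, -1), "word_bits")
})

test_that("shift-add scaling is bit-identical to direct multiplication", {
  fmt <- fixed_format(44, 20)
  # identity scaling: one shift, no adds
  tr <- op_trace()
  v <- to_fixed(3.25, fmt)
  expect_equal(shift_add_scale(v, csd_decompose(1), fmt, tr), v)
  ops <- as.list(tr)
  expect_equal(ops$shift, 1)
  expect_equal(ops$add + ops$sub, 0)
  expect_equal(ops$mul + ops$div, 0)
  # integer decompositions: exact product
  expect_equal(shift_add_scale(to_fixed(1, fmt), csd_decompose(200), fmt),
               to_fixed(200, fmt))
  set.seed(5)
  for (i in 1:500) {
    x <- round(stats::runif(1, -1e6, 1e6))
    d <- csd_decompose(round(stats::runif(1, 1, 500)), min_exponent = 0)
    expect_identical(shift_add_scale(x, d, fmt), x * d$value)
  }
  # negative exponents follow arithmetic-shift (floor) semantics
  for (i in 1:500) {
    x <- round(stats::runif(1, -1e6, 1e6))
    d <- csd_decompose(stats::runif(1, 0.01, 4), 3, -10)
    oracle <- sum(d$signs * ifelse(d$exponents >= 0,
                                   x * 2^d$exponents,
                                   floor(x / 2^(-d$exponents))))
    expect_identical(shift_add_scale(x, d, fmt), oracle)
  }
})

test_that("word-width analysis reproduces the datapath sizing rule", {
  expect_equal(bit_width_analysis(-60, 10, 20), 28L)
  expect_equal(bit_width_analysis(-1, 1, 0), 2L)
  w <- sapply(seq(10, 200, by = 10), function(m) bit_width_analysis(-m, 10, 20))
  expect_true(all(diff(w) >= 0))  # widening the range never shrinks the word
  expect_error(bit_width_analysis(5, 5), "degenerate")
})

test_that("digitised presets reproduce the printed decompositions verbatim", {
  d <- digital_preset("Tonic spiking")
  expect_equal(vapply(d, function(x) x$value, numeric(1)),
               c(C = 200, gL = 10, EL = -70, VT = -50, DeltaT = 2, a = 2,
                 tau_w = 28, b = 0, Vr = -56, I = 500))
  expect_equal(format(d$C), "+2^7 +2^6 +2^3")
  expect_equal(format(d$I), "+2^9 -2^3 -2^2")
  expect_equal(digital_preset("cAD")$DeltaT$value, 5.5)      # 4 + 1 + 1/2
  expect_equal(digital_preset("can")$a$value, 1.75)          # 2 - 1/4
  expect_equal(digital_preset("can")$C$value, 56)            # sign-corrected
  expect_equal(digital_preset("can", printed_can_C = TRUE)$C$value, -56)
  expect_equal(digital_preset("RS")$Vr$value, -53)
  expect_error(digital_preset("nope"), "valid names")
})

test_that("divergence report flags exactly the large departures", {
  rep <- digital_divergence_report()
  expect_equal(nrow(rep), 80)  # 8 patterns x 10 parameters
  flagged <- rep[rep$flagged, c("pattern", "param")]
  key <- paste(flagged$pattern, flagged$param)
  expect_setequal(key, c("cAD gL", "RS DeltaT", "RS a"))
  # every other realized value is within 10% of the continuous row
  expect_true(all(rep$rel_dev[!rep$flagged] <= 0.1))
  # the printed negative capacitance is flagged once restored
  repP <- digital_divergence_report(printed_can_C = TRUE)
  expect_true(repP$flagged[repP$pattern == "can" & repP$param == "C"])
})

test_that("fixed-point memory export is two's-complement exact", {
  fmt <- fixed_format(28, 20)
  p <- tonic()
  lut <- build_lut(p, v_min = -60, v_max = -40, n_points = 4,
                   ceiling = 100)
  lut$values <- c(0, -1, 1.5, -62.5)  # known words
  f <- withr::local_tempfile(fileext = ".hex")
  export_fixed_lut(lut, fmt, f, "hex")
  lines <- readLines(f)
  expect_equal(lines[1], "0000000")
  expect_equal(lines[2], "FF00000")  # two's complement of -2^20 in 28 bits
  expect_equal(import_fixed_lut(f, 28, 20), to_fixed(lut$values, fmt))
  fc <- withr::local_tempfile(fileext = ".coe")
  export_fixed_lut(lut, fmt, fc, "coe")
  expect_match(readLines(fc)[1], "memory_initialization_radix=16;")
  expect_equal(import_fixed_lut(fc, 28, 20, "coe"), to_fixed(lut$values, fmt))
  lut$values <- c(1e9, 0, 0, 0)
  expect_error(export_fixed_lut(lut, fmt, f), "overflow")
})
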