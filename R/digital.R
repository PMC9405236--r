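# Digitised parameter sets: every constant expressed as a signed sum of
# powers of two, stored verbatim as printed in the reference design (row
# order matches the firing-pattern presets).  "(1/2)" and "(1/4)" denote
# 2^-1 and 2^-2.
.digital_table <- list(
  "Tonic spiking" = c(
    C = "128+64+8", gL = "8+2", EL = "-64-4-2", VT = "-32-16-2", DeltaT = "2",
    a = "2", tau_w = "16+8+4", b = "0", Vr = "-32-16-8", I = "512-8-4"),
  "Adaptation" = c(
    C = "128+64+8", gL = "8+4", EL = "-64-4-2", VT = "-32-16-2", DeltaT = "2",
    a = "2", tau_w = "256+32+8", b = "64-4", Vr = "-32-16-8", I = "512-8-4"),
  "Initial bursting" = c(
    C = "128+2", gL = "16+2", EL = "-32-16-8-2", VT = "-32-16-2", DeltaT = "2",
    a = "4", tau_w = "128+16+4", b = "128-8", Vr = "-32-16-2", I = "256+128+16"),
  "Delayed accelerating" = c(
    C = "128+64+8", gL = "8+4", EL = "-64-4-2", VT = "-32-16-2", DeltaT = "2",
    a = "-8-2", tau_w = "256+64-16", b = "0", Vr = "-32-16-8-2", I = "256+64-16"),
  "Irregular spiking" = c(
    C = "64+32+4", gL = "8+4", EL = "-64+4", VT = "-32-16-2", DeltaT = "2",
    a = "-8-2-1", tau_w = "128+2", b = "16+8+4", Vr = "-32-16", I = "128+32"),
  "can" = c(
    C = "-32-16-8", gL = "2+1", EL = "-64+2", VT = "-32-8-2", DeltaT = "2+1",
    a = "2-(1/4)", tau_w = "16", b = "64-2-1", Vr = "-32-16-4", I = "128+64-8"),
  "cAD" = c(
    C = "64+16+4", gL = "1+(1/2)", EL = "-64+4+1", VT = "-64+8",
    DeltaT = "4+1+(1/2)", a = "2", tau_w = "32+8+1", b = "64-8-1",
    Vr = "-64+8+2", I = "128-8-4"),
  "RS" = c(
    C = "64+32+8", gL = "4+(1/2)", EL = "-64-1", VT = "-64+8+4", DeltaT = "1",
    a = "-1", tau_w = "64+16+8", b = "64+1", Vr = "-64+8+2+1", I = "64+32+2")
)

# parse "512-8-4" / "2-(1/4)" / "-64+4" / "0" into a csd object
.parse_pow_terms <- function(txt) {
  s <- gsub("[() ]", "", txt)
  if (s == "0") return(csd_terms(integer(0), integer(0), target = 0))
  toks <- regmatches(s, gregexpr("[+-]?[0-9/]+", s))[[1]]
  signs <- ifelse(startsWith(toks, "-"), -1L, 1L)
  mags <- vapply(sub("^[+-]", "", toks), function(m) {
    if (grepl("/", m)) {
      ab <- as.numeric(strsplit(m, "/")[[1]])
      ab[1] / ab[2]
    } else as.numeric(m)
  }, numeric(1), USE.NAMES = FALSE)
  expo <- log2(mags)
  if (any(expo != round(expo)))
    stop("term is not a power of two: ", txt, call. = FALSE)
  csd_terms(signs, as.integer(round(expo)))
}

#' Digitised parameter presets of the hardware design
#'
#' Returns the stored power-of-two decompositions of the ten model constants
#' for one firing pattern, verbatim as tabulated for the hardware design —
#' including its deliberate approximations (e.g. the tonic adaptation time
#' constant realized as 16+8+4 = 28 ms against the continuous 30 ms).  These
#' are stored, not recomputed; [csd_decompose()] is the independent greedy
#' utility and [digital_divergence_report()] enumerates where they differ
#' from the continuous presets.
#'
#' The printed capacitance entry of the "can" row is negative
#' (-32-16-8); a negative capacitance is unphysical, so by default its sign
#' is corrected to +56. Set `printed_can_C = TRUE` for the verbatim entry.
#'
#' @param name firing-pattern label (see [adex_pattern_names()]).
#' @param printed_can_C keep the printed negative capacitance of the "can"
#'   row instead of the sign-corrected +56.
#' @return Named list of [csd_terms()] objects (`C`, `gL`, `EL`, `VT`,
#'   `DeltaT`, `a`, `tau_w`, `b`, `Vr`, `I`), with the continuous target
#'   value of each attached.
#' @export
#' @examples
#' digital_preset("Tonic spiking")$C$value  # 200
digital_preset <- function(name, printed_can_C = FALSE) {
  if (!name %in% names(.digital_table))
    stop("unknown pattern '", name, "'; valid names: ",
         paste(names(.digital_table), collapse = ", "), call. = FALSE)
  d <- lapply(.digital_table[[name]], .parse_pow_terms)
  cont <- .preset_table[[name]]
  for (nm in names(d)) d[[nm]]$target <- unname(cont[nm])
  if (name == "can" && !printed_can_C)
    d$C <- csd_terms(-d$C$signs, d$C$exponents, target = unname(cont["C"]))
  d
}

# realized continuous values of a digital preset
.digital_values <- function(name, printed_can_C = FALSE) {
  vapply(digital_preset(name, printed_can_C), function(d) d$value, numeric(1))
}

#' Divergences between digitised and continuous parameters
#'
#' Row-by-row comparison of each stored power-of-two decomposition against
#' its continuous counterpart, plus the value realized by the independent
#' greedy [csd_decompose()].  Entries whose realized value departs from the
#' continuous one by more than `tol` (relative) are flagged.
#'
#' @param tol relative deviation above which an entry is flagged (default
#'   0.1).
#' @param printed_can_C passed to [digital_preset()].
#' @return A data frame with one row per (pattern, parameter).
#' @export
digital_divergence_report <- function(tol = 0.1, printed_can_C = FALSE) {
  rows <- lapply(adex_pattern_names(), function(nm) {
    d <- digital_preset(nm, printed_can_C)
    cont <- .preset_table[[nm]]
    data.frame(
      pattern = nm,
      param = names(d),
      continuous = unname(cont[names(d)]),
      realized = vapply(d, function(x) x$value, numeric(1)),
      terms = vapply(d, format, character(1)),
      greedy = vapply(names(d), function(p)
        csd_decompose(unname(cont[p]))$value, numeric(1)),
      row.names = NULL)
  })
  df <- do.call(rbind, rows)
  df$rel_dev <- ifelse(df$continuous == 0,
                       abs(df$realized - df$continuous),
                       abs(df$realized - df$continuous) / abs(df$continuous))
  df$flagged <- df$rel_dev > tol
  df
}

#' Simulate the multiplierless fixed-point pipeline
#'
#' Bit-exact emulation of the digital datapath: state and constants are
#' two's-complement fixed-point words; the nonlinearity is a table read; the
#' per-coefficient scalings `dt/C`, `dt/tau_w` and `a` are pre-decomposed
#' into canonical signed-digit form (at most 3 terms, exponents down to -25)
#' and applied as shift/add chains.  Every arithmetic event is tallied; the
#' tally contains no multiply, divide or exponential entries by
#' construction, which is the point being certified.  Overflow saturates
#' (and is counted) rather than wrapping, and the run continues, as the
#' hardware's does.
#'
#' All constants are taken from the digitised preset ([digital_preset()]),
#' not the continuous one.
#'
#' @param name firing-pattern label.
#' @param lut optional [build_lut()] table; by default one is built from the
#'   digitised parameter values with ceiling `C (v_max - v_min) / dt` (the
#'   smallest cap at which a single capped Euler step crosses the whole
#'   operating range, so the cap does not slow the upstroke).
#' @param fmt a [fixed_format()]; the default 44-bit/20-fraction word covers
#'   the table-value path (the printed 28-bit analysis applies to the
#'   membrane-voltage path only; see [bit_width_analysis()]).
#' @param dt time step (ms), default 1/128.
#' @param T duration (ms).
#' @param init initial [neuron_state()]; same default as [simulate_adex()].
#' @param printed_can_C passed to [digital_preset()].
#' @return A list of class `fixed_sim`: `trace` (a [voltage_trace()] on the
#'   mV/pA scale), `V_raw`, `W_raw` (integer words), `ops` (operation
#'   counts), `n_saturations`, `fmt`, `lut`, `csd` (the coefficient
#'   decompositions used).
#' @export
simulate_fixed <- function(name, lut = NULL, fmt = fixed_format(44, 20),
                           dt = 1 / 128, T = 1000, init = NULL,
                           printed_can_C = FALSE) {
  .check_sim_args(dt, T)
  dv <- .digital_values(name, printed_can_C)
  p <- do.call(adex_params, as.list(dv))
  if (is.null(lut))
    lut <- build_lut(p, ceiling = p$C * 70 / dt)
  init <- .default_init(init, p, lut$v_min)
  csd <- list(dtC = csd_decompose(dt / p$C, 3, -25),
              dtTau = csd_decompose(dt / p$tau_w, 3, -25),
              a = csd_decompose(p$a, 3, -25))
  n <- floor(T / dt)
  lut_fx <- to_fixed(lut$values, fmt)
  out <- .sim_fixed_cpp(
    to_fixed(p$I, fmt), to_fixed(p$EL, fmt), to_fixed(p$Vr, fmt),
    to_fixed(p$b, fmt),
    csd$dtC$exponents, csd$dtC$signs,
    csd$dtTau$exponents, csd$dtTau$signs,
    csd$a$exponents, csd$a$signs,
    lut_fx, lut$v_min, lut$dv,
    fmt$word_bits, fmt$frac_bits,
    to_fixed(init$V, fmt), to_fixed(init$W, fmt), n, to_fixed(10, fmt))
  t <- (0:n) * dt
  trace <- voltage_trace(t, from_fixed(out$V_raw, fmt),
                         from_fixed(out$W_raw, fmt),
                         spike_times = t[out$spike_idx + 1L])
  structure(list(trace = trace, V_raw = out$V_raw, W_raw = out$W_raw,
                 ops = out$ops, n_saturations = out$n_saturations,
                 fmt = fmt, lut = lut, csd = csd, params = p),
            class = "fixed_sim")
}

#' @export
print.fixed_sim <- function(x, ...) {
  cat("fixed-point pipeline run:\n  ")
  print(x$trace)
  cat(sprintf("  ops: %s; saturations: %d\n",
              paste(names(x$ops), unlist(x$ops), sep = "=", collapse = " "),
              x$n_saturations))
  invisible(x)
}

#' Write a fixed-point trace as CSV
#'
#' Dialect `t_ms,V_raw,W_raw,V_mV,W_pA,spike` with raw integer words
#' alongside the rescaled reals.
#'
#' @param sim a `fixed_sim` from [simulate_fixed()].
#' @param path file path.
#' @return `path` invisibly.
#' @export
write_fixed_trace_csv <- function(sim, path) {
  stopifnot(inherits(sim, "fixed_sim"))
  tr <- sim$trace
  df <- data.frame(t_ms = tr$t, V_raw = sim$V_raw, W_raw = sim$W_raw,
                   V_mV = tr$V, W_pA = tr$W,
                   spike = as.integer(tr$t %in% tr$spike_times))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Canonical per-model operation inventories.  Each row is one functional
# unit of the update datapath; the census is their tally, which reproduces
# the reference design's minimum-resource accounting.
.census_nodes <- list(
  original = data.frame(
    node = c("exp((V-VT)/DeltaT)",
             "gL*(EL-V)", "gL*DeltaT", "(gL*DeltaT)*exp", "a*(V-EL)",
             "dt*FV", "dt*FW",
             "(V-VT)/DeltaT", "leak/C", "expterm/C", "I/C", "W/C",
             "expterm/C + I/C", "leak/C + drive", "V + dt*FV", "W + dt*FW",
             "W + b",
             "EL - V", "V - VT", "V - EL", "drive - W/C", "a*(V-EL) - W",
             "apex comparator"),
    op = c("exp",
           rep("mul", 6),
           rep("div", 5),
           rep("add", 5),
           rep("sub", 6))),
  proposed = data.frame(
    node = c("ADX[V] + I", "V + dV", "W + dW",
             "drive - W", "V - EL", "a-branch - W"),
    op = c(rep("add", 3), rep("sub", 3)))
)

#' Minimum functional-unit census of the update datapath
#'
#' Tallies the exponential, multiplier, divider, adder and subtractor units
#' of the canonical update expression graph for the original model (exact
#' exponential, per-coefficient divisions) or the proposed N-LUT model
#' (table read plus shift/add scalings; constant scalings realized as
#' shifts are not multipliers).  The proposed census is independent of the
#' firing pattern.
#'
#' @param model `"original"` or `"proposed"`.
#' @return A named list of class `resource_census` with counts
#'   `exponential`, `multiplier`, `divider`, `adder`, `subtractor`; the node
#'   table is attached as attribute `"nodes"`.
#' @export
#' @examples
#' unlist(resource_census("proposed"))  # 0 0 0 3 3
resource_census <- function(model = c("original", "proposed")) {
  model <- match.arg(model)
  nodes <- .census_nodes[[model]]
  tab <- table(factor(nodes$op, levels = c("exp", "mul", "div", "add", "sub")))
  structure(list(exponential = unname(tab["exp"]),
                 multiplier = unname(tab["mul"]),
                 divider = unname(tab["div"]),
                 adder = unname(tab["add"]),
                 subtractor = unname(tab["sub"])),
            class = "resource_census", nodes = nodes, model = model)
}

#' @export
print.resource_census <- function(x, ...) {
  cat(sprintf("resource census (%s): exp=%d mul=%d div=%d add=%d sub=%d\n",
              attr(x, "model"), x$exponential, x$multiplier, x$divider,
              x$adder, x$subtractor))
  invisible(x)
}
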