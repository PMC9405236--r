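#' Fixed-point format
#'
#' A two's-complement word layout with `word_bits` total bits of which
#' `frac_bits` are fraction bits (one bit is the sign).  `word_bits` is
#' limited to 50 so every representable word is exact in a double.
#'
#' @param word_bits total word width (bits).
#' @param frac_bits fraction bits, `0 <= frac_bits < word_bits`.
#' @param signed must be `TRUE` (unsigned layouts are not used anywhere in
#'   the pipeline).
#' @return An object of class `fixed_format`.
#' @export
#' @examples
#' fixed_format(28, 20)
fixed_format <- function(word_bits, frac_bits, signed = TRUE) {
  stopifnot(isTRUE(signed))
  if (!is.numeric(word_bits) || !is.numeric(frac_bits) ||
      word_bits <= frac_bits || frac_bits < 0 || word_bits > 50)
    stop("need word_bits > frac_bits >= 0 and word_bits <= 50", call. = FALSE)
  structure(list(word_bits = as.integer(word_bits),
                 frac_bits = as.integer(frac_bits), signed = TRUE),
            class = "fixed_format")
}

#' @export
print.fixed_format <- function(x, ...) {
  cat(sprintf("fixed_format: Q%d.%d (%d-bit word, %d fraction bits)\n",
              x$word_bits - x$frac_bits - 1, x$frac_bits,
              x$word_bits, x$frac_bits))
  invisible(x)
}

.fx_limits <- function(fmt) {
  c(lo = -2^(fmt$word_bits - 1), hi = 2^(fmt$word_bits - 1) - 1)
}

#' Convert between reals and fixed-point integer words
#'
#' `to_fixed` rounds to the nearest representable value (ties away from
#' zero); values outside the word range saturate with a warning, matching
#' hardware saturation.  `from_fixed` rescales the integer word back to a
#' real; the round trip error is at most `2^(-frac_bits - 1)`.
#'
#' @param x real value(s).
#' @param rep integer word(s) as stored by `to_fixed`.
#' @param fmt a [fixed_format()].
#' @return Integer-valued numeric vector (`to_fixed`) or reals
#'   (`from_fixed`).
#' @export
#' @examples
#' to_fixed(1, fixed_format(28, 20))  # 1048576
to_fixed <- function(x, fmt) {
  stopifnot(inherits(fmt, "fixed_format"))
  r <- floor(abs(x) * 2^fmt$frac_bits + 0.5) * sign(x)
  lim <- .fx_limits(fmt)
  over <- r < lim["lo"] | r > lim["hi"]
  if (any(over)) {
    warning(sum(over), " value(s) saturated to the ",
            fmt$word_bits, "-bit word range", call. = FALSE)
    r <- pmin(pmax(r, lim["lo"]), lim["hi"])
  }
  r
}

#' @rdname to_fixed
#' @export
from_fixed <- function(rep, fmt) {
  stopifnot(inherits(fmt, "fixed_format"))
  rep / 2^fmt$frac_bits
}

#' Canonical signed-digit decomposition of a constant
#'
#' Greedy nearest-signed-power-of-two residual reduction: at each step the
#' signed power of two (with exponent at least `min_exponent`) closest to the
#' residual is appended, distance ties going to the larger exponent.  The
#' expansion stops at `max_terms` terms, when the residual is exactly zero,
#' or when no allowed term reduces the absolute residual.  Multiplication by
#' the realized value then needs only shifts and adds/subtracts.
#'
#' @param x the constant to decompose (non-zero unless an empty decomposition
#'   is acceptable).
#' @param max_terms maximum number of signed powers (default 3).
#' @param min_exponent smallest allowed exponent (default -2; the fixed-point
#'   pipeline extends this to -25 for sub-unity coefficients).
#' @return An object of class `csd` with fields `signs` (+1/-1), `exponents`
#'   (strictly decreasing integers), `value` (realized sum) and `target`.
#' @export
#' @examples
#' csd_decompose(1.8)$value  # 1.75 = 2 - 1/4
csd_decompose <- function(x, max_terms = 3, min_exponent = -2) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("x must be a single finite number", call. = FALSE)
  signs <- integer(0); expo <- integer(0)
  r <- x
  while (length(expo) < max_terms && r != 0) {
    e <- .nearest_pow2_exponent(abs(r), min_exponent)
    s <- if (r > 0) 1L else -1L
    if (abs(r - s * 2^e) >= abs(r)) break  # no allowed term improves
    signs <- c(signs, s); expo <- c(expo, e)
    r <- r - s * 2^e
  }
  csd_terms(signs, expo, target = x)
}

# nearest power-of-two exponent to a positive magnitude, ties to the larger
.nearest_pow2_exponent <- function(m, min_exponent) {
  e_hi <- max(ceiling(log2(m)), min_exponent)
  if (e_hi == min_exponent) return(e_hi)
  e_lo <- e_hi - 1L
  if (abs(2^e_hi - m) <= abs(m - 2^e_lo)) e_hi else e_lo
}

#' Construct a signed-power-of-two decomposition from explicit terms
#'
#' @param signs vector of +1/-1 term signs.
#' @param exponents matching integer exponents, strictly decreasing.
#' @param target the continuous constant the decomposition approximates
#'   (defaults to the realized value).
#' @return A `csd` object; `value` is the exact sum of the terms.
#' @export
csd_terms <- function(signs, exponents, target = NULL) {
  stopifnot(length(signs) == length(exponents))
  if (length(exponents) > 1 && any(diff(exponents) >= 0))
    stop("exponents must be strictly decreasing", call. = FALSE)
  if (anyDuplicated(exponents)) stop("duplicate exponents", call. = FALSE)
  value <- sum(signs * 2^exponents)
  if (is.null(target)) target <- value
  structure(list(signs = as.integer(signs), exponents = as.integer(exponents),
                 value = value, target = target),
            class = "csd")
}

#' @export
print.csd <- function(x, ...) {
  if (!length(x$exponents)) {
    cat("csd: 0 (empty)\n")
    return(invisible(x))
  }
  term <- paste0(ifelse(x$signs > 0, "+", "-"), "2^", x$exponents)
  cat(sprintf("csd: %s = %g (target %g)\n",
              paste(term, collapse = " "), x$value, x$target))
  invisible(x)
}

#' @export
format.csd <- function(x, ...) {
  if (!length(x$exponents)) return("0")
  paste(paste0(ifelse(x$signs > 0, "+", "-"), "2^", x$exponents),
        collapse = " ")
}

#' Operation trace
#'
#' A mutable tally of the arithmetic operations performed by the fixed-point
#' pipeline, used to certify multiplierless execution.
#'
#' @return An environment of class `op_trace` with counters `shift`, `add`,
#'   `sub`, `mul`, `div`, `exp`, `lut_read`.
#' @export
op_trace <- function() {
  e <- new.env(parent = emptyenv())
  for (nm in c("shift", "add", "sub", "mul", "div", "exp", "lut_read"))
    assign(nm, 0, envir = e)
  class(e) <- "op_trace"
  e
}

#' @export
print.op_trace <- function(x, ...) {
  v <- vapply(c("shift", "add", "sub", "mul", "div", "exp", "lut_read"),
              function(nm) get(nm, envir = x), numeric(1))
  cat("op_trace:\n"); print(v)
  invisible(x)
}

#' @export
as.list.op_trace <- function(x, ...) {
  nms <- c("shift", "add", "sub", "mul", "div", "exp", "lut_read")
  stats::setNames(lapply(nms, function(nm) get(nm, envir = x)), nms)
}

.trace_bump <- function(trace, what, by = 1) {
  if (is.null(trace)) return(invisible(NULL))
  assign(what, get(what, envir = trace) + by, envir = trace)
  invisible(NULL)
}

#' Multiply a fixed-point value by a decomposed constant using shifts
#'
#' Computes `v * d$value` exactly, using only arithmetic shifts and
#' additions/subtractions (one shift per term; one add or sub per term after
#' the first), logging each into `trace`.  Intermediate results saturate to
#' the word range with a warning.
#'
#' @param v fixed-point integer word(s).
#' @param d a [csd_decompose()] decomposition.
#' @param fmt a [fixed_format()].
#' @param trace optional [op_trace()] accumulator.
#' @return The scaled fixed-point word(s).
#' @export
shift_add_scale <- function(v, d, fmt, trace = NULL) {
  stopifnot(inherits(d, "csd"), inherits(fmt, "fixed_format"))
  lim <- .fx_limits(fmt)
  sat <- function(x) {
    over <- x < lim["lo"] | x > lim["hi"]
    if (any(over)) {
      warning("shift_add_scale: ", sum(over), " saturation(s)", call. = FALSE)
      x <- pmin(pmax(x, lim["lo"]), lim["hi"])
    }
    x
  }
  acc <- rep(0, length(v))
  for (t in seq_along(d$exponents)) {
    e <- d$exponents[t]
    term <- if (e >= 0) v * 2^e else floor(v / 2^(-e))  # arithmetic shift
    term <- sat(term)
    .trace_bump(trace, "shift")
    if (t == 1L) {
      acc <- if (d$signs[t] > 0) term else sat(-term)
    } else if (d$signs[t] > 0) {
      acc <- sat(acc + term); .trace_bump(trace, "add")
    } else {
      acc <- sat(acc - term); .trace_bump(trace, "sub")
    }
  }
  acc
}

#' Word-width analysis for the membrane-voltage datapath
#'
#' `integer_bits = ceil(log2(max(|v_min|, |v_max|)))`, plus the fraction
#' bits, one guard bit and one sign bit.  For the operating range
#' `[-60, +10]` mV with 20 fraction bits this gives `6 + 20 + 1 + 1 = 28`.
#'
#' @param v_min,v_max operating voltage range (mV), `v_min < v_max`.
#' @param frac_bits fraction bits (default 20).
#' @return Total word width in bits.
#' @export
#' @examples
#' bit_width_analysis(-60, 10)  # 28
bit_width_analysis <- function(v_min, v_max, frac_bits = 20) {
  if (!is.numeric(v_min) || !is.numeric(v_max) || v_min >= v_max)
    stop("degenerate range: need v_min < v_max", call. = FALSE)
  m <- max(abs(v_min), abs(v_max))
  integer_bits <- if (m <= 1) 0L else as.integer(ceiling(log2(m)))
  as.integer(integer_bits + frac_bits + 1L + 1L)
}

#' Export a lookup table as fixed-point memory words
#'
#' Writes each table value as a two's-complement hexadecimal word
#' (`ceil(word_bits/4)` digits), either one word per line (`dialect =
#' "hex"`) or as a COE-style memory-initialisation file (`dialect = "coe"`).
#' Values that do not fit the word error out before anything is written.
#'
#' @param lut a [build_lut()] table.
#' @param fmt a [fixed_format()].
#' @param path output file.
#' @param dialect `"hex"` or `"coe"`.
#' @return `path` invisibly.
#' @export
export_fixed_lut <- function(lut, fmt, path, dialect = c("hex", "coe")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(lut, "lut_spec"), inherits(fmt, "fixed_format"))
  lim <- .fx_limits(fmt)
  words <- floor(abs(lut$values) * 2^fmt$frac_bits + 0.5) * sign(lut$values)
  if (any(words < lim["lo"] | words > lim["hi"]))
    stop("table value overflows the ", fmt$word_bits, "-bit word", call. = FALSE)
  hx <- .to_hex_words(words, fmt$word_bits)
  if (dialect == "hex") {
    writeLines(hx, path)
  } else {
    writeLines(c("memory_initialization_radix=16;",
                 paste0("memory_initialization_vector=",
                        paste(hx, collapse = ","), ";")), path)
  }
  invisible(path)
}

#' @rdname export_fixed_lut
#' @param frac_bits fraction bits used when the file was written (needed to
#'   rescale on import).
#' @param word_bits word width used when the file was written.
#' @return `import_fixed_lut` returns the integer words.
#' @export
import_fixed_lut <- function(path, word_bits, frac_bits,
                             dialect = c("hex", "coe")) {
  dialect <- match.arg(dialect)
  ln <- readLines(path)
  hx <- if (dialect == "hex") {
    ln[nzchar(ln)]
  } else {
    vec <- grep("memory_initialization_vector", ln, value = TRUE)
    strsplit(sub(";.*$", "", sub("^.*=", "", vec)), ",")[[1]]
  }
  .from_hex_words(hx, word_bits)
}

# two's-complement hex encode/decode without 64-bit integer support:
# work digit by digit so words up to 50 bits stay exact.
.to_hex_words <- function(words, word_bits) {
  ndig <- ceiling(word_bits / 4)
  vapply(words, function(w) {
    if (w < 0) w <- w + 2^word_bits
    dig <- character(ndig)
    for (i in seq_len(ndig)) {
      dig[ndig - i + 1] <- sprintf("%X", w %% 16)
      w <- w %/% 16
    }
    paste(dig, collapse = "")
  }, character(1))
}

.from_hex_words <- function(hx, word_bits) {
  vals <- vapply(hx, function(h) {
    dig <- strtoi(strsplit(toupper(trimws(h)), "")[[1]], base = 16L)
    sum(dig * 16^(rev(seq_along(dig)) - 1))
  }, numeric(1), USE.NAMES = FALSE)
  ifelse(vals >= 2^(word_bits - 1), vals - 2^word_bits, vals)
}
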