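#' @keywords internal
"_PACKAGE"

# Half-up rounding (0.005 -> 0.01), the convention used when matching
# printed 2-decimal rates. base::round() rounds half to even.
round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  y <- x * s
  floor(y + 0.5 + abs(y) * 1e-12 + 1e-12) / s
}

# Half-up rounding of the ratio a/b in exact integer arithmetic:
# floor(a/b * 10^digits + 1/2) without any floating-point step.
round_ratio_half_up <- function(a, b, digits = 2) {
  s <- 10^digits
  (2 * a * s + b) %/% (2 * b) / s
}

# One reproducible RNG stream per subject, independent of generation order.
subject_seed <- function(seed, index) {
  as.integer(((as.double(seed) %% 2147483647) * 7919 +
                as.double(index) * 104729) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
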