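`%||%` <- function(a, b) if (is.null(a)) b else a

# round half away from zero to `digits` decimals (base round() is half-even)
round_half_away <- function(x, digits = 1L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# derive a stream of child seeds (< 2^31) from one master seed without
# touching the caller's RNG state
child_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

is_binary01 <- function(y) all(y %in% c(0, 1))
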