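# Shared helpers: RNG stream derivation, safe sampling, population SD.

# sample() treats a length-1 numeric x as 1:x; always sample from a vector.
sample_vec <- function(x, size = length(x), replace = FALSE) {
  if (length(x) == 1L && size == 1L) return(x)
  sample(x, size = size, replace = replace)
}

# Deterministic 32-bit sub-seed from a master seed and a string tag, so
# per-county (and per-realization) RNG streams are independent of the order
# in which units are processed. Doubles stay < 2^53 so arithmetic is exact.
derive_seed <- function(seed, tag) {
  h <- 0
  for (code in utf8ToInt(as.character(tag))) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer((abs(seed) %% 2147483647 * 69069 + h * 7919 + 1) %% 2147483647)
}

# Population standard deviation (N denominator); 0 for length-1 input.
pop_sd <- function(x) {
  if (length(x) <= 1L) return(0)
  sqrt(mean((x - mean(x))^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
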