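is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

is_scalar_count <- function(x) {
  is_scalar_number(x) && x >= 0 && x == trunc(x)
}

# Deterministic per-agent substream seed from a master seed and an agent id.
# Splitmix-style integer mixing kept in double arithmetic (< 2^53 throughout)
# so the result is a valid 32-bit R seed, reproducible on any platform and
# independent of the order in which agents are simulated.
derive_seed <- function(master_seed, id) {
  stopifnot(is_scalar_count(master_seed), all(id >= 0))
  x <- (master_seed %% 2147483647) + 1
  h <- (x * 2654435761 + id * 40503 + 12345) %% 2147483629
  as.integer(h %% 2147483646) + 1L
}

# Validate a 7-character binary string (exposure pattern or desert history).
check_bits <- function(bits, what = "pattern", n_bits = 7L) {
  if (!is.character(bits) || length(bits) != 1L || is.na(bits))
    stop(sprintf("%s must be a single character string", what), call. = FALSE)
  if (nchar(bits) != n_bits)
    stop(sprintf("%s must have exactly %d digits, got %d (\"%s\")",
                 what, n_bits, nchar(bits), bits), call. = FALSE)
  if (grepl("[^01]", bits))
    stop(sprintf("%s must contain only 0s and 1s (\"%s\")", what, bits),
         call. = FALSE)
  invisible(bits)
}

bits_to_logical <- function(bits) {
  strsplit(bits, "")[[1]] == "1"
}
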