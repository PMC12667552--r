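# Shared fixtures for the suite.

NINEMER <- "GCTGCTGCT"

# All DNA strings over `alphabet` of length 0..max_len (used by the
# exhaustive alignment-oracle tests).
all_strings <- function(max_len, alphabet = c("A", "C")) {
  out <- ""
  for (len in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(alphabet), len))
    out <- c(out, do.call(paste0, grid))
  }
  out
}

# Deterministic pseudo-random byte messages for codec property tests.
random_bytes <- function(n) as.raw(sample.int(256L, n, replace = TRUE) - 1L)
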