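# Seed derivation for reproducible substreams: iteration i of a procedure
# seeded with `seed` uses derive_seed(seed, i), so per-iteration results are
# stable under changes of the iteration count. Kept below 2^31 - 1.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 1e6 * 7919 + as.numeric(i) * 104729) %% 2147483647)
}
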