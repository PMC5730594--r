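# order-independent child seeds from the master seed and a string id.
# Lehmer-style multiplicative mixing (48271 mod 2^31-1, exact in doubles)
# after every character and a final scramble round: ids differing only in
# their last digit must not map to adjacent seeds, or the per-assemblage
# RNG streams become correlated.
derive_seed <- function(master, id) {
  p <- 2147483647
  h <- (as.numeric(master) %% (p - 1)) + 1
  for (ch in utf8ToInt(as.character(id)))
    h <- (h * 48271 + ch) %% p
  h <- (h * 48271) %% p
  as.integer((h * 48271) %% p)
}
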