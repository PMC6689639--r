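# Index sampling primitives shared (draw-for-draw) with the compiled
# engine. Both paths consume R's global RNG stream in the same order, so
# a run stepped in R reproduces a compiled run exactly. base::sample is
# avoided because its internal draw pattern cannot be reproduced from C
# with unif_rand() alone.

# One uniform index in 1..k; consumes exactly one uniform draw.
unif_index <- function(k) {
  u <- runif(1L)
  1L + min(as.integer(floor(u * k)), k - 1L)
}

# First d entries of a partial Fisher-Yates shuffle of 1..m: a uniform
# d-subset without replacement, in sampled order. Consumes exactly d
# uniform draws.
sample_index <- function(m, d) {
  pool <- seq_len(m)
  for (i in seq_len(d)) {
    j <- i - 1L + unif_index(m - i + 1L)
    tmp <- pool[i]
    pool[i] <- pool[j]
    pool[j] <- tmp
  }
  pool[seq_len(d)]
}

# Uniform choice among a vector of candidate positions (tie-breaking).
# Always consumes one draw, even for a single candidate, to keep the
# stream aligned with the compiled engine.
pick_uniform <- function(candidates) {
  candidates[unif_index(length(candidates))]
}
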