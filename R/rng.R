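# Random-draw contract shared by the R reference engine and the C++ engine.
#
# Every stochastic decision in the life cycle is expressed through the two
# primitives below, each consuming a fixed number of uniforms from R's global
# RNG stream in a documented order.  The C++ engine reproduces the identical
# arithmetic through unif_rand(), so both engines yield bitwise-equal
# trajectories from the same seed.  Keep base helpers such as sample(),
# sum() and mean() out of any draw-relevant computation: their internal
# algorithms/accumulators are not reproducible from the C RNG API.

# One uniform draw -> index in 1..k.
rng_index <- function(k) {
  j <- 1L + as.integer(stats::runif(1) * k)
  if (j > k) k else j
}

# Uniform random permutation of 1..n via Fisher-Yates (n - 1 draws; none for
# n < 2).
rng_perm <- function(n) {
  p <- seq_len(n)
  if (n >= 2L) {
    for (i in n:2L) {
      j <- rng_index(i)
      tmp <- p[i]
      p[i] <- p[j]
      p[j] <- tmp
    }
  }
  p
}

# Roulette-wheel draw over nonnegative weights: one uniform, cumulative walk
# with plain double accumulation (matching the C++ engine exactly).  All-zero
# (or fully non-positive) weights fall back to a uniform index draw.
rng_roulette <- function(weights) {
  n <- length(weights)
  cum <- numeric(n)
  tot <- 0
  for (i in seq_len(n)) {
    wi <- weights[i]
    if (wi < 0) wi <- 0
    tot <- tot + wi
    cum[i] <- tot
  }
  if (tot <= 0) {
    return(rng_index(n))
  }
  u <- stats::runif(1) * tot
  for (i in seq_len(n)) {
    if (u < cum[i]) {
      return(i)
    }
  }
  n
}

# Window mean with plain double accumulation (see note above).
plain_mean <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  s / length(x)
}
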