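# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# mass-shift distribution of a molecule with k tracer carbons out of n, by
# explicit enumeration of heavy-isotope placements on the n - k non-tracer
# carbons (each heavy with probability p)
enumerate_mass_shift <- function(n, k, p) {
  free <- n - k
  out <- numeric(n + 1)
  if (free == 0) {
    out[k + 1] <- 1
    return(out)
  }
  for (code in 0:(2^free - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(free)]
    h <- sum(bits)
    out[k + h + 1] <- out[k + h + 1] + p^h * (1 - p)^(free - h)
  }
  out
}

# textbook pooled two-sample t (b vs a), two-tailed p
pooled_t_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), df = n1 + n2 - 2))
}

# random valid MID of length n + 1 (normalized exponentials)
random_mid <- function(n) {
  x <- rexp(n + 1)
  x / sum(x)
}
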