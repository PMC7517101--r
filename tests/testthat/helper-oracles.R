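# Independent oracles used to cross-check the implementation.

# Entropy-sum mutual information oracle: I = H(X) + H(Y) - H(X,Y), in bits.
mi_entropy_oracle <- function(p) {
  p <- p / sum(p)
  h <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  h(rowSums(p)) + h(colSums(p)) - h(as.vector(p))
}

entropy_bits_oracle <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }

# Brute-force: MI values attainable by permuting y over ALL orderings.
enumerate_permutation_mi <- function(x, y) {
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  vapply(perms(y), function(yp) {
    mi_entropy_oracle(as.matrix(table(factor(yp, 0:1), factor(x, 0:1))))
  }, numeric(1))
}

# Random joint probability table.
random_prob_table <- function(k = 2, m = 2) {
  tab <- matrix(stats::rexp(k * m), k, m)
  tab / sum(tab)
}

sim_obs_quick <- function(nobs = 60, s = 0.4, a = 0.1, seed = 1) {
  simulate_observations(nobs, s = s, a = a, seed = seed)
}
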