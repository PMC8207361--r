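# Independent oracles used across the suite.

# Asymptotic growth rate by bisection on the Euler-Lotka equation
# sum_i R_i * l_i * lambda^(-i) = 1, with l_1 = 1 (newborn survival is 1)
# and l_{i+1} = l_i * s_i the cumulative survivorship. Independent of the
# eigen-decomposition route used by the package.
ol_growth_rate <- function(vr, lower = 1e-6, upper = 4, tol = 1e-12) {
  s <- pmax(0, 1 - vr$M - vr$Fvec)
  l <- cumprod(c(1, s[-vr$n_ages]))
  f <- function(lam) sum(vr$R * l * lam^(-seq_len(vr$n_ages))) - 1
  # f is decreasing in lambda; root bracketed in (lower, upper)
  stats::uniroot(f, c(lower, upper), tol = tol)$root
}

# Direct-summation Shannon index oracle (no zero-handling shortcuts).
ol_shannon <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

# Fraction of fish sitting in a cell whose habitat index is (one of) the
# closest level(s) to the fish's preference.
reached_fraction <- function(state, grid) {
  lev <- seq(0, 1, by = 0.1)
  best <- vapply(state$Z, function(z) min(abs(lev - z)), numeric(1))
  mean(abs(grid$H[state$cell] - state$Z) <= best + 1e-12)
}
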