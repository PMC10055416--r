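# Shared fixtures: all synthetic, generated in code.

# Well-conditioned random correlation matrix: Gram matrix of 2m Gaussian
# rows, normalized to unit diagonal.
random_corr <- function(m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(2 * m * m), 2 * m, m)
  S <- crossprod(A) / (2 * m)
  d <- sqrt(diag(S))
  S / (d %o% d)
}

# Single strong association in an otherwise null locus with identity LD.
spike_stats <- function(m = 20, idx = 7, z_val = 6, n = 5000) {
  z <- numeric(m)
  z[idx] <- z_val
  summary_stats(z, diag(m), n)
}
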