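# Independent oracles used to check the package's computations. These stay
# deliberately naive: direct dense linear algebra and explicit enumeration,
# sharing no code with the implementation paths they verify.

# Dense multivariate normal log-pdf at the origin-mean model
# Sigma = M + M diag(n*sigma2*c) M, computed from scratch with solve()/det().
oracle_mvn_loglik <- function(stats, cvec, sigma2 = 0.005, ridge = 1e-4) {
  m <- stats$m
  M <- stats$ld
  diag(M) <- diag(M) + ridge
  Sigma <- M + M %*% (stats$n * sigma2 * cvec * M)
  Sigma <- (Sigma + t(Sigma)) / 2
  ld <- determinant(Sigma, logarithm = TRUE)
  -0.5 * (m * log(2 * pi) + as.numeric(ld$modulus) +
            drop(crossprod(stats$z, solve(Sigma, stats$z))))
}

# All causal configurations with support size <= smax, as index vectors.
enumerate_configs <- function(m, smax = m) {
  out <- list(integer(0))
  for (k in seq_len(smax)) {
    out <- c(out, utils::combn(m, k, simplify = FALSE))
  }
  out
}

# Brute-force configuration posterior and PIPs by explicit enumeration.
oracle_posterior <- function(stats, configs, p0, sigma2 = 0.005, ridge = 1e-4) {
  m <- stats$m
  lw <- vapply(configs, function(ix) {
    b <- numeric(m)
    b[ix] <- 1
    oracle_mvn_loglik(stats, b, sigma2, ridge) +
      length(ix) * log(p0) + (m - length(ix)) * log(1 - p0)
  }, numeric(1))
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  pip <- numeric(m)
  for (j in seq_along(configs)) pip[configs[[j]]] <- pip[configs[[j]]] + w[j]
  list(prob = w, pip = pip)
}

# Precision-recall area by cumulative-count sweep over a descending sort --
# an independent formulation of the tie-grouped step integral.
oracle_auprc <- function(score, truth) {
  ord <- order(-score)
  s <- score[ord]
  y <- truth[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  P <- sum(y)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  prec <- (tp / (tp + fp))[last_of_tie]
  rec <- (tp / P)[last_of_tie]
  sum(diff(c(0, rec)) * prec)
}
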