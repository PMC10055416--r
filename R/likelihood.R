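#' Multivariate-normal log-likelihood of GWAS z-scores
#'
#' Evaluates `log N(z; 0, Sigma)` with
#' `Sigma = M + M (n * sigma2 * diag(c)) M`, where `M` is the
#' ridge-stabilized LD matrix and `c` is a (possibly relaxed) causal vector
#' in `[0,1]^m`. This is the generative model tying a causal configuration
#' to the observed summary statistics.
#'
#' Two evaluation paths are provided. `"dense"` forms `Sigma` explicitly and
#' factorizes it (O(m^3)). `"lowrank"` exploits the sparsity of `c`: writing
#' `Sigma = M + U D U'` with `U = M[, s]` the LD columns of the support
#' `s = {i : c_i > 0}` and `D = n * sigma2 * diag(c_s)`, the Woodbury and
#' matrix-determinant identities reduce everything to k-by-k solves against
#' a cached factorization of `M`:
#' \deqn{z' \Sigma^{-1} z = z' M^{-1} z - z_s' (D^{-1} + M_{ss})^{-1} z_s}
#' \deqn{\log\det\Sigma = \log\det M + \log\det(I + D^{1/2} M_{ss} D^{1/2})}
#' so each evaluation costs O(k^3) after the one-time Cholesky of `M`.
#'
#' @param stats A [summary_stats()] object.
#' @param c Numeric vector in `[0,1]^m`, the causal vector.
#' @param prior An [effect_prior()].
#' @param method `"lowrank"` (default) or `"dense"`.
#' @param cache Optional precomputed LD factorization (internal reuse).
#' @return The log-density, a single number.
#' @examples
#' ss <- summary_stats(c(0, 0), diag(2), n = 100)
#' gwas_log_likelihood(ss, c(0, 0), effect_prior(ridge = 0))  # -log(2*pi)
#' @export
gwas_log_likelihood <- function(stats, c, prior = effect_prior(),
                                method = c("lowrank", "dense"), cache = NULL) {
  method <- match.arg(method)
  if (length(c) != stats$m) {
    stop_input("dimension mismatch: length(c) = %d but m = %d", length(c), stats$m)
  }
  if (any(c < 0 | c > 1)) stop_input("c must lie in [0,1]")
  if (method == "dense") {
    return(gwas_ll_dense(stats, c, prior))
  }
  if (is.null(cache)) cache <- ld_cache(stats, prior)
  gwas_ll_lowrank(cache, c)
}

gwas_ll_dense <- function(stats, c, prior) {
  m <- stats$m
  M <- stats$ld
  diag(M) <- diag(M) + prior$ridge
  s <- stats$n * prior$sigma2 * c
  Sigma <- M + M %*% (s * M)
  Sigma <- (Sigma + t(Sigma)) / 2
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
    stop_numeric("covariance not positive definite (smallest eigenvalue %.3g)", ev)
  }
  u <- backsolve(ch, stats$z, transpose = TRUE)
  -0.5 * (m * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(u^2))
}

gwas_ll_lowrank <- function(cache, c) {
  s <- which(c > 0)
  k <- length(s)
  if (k == 0) return(cache$base_ll)
  d <- cache$nsigma2 * c[s]
  dh <- sqrt(d)
  Mss <- cache$M[s, s, drop = FALSE]
  K <- diag(k) + (dh %o% dh) * Mss
  chK <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(chK)) {
    ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
    stop_numeric("low-rank capacitance not positive definite (smallest eigenvalue %.3g)", ev)
  }
  v <- backsolve(chK, dh * cache$z[s], transpose = TRUE)
  quad <- cache$q0 - sum(v^2)
  logdet <- cache$logdetM + 2 * sum(log(diag(chK)))
  -0.5 * (cache$m * log(2 * pi) + logdet + quad)
}

# Log-likelihood plus its gradient with respect to the support entries of c.
# d ll / d c_i = 0.5 * n * sigma2 * ( (M Sigma^{-1} z)_i^2 - (M Sigma^{-1} M)_{ii} )
# for i in the support, evaluated through the same Woodbury reduction.
gwas_ll_grad <- function(cache, c) {
  s <- which(c > 0)
  k <- length(s)
  if (k == 0) {
    return(list(ll = cache$base_ll, support = integer(0), grad = numeric(0)))
  }
  d <- cache$nsigma2 * c[s]
  dh <- sqrt(d)
  Mss <- cache$M[s, s, drop = FALSE]
  K <- diag(k) + (dh %o% dh) * Mss
  chK <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(chK)) {
    ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
    stop_numeric("low-rank capacitance not positive definite (smallest eigenvalue %.3g)", ev)
  }
  zs <- cache$z[s]
  v <- backsolve(chK, dh * zs, transpose = TRUE)
  ll <- -0.5 * (cache$m * log(2 * pi) +
                  cache$logdetM + 2 * sum(log(diag(chK))) +
                  cache$q0 - sum(v^2))
  # alpha = (D^{-1} + Mss)^{-1} z_s ; w_s = (M Sigma^{-1} z)_s = z_s - Mss alpha
  alpha <- dh * backsolve(chK, v)
  ws <- zs - drop(Mss %*% alpha)
  # diag of (M Sigma^{-1} M)_ss = Mss - T' K^{-1} T with T = Dh Mss
  Tm <- dh * Mss
  Y <- backsolve(chK, Tm, transpose = TRUE)
  diagB <- diag(Mss) - colSums(Y^2)
  grad <- 0.5 * cache$nsigma2 * (ws^2 - diagB)
  list(ll = ll, support = s, grad = grad)
}
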