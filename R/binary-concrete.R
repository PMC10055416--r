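#' Sample from the binary concrete distribution
#'
#' The binary concrete (relaxed Bernoulli) distribution places its mass on
#' the open interval (0,1); temperature `lam` controls how tightly samples
#' concentrate near \{0,1\}. Sampling uses the reparameterization
#' `c_i = sigmoid((logit(u_i) + logit(p_i)) / lam)` with `u_i ~ Uniform(0,1)`,
#' which makes draws differentiable in `p` (see [bc_sample_grad()]). A key
#' law of the distribution is `P(c_i > 1/2) = p_i` at every temperature.
#'
#' @param p Numeric vector of probabilities in (0,1) (clamped at 1e-6).
#' @param lam Positive temperature.
#' @param u Optional uniform draws, strictly inside (0,1); a matrix draws one
#'   sample per row. If `NULL`, draws are taken from the R RNG.
#' @param seed Optional integer seed used when `u` is `NULL`.
#' @return Samples with the shape of `u` (vector or matrix).
#' @examples
#' bc_sample(p = c(0.5, 0.9), lam = 1, u = c(0.5, 0.5)) # 0.5, 0.9
#' @export
bc_sample <- function(p, lam, u = NULL, seed = NULL) {
  if (lam <= 0) stop_input("lam must be > 0")
  p <- clamp_prob(p)
  if (is.null(u)) {
    if (!is.null(seed)) set.seed(seed)
    u <- runif(length(p))
  }
  if (any(u <= 0 | u >= 1)) stop_input("u must lie strictly inside (0,1)")
  lp <- logit(p)
  if (is.matrix(u)) {
    if (ncol(u) != length(p)) stop_input("ncol(u) = %d but length(p) = %d", ncol(u), length(p))
    sigmoid(sweep(logit(u), 2, lp, "+") / lam)
  } else {
    if (length(u) != length(p)) stop_input("length(u) = %d but length(p) = %d", length(u), length(p))
    sigmoid((logit(u) + lp) / lam)
  }
}

# Sample and its derivative with respect to p (the reparameterization
# gradient): dc/dp = c(1-c) / (lam * p * (1-p)).
bc_sample_grad <- function(p, lam, u) {
  p <- clamp_prob(p)
  c <- bc_sample(p, lam, u)
  dcdp <- c * (1 - c) / (lam * p * (1 - p))
  list(c = c, dc_dp = dcdp)
}

#' Log-density of the binary concrete distribution
#'
#' Sums the element-wise log-density
#' `log q(c_i; p_i, lam) = log lam + log p_i + log(1-p_i)
#'  - (lam+1)(log c_i + log(1-c_i)) - 2 log(p_i c_i^{-lam} + (1-p_i)(1-c_i)^{-lam})`
#' over the vector, with the final term evaluated in log space.
#'
#' @inheritParams bc_sample
#' @param c Numeric vector strictly inside (0,1).
#' @return Total log-density, a single number.
#' @export
bc_log_density <- function(p, lam, c) {
  if (lam <= 0) stop_input("lam must be > 0")
  if (any(c <= 0 | c >= 1)) stop_input("c must lie strictly inside (0,1)")
  p <- clamp_prob(p)
  if (length(c) != length(p)) stop_input("length(c) = %d but length(p) = %d", length(c), length(p))
  # log(p c^-lam + (1-p)(1-c)^-lam) via pairwise logsumexp
  a <- log(p) - lam * log(c)
  b <- log1p(-p) - lam * log1p(-c)
  mx <- pmax(a, b)
  log_denom <- mx + log(exp(a - mx) + exp(b - mx))
  sum(log(lam) + log(p) + log1p(-p) -
        (lam + 1) * (log(c) + log1p(-c)) - 2 * log_denom)
}

#' KL divergence from the proposal to the prior (Bernoulli limit)
#'
#' In the small-temperature regime the binary concrete distribution behaves
#' like a Bernoulli, and the KL divergence between proposal and prior
#' reduces to the closed-form Bernoulli KL
#' `sum_i p_i log(p_i/p0) + (1-p_i) log((1-p_i)/(1-p0))`. This is the
#' sparsity regularizer of the variational objective; it is non-negative and
#' zero only when every `p_i` equals `p0`.
#'
#' @param p Numeric vector of proposal probabilities.
#' @param prior A [prior_config()] (or a bare scalar `p0`).
#' @return The KL divergence, a single non-negative number.
#' @export
bc_kl_to_prior <- function(p, prior = prior_config(p0 = 0.5)) {
  p0 <- if (inherits(prior, "prior_config")) {
    prior$p0 %||% stop_input("prior p0 unresolved; supply p0 or use resolve via m")
  } else {
    prior
  }
  p <- clamp_prob(p)
  sum(p * (log(p) - log(p0)) + (1 - p) * (log1p(-p) - log1p(-p0)))
}
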