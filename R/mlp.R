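# The inference network: a fully connected multilayer perceptron mapping the
# z-score vector to the probability map p in (0,1)^m. Trained per locus from
# random initialization; forward, backward and the Adam update are written
# out explicitly so the package has no deep-learning runtime dependency.

#' Inference-network configuration
#'
#' @param hidden_sizes Integer vector of hidden-layer widths.
#' @param activation `"relu"` or `"tanh"` hidden nonlinearity.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `inference_net_config`.
#' @export
inference_net_config <- function(hidden_sizes = c(256, 256),
                                 activation = c("relu", "tanh"),
                                 seed = 1L) {
  activation <- match.arg(activation)
  if (any(hidden_sizes < 1)) stop_input("hidden_sizes must be positive")
  structure(
    list(hidden_sizes = as.integer(hidden_sizes), activation = activation,
         seed = as.integer(seed)),
    class = "inference_net_config"
  )
}

# Glorot-uniform hidden weights. The output layer starts at zero weight with
# bias logit(p0), so the initial probability map equals the prior exactly for
# any input; the output weights pick up gradient from the first step onward.
mlp_init <- function(m, cfg, p0) {
  sizes <- c(m, cfg$hidden_sizes, m)
  nl <- length(sizes) - 1
  W <- vector("list", nl)
  b <- vector("list", nl)
  for (l in seq_len(nl)) {
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1]))
    W[[l]] <- matrix(runif(sizes[l] * sizes[l + 1], -lim, lim), sizes[l + 1], sizes[l])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  W[[nl]] <- matrix(0, m, sizes[nl])
  b[[nl]] <- rep(logit(clamp_prob(p0)), m)
  list(W = W, b = b, activation = cfg$activation, nl = nl)
}

act_fun <- function(x, kind) if (kind == "relu") pmax(x, 0) else tanh(x)

act_grad <- function(x, kind) if (kind == "relu") as.numeric(x > 0) else 1 - tanh(x)^2

# Forward pass; returns the clamped probability map plus everything the
# backward pass needs.
mlp_forward <- function(net, z) {
  nl <- net$nl
  h <- vector("list", nl + 1)
  a <- vector("list", nl)
  h[[1]] <- z
  for (l in seq_len(nl)) {
    a[[l]] <- drop(net$W[[l]] %*% h[[l]]) + net$b[[l]]
    h[[l + 1]] <- if (l < nl) act_fun(a[[l]], net$activation) else sigmoid(a[[l]])
  }
  p_raw <- h[[nl + 1]]
  list(p = clamp_prob(p_raw), p_raw = p_raw, h = h, a = a)
}

# Backward pass: gradient of a scalar loss with respect to all weights,
# given dL/dp at the (unclamped) sigmoid output.
mlp_backward <- function(net, fwd, dL_dp) {
  nl <- net$nl
  gW <- vector("list", nl)
  gb <- vector("list", nl)
  delta <- dL_dp * fwd$p_raw * (1 - fwd$p_raw)
  for (l in rev(seq_len(nl))) {
    gW[[l]] <- delta %o% fwd$h[[l]]
    gb[[l]] <- delta
    if (l > 1) {
      delta <- drop(crossprod(net$W[[l]], delta)) * act_grad(fwd$a[[l - 1]], net$activation)
    }
  }
  list(W = gW, b = gb)
}

adam_init <- function(net) {
  zero_like <- function(x) lapply(x, function(v) v * 0)
  list(mW = zero_like(net$W), vW = zero_like(net$W),
       mb = zero_like(net$b), vb = zero_like(net$b), t = 0)
}

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$W[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    net$W[[l]] <- net$W[[l]] - lr * (state$mW[[l]] / bc1) / (sqrt(state$vW[[l]] / bc2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    net$b[[l]] <- net$b[[l]] - lr * (state$mb[[l]] / bc1) / (sqrt(state$vb[[l]] / bc2) + eps)
  }
  list(net = net, state = state)
}
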