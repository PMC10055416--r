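#' Training configuration for the variational fit
#'
#' @param iters Number of gradient iterations T.
#' @param mc_samples Monte Carlo samples L per iteration.
#' @param step_size Adam learning rate.
#' @param lam_init,lam_final Relaxation temperature annealed geometrically
#'   from `lam_init` to `lam_final` over the run; `lam_final` defaults to
#'   0.01, the Bernoulli-like regime in which the KL approximation holds.
#' @param support_threshold Entries of a sampled causal vector at or below
#'   this value are zeroed before the likelihood is evaluated.
#' @param support_cap At most this many entries are kept per sample (largest
#'   values win; ties broken by lowest variant index).
#' @param binarize_gamma Threshold used to binarize sampled causal vectors
#'   into harvested configurations (default 0.1).
#' @param seed Integer seed controlling all randomness of the fit.
#' @return An object of class `train_config`.
#' @export
train_config <- function(iters = 2000L, mc_samples = 10L, step_size = 1e-3,
                         lam_init = 0.5, lam_final = 0.01,
                         support_threshold = 0.01, support_cap = 50L,
                         binarize_gamma = 0.1, seed = 1L) {
  if (iters < 1 || mc_samples < 1) stop_input("iters and mc_samples must be positive")
  if (lam_final > lam_init) stop_input("lam_final must be <= lam_init")
  if (!(support_threshold > 0 && support_threshold < binarize_gamma && binarize_gamma < 1)) {
    stop_input("need 0 < support_threshold < binarize_gamma < 1")
  }
  structure(
    list(iters = as.integer(iters), mc_samples = as.integer(mc_samples),
         step_size = step_size, lam_init = lam_init, lam_final = lam_final,
         support_threshold = support_threshold, support_cap = as.integer(support_cap),
         binarize_gamma = binarize_gamma, seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Binarize a relaxed causal vector
#'
#' `b_i = 1` iff `c_i > gamma` (strictly). With the default `gamma = 0.1`
#' only variants whose estimated effect-size variance exceeds `0.1 * sigma2`
#' survive into a harvested configuration.
#'
#' @param c Numeric vector in `[0,1]`.
#' @param gamma Threshold in (0,1).
#' @return Integer 0/1 vector.
#' @examples
#' binarize(c(0.05, 0.5, 0.95), 0.1)
#' @export
binarize <- function(c, gamma = 0.1) {
  if (gamma <= 0 || gamma >= 1) stop_input("gamma must lie in (0,1)")
  as.integer(c > gamma)
}

# Zero entries <= threshold; if more than cap survive keep the cap largest
# (ties by lowest index, which order() gives natively).
prune_support <- function(c, threshold, cap) {
  keep <- which(c > threshold)
  if (length(keep) > cap) {
    keep <- keep[order(-c[keep])][seq_len(cap)]
  }
  out <- numeric(length(c))
  out[keep] <- c[keep]
  out
}

#' Variational loss (negated evidence lower bound)
#'
#' Monte Carlo estimate of the objective minimized during fitting: the
#' negated mean log-likelihood of the z-scores over `L` sampled causal
#' vectors, plus the Bernoulli-limit KL divergence from the proposal to the
#' prior. Sampled vectors are support-pruned exactly as in the training
#' loop before the likelihood is evaluated.
#'
#' @param stats A [summary_stats()] object.
#' @param p Probability map in (0,1)^m.
#' @param lam Relaxation temperature used for sampling.
#' @param prior A [prior_config()]; a `NULL` `p0` resolves to 1/m.
#' @param eff An [effect_prior()].
#' @param u_draws L-by-m matrix of uniforms strictly inside (0,1).
#' @param support_threshold,support_cap Pruning constants (see
#'   [train_config()]).
#' @return The loss, a single number.
#' @export
vi_loss <- function(stats, p, lam, prior = prior_config(), eff = effect_prior(),
                    u_draws, support_threshold = 0.01, support_cap = 50L) {
  cache <- ld_cache(stats, eff)
  p0 <- resolve_p0(prior, stats$m)
  cs <- bc_sample(p, lam, u = u_draws)
  if (!is.matrix(cs)) cs <- matrix(cs, nrow = 1)
  ll <- vapply(seq_len(nrow(cs)), function(l) {
    gwas_ll_lowrank(cache, prune_support(cs[l, ], support_threshold, support_cap))
  }, numeric(1))
  -mean(ll) + bc_kl_to_prior(p, p0)
}

#' Probability map from a fitted inference network
#'
#' Deterministic forward pass of the network on a z-score vector. Mostly
#' useful for inspecting a fit; [fit_finemap_vi()] calls it internally every
#' iteration.
#'
#' @param net_state Network state as stored in a fit result.
#' @param z Numeric z-score vector of the dimension the network was built for.
#' @return Numeric vector in (0,1)^m.
#' @export
probability_map <- function(net_state, z) {
  if (length(z) != ncol(net_state$W[[1]])) {
    stop_input("z has length %d but network input is %d", length(z), ncol(net_state$W[[1]]))
  }
  mlp_forward(net_state, z)$p
}

#' Fit the variational fine-mapping model to one locus
#'
#' Runs the stochastic optimization: at every iteration the inference
#' network produces the probability map `p = F(z; phi)`, `L` relaxed causal
#' vectors are sampled by the reparameterization trick, each is
#' support-pruned, binarized (threshold `binarize_gamma`) and harvested into
#' the configuration set, the Monte Carlo loss and its gradient are
#' evaluated, and one Adam step is taken on the network weights. The
#' temperature is annealed geometrically from `lam_init` to `lam_final`.
#'
#' @param stats A [summary_stats()] object.
#' @param net_cfg An [inference_net_config()].
#' @param tr A [train_config()].
#' @param prior A [prior_config()].
#' @param eff An [effect_prior()].
#' @return A list with `p_map` (final probability map), `configs` (the
#'   harvested configuration set), `loss_trace`, `lam_trace`, and `net` (the
#'   trained network state). Identical seeds give identical results.
#' @export
fit_finemap_vi <- function(stats, net_cfg = inference_net_config(),
                           tr = train_config(), prior = prior_config(),
                           eff = effect_prior()) {
  m <- stats$m
  p0 <- resolve_p0(prior, m)
  cache <- ld_cache(stats, eff)

  set.seed(net_cfg$seed)
  net <- mlp_init(m, net_cfg, p0)
  opt <- adam_init(net)

  set.seed(tr$seed)
  n_iter <- tr$iters
  L <- tr$mc_samples
  lam_sched <- tr$lam_init * (tr$lam_final / tr$lam_init)^((seq_len(n_iter) - 1) / max(n_iter - 1, 1))
  loss_trace <- numeric(n_iter)
  harvest <- new.env(parent = emptyenv())

  log_p0 <- log(p0)
  log_1p0 <- log1p(-p0)

  for (t in seq_len(n_iter)) {
    lam <- lam_sched[t]
    fwd <- mlp_forward(net, stats$z)
    p <- fwd$p
    U <- matrix(runif(L * m), L, m)
    lp <- logit(p)

    dL_dp <- numeric(m)
    ll_sum <- 0
    for (l in seq_len(L)) {
      c_raw <- sigmoid((logit(U[l, ]) + lp) / lam)
      c_l <- prune_support(c_raw, tr$support_threshold, tr$support_cap)
      # harvest the binarized configuration
      key_idx <- which(c_l > tr$binarize_gamma)
      key <- paste0("k", paste(key_idx, collapse = ","))
      prev <- harvest[[key]]
      harvest[[key]] <- if (is.null(prev)) list(idx = key_idx, count = 1L) else {
        prev$count <- prev$count + 1L
        prev
      }
      g <- gwas_ll_grad(cache, c_l)
      ll_sum <- ll_sum + g$ll
      if (length(g$support)) {
        sidx <- g$support
        dcdp <- c_l[sidx] * (1 - c_l[sidx]) / (lam * p[sidx] * (1 - p[sidx]))
        dL_dp[sidx] <- dL_dp[sidx] - g$grad * dcdp / L
      }
    }
    kl <- sum(p * (log(p) - log_p0) + (1 - p) * (log1p(-p) - log_1p0))
    loss <- -ll_sum / L + kl
    if (!is.finite(loss)) {
      stop_numeric("non-finite loss at iteration %d; try a smaller step_size", t)
    }
    loss_trace[t] <- loss
    dL_dp <- dL_dp + (log(p) - log_p0) - (log1p(-p) - log_1p0)

    grads <- mlp_backward(net, fwd, dL_dp)
    upd <- adam_step(net, grads, opt, tr$step_size)
    net <- upd$net
    opt <- upd$state
  }

  keys <- ls(harvest, sorted = TRUE)
  configs <- configuration_set(
    configs = lapply(keys, function(k) harvest[[k]]$idx),
    counts = vapply(keys, function(k) harvest[[k]]$count, integer(1)),
    m = m
  )
  list(
    p_map = mlp_forward(net, stats$z)$p,
    configs = configs,
    loss_trace = loss_trace,
    lam_trace = lam_sched,
    net = net
  )
}

#' Set of harvested causal configurations
#'
#' A deduplicated collection of binary causal configurations, each stored as
#' the integer indices of its causal variants, together with how often each
#' was harvested during optimization. Counts are diagnostics only: posterior
#' weight comes from re-scoring each configuration under the likelihood.
#'
#' @param configs List of integer index vectors (possibly empty vectors for
#'   the null configuration).
#' @param counts Integer multiplicities (default all 1).
#' @param m Number of variants the configurations refer to.
#' @return An object of class `configuration_set`.
#' @export
configuration_set <- function(configs, counts = NULL, m) {
  configs <- lapply(configs, function(ix) sort(as.integer(ix)))
  keys <- vapply(configs, paste, character(1), collapse = ",")
  if (anyDuplicated(keys)) stop_input("duplicate configurations in configuration_set")
  if (length(configs) && max(c(0L, unlist(configs))) > m) {
    stop_input("configuration index exceeds m = %d", m)
  }
  counts <- counts %||% rep(1L, length(configs))
  structure(
    list(configs = configs, counts = as.integer(counts), m = as.integer(m)),
    class = "configuration_set"
  )
}

#' @export
print.configuration_set <- function(x, ...) {
  sizes <- lengths(x$configs)
  cat(sprintf(
    "<configuration_set> %d configurations over m = %d variants (support 0-%d, %d draws)\n",
    length(x$configs), x$m, if (length(sizes)) max(sizes) else 0L, sum(x$counts)
  ))
  invisible(x)
}
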