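#' Posterior probabilities of harvested causal configurations
#'
#' Re-scores every configuration `b` in the set under the summary-statistic
#' likelihood and the factorized Bernoulli prior
#' `p(b) = prod_i p0^{b_i} (1-p0)^{1-b_i}`, then normalizes over the
#' supplied set (a reduced stand-in for the full 2^m configuration space):
#' `P(b | z, LD) = p(z | LD, b) p(b) / sum_{b'} p(z | LD, b') p(b')`.
#' Normalization happens in log space with a log-sum-exp guard.
#'
#' @param configs A [configuration_set()].
#' @param stats A [summary_stats()] object.
#' @param prior A [prior_config()]; `NULL` `p0` resolves to 1/m.
#' @param eff An [effect_prior()].
#' @return A tibble with one row per configuration: `config` (list-column of
#'   integer index vectors), `size`, `count`, `log_weight` (unnormalized)
#'   and `prob` (normalized; sums to 1).
#' @export
config_posterior <- function(configs, stats, prior = prior_config(),
                             eff = effect_prior()) {
  if (!inherits(configs, "configuration_set")) {
    stop_input("configs must be a configuration_set")
  }
  if (length(configs$configs) == 0) stop_input("configuration set is empty")
  if (configs$m != stats$m) {
    stop_input("configuration set is over m = %d but stats has m = %d", configs$m, stats$m)
  }
  m <- stats$m
  p0 <- resolve_p0(prior, m)
  cache <- ld_cache(stats, eff)
  lp1 <- log(p0)
  lp0 <- log1p(-p0)
  log_w <- vapply(configs$configs, function(ix) {
    b <- numeric(m)
    b[ix] <- 1
    gwas_ll_lowrank(cache, b) + length(ix) * lp1 + (m - length(ix)) * lp0
  }, numeric(1))
  lse <- logsumexp(log_w)
  tibble::tibble(
    config = configs$configs,
    size = lengths(configs$configs),
    count = configs$counts,
    log_weight = log_w,
    prob = exp(log_w - lse)
  )
}

#' Posterior inclusion probabilities from a configuration posterior
#'
#' The PIP of variant `i` is the total posterior probability of the
#' configurations in which it is causal:
#' `PIP_i = sum over configs b with b_i = 1 of P(b | z, LD)`.
#'
#' @param posterior A tibble from [config_posterior()] (columns `config`,
#'   `prob`).
#' @param m Number of variants.
#' @return Numeric vector of length `m` with values in `[0,1]`.
#' @export
compute_pips <- function(posterior, m) {
  pip <- numeric(m)
  for (j in seq_len(nrow(posterior))) {
    ix <- posterior$config[[j]]
    pip[ix] <- pip[ix] + posterior$prob[j]
  }
  pip
}

# Logical n_configs x m inclusion matrix for conditional-probability sums.
config_matrix <- function(posterior, m) {
  J <- nrow(posterior)
  inc <- matrix(FALSE, J, m)
  for (j in seq_len(J)) inc[j, posterior$config[[j]]] <- TRUE
  inc
}

#' Credible sets from a configuration posterior
#'
#' Builds level-`coverage` credible sets in two steps. Step 1 greedily
#' selects "key" variants: starting from the empty conditioning set, the
#' variant with the highest conditional probability of being causal given
#' that all previously chosen keys are causal is added, until that
#' conditional probability drops below `key_prob_min` or `max_sets` keys
#' have been found. Step 2 builds one set per key variant: all other
#' variants are ranked by their conditional inclusion probability given the
#' *other* key variants, and variants are added in decreasing order until
#' the cumulative conditional probability reaches `coverage`. If the
#' available mass cannot reach `coverage` the set contains every variant
#' with positive conditional probability and is flagged. Ties are broken by
#' larger `|z|`, then lower index.
#'
#' @param posterior A tibble from [config_posterior()].
#' @param stats The [summary_stats()] the posterior was computed from (used
#'   for `m` and tie-breaking by `|z|`).
#' @param coverage Target coverage level in (0,1); default 0.95.
#' @param max_sets Maximum number of credible sets (default 10).
#' @param key_prob_min Conditional-probability floor for admitting a new key
#'   variant (default 0.5).
#' @return A tibble with one row per credible set: `cs` (set id), `key`
#'   (key variant index), `variants` (list-column of integer indices),
#'   `size`, `attained` (cumulative conditional probability) and
#'   `below_coverage` flag. Zero rows when no variant passes the key
#'   threshold.
#' @export
credible_sets <- function(posterior, stats, coverage = 0.95, max_sets = 10L,
                          key_prob_min = 0.5) {
  if (coverage <= 0 || coverage >= 1) stop_input("coverage must lie in (0,1)")
  m <- stats$m
  inc <- config_matrix(posterior, m)
  w <- posterior$prob
  absz <- abs(stats$z)

  # P(b_i = 1 for all i in cond & b_j = 1) / P(b_i = 1 for all i in cond)
  cond_inclusion <- function(cond) {
    in_cond <- if (length(cond)) {
      rowSums(inc[, cond, drop = FALSE]) == length(cond)
    } else {
      rep(TRUE, nrow(inc))
    }
    denom <- sum(w[in_cond])
    if (denom <= 0) return(NULL)
    num <- colSums(inc[in_cond, , drop = FALSE] * w[in_cond])
    num / denom
  }

  # step 1: greedy key-variant selection
  keys <- integer(0)
  repeat {
    if (length(keys) >= max_sets) break
    q <- cond_inclusion(keys)
    if (is.null(q)) break
    cand <- setdiff(seq_len(m), keys)
    ord <- cand[order(-q[cand], -absz[cand], cand)]
    best <- ord[1]
    if (q[best] < key_prob_min) break
    keys <- c(keys, best)
  }
  if (length(keys) == 0) {
    return(tibble::tibble(
      cs = integer(0), key = integer(0), variants = list(), size = integer(0),
      attained = numeric(0), below_coverage = logical(0)
    ))
  }

  # step 2: one set per key, conditioning on the other keys
  rows <- lapply(seq_along(keys), function(j) {
    others <- keys[-j]
    q <- cond_inclusion(others)
    if (is.null(q)) q <- compute_pips(posterior, m)
    cand <- setdiff(seq_len(m), others)
    cand <- cand[q[cand] > 0]
    cand <- cand[order(-q[cand], -absz[cand], cand)]
    cum <- cumsum(q[cand])
    cut <- which(cum >= coverage)
    if (length(cut)) {
      take <- seq_len(cut[1])
      flagged <- FALSE
    } else {
      take <- seq_along(cand)
      flagged <- TRUE
    }
    vars <- sort(cand[take])
    tibble::tibble(
      key = keys[j], variants = list(vars), size = length(vars),
      attained = if (length(take)) cum[max(take)] else 0,
      below_coverage = flagged
    )
  })
  out <- dplyr::bind_rows(rows)
  out$cs <- seq_len(nrow(out))
  out[, c("cs", "key", "variants", "size", "attained", "below_coverage")]
}
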