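test_that("the probability map is deterministic and stays inside (0,1)", {
  ss <- spike_stats(m = 15, idx = 4)
  net_cfg <- inference_net_config(hidden_sizes = c(32, 32), seed = 3)
  p0 <- 1 / 15
  set.seed(3)
  net <- finemapvi:::mlp_init(15, net_cfg, p0)
  p1 <- probability_map(net, ss$z)
  p2 <- probability_map(net, ss$z)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))
  # freshly initialized network starts at the prior map
  expect_equal(p1, rep(p0, 15), tolerance = 1e-8)
  expect_error(probability_map(net, rnorm(9)), "length")
})

test_that("the variational loss decomposes into its two hand-computed terms", {
  set.seed(41)
  m <- 8
  ld <- random_corr(m)
  ss <- summary_stats(rnorm(m), ld, 4000)
  p <- runif(m, 0.05, 0.6)
  lam <- 0.2
  L <- 6
  U <- matrix(runif(L * m, 0.01, 0.99), L, m)
  p0 <- 0.1
  eff <- effect_prior()

  got <- vi_loss(ss, p, lam, prior_config(p0 = p0), eff, U)

  lls <- vapply(seq_len(L), function(l) {
    cl <- bc_sample(p, lam, u = U[l, ])
    cl[cl <= 0.01] <- 0
    oracle_mvn_loglik(ss, cl)
  }, numeric(1))
  kl <- sum(p * log(p / p0) + (1 - p) * log((1 - p) / (1 - p0)))
  expect_equal(got, -mean(lls) + kl, tolerance = 1e-9)

  # at p = p0 the KL term vanishes exactly
  pu <- rep(p0, m)
  expect_equal(vi_loss(ss, pu, lam, prior_config(p0 = p0), eff, U),
               -mean(vapply(seq_len(L), function(l) {
                 cl <- bc_sample(pu, lam, u = U[l, ])
                 cl[cl <= 0.01] <- 0
                 oracle_mvn_loglik(ss, cl)
               }, numeric(1))), tolerance = 1e-9)
})

test_that("under null data the loss over constant maps is minimized near the prior", {
  set.seed(47)
  m <- 20
  ss <- summary_stats(rep(0, m), diag(m), 5000)
  p0 <- 1 / m
  L <- 200
  U <- matrix(runif(L * m, 1e-4, 1 - 1e-4), L, m)
  grid <- c(0.005, 0.01, 0.02, 0.05, 0.1, 0.2, 0.35, 0.5)
  losses <- vapply(grid, function(pc) {
    vi_loss(ss, rep(pc, m), lam = 0.05, prior_config(p0 = p0), effect_prior(), U)
  }, numeric(1))
  expect_lte(abs(grid[which.min(losses)] - p0), 0.05)
  # and far-from-prior maps are clearly worse
  expect_gt(losses[grid == 0.5], min(losses))
})

test_that("binarization thresholds strictly", {
  expect_equal(binarize(c(0.05, 0.5, 0.95), 0.1), c(0L, 1L, 1L))
  expect_equal(binarize(0.1, 0.1), 0L)
  expect_equal(binarize(rep(0, 4), 0.3), rep(0L, 4))
  expect_error(binarize(0.5, 0), "0,1")
})

test_that("fitting a strong single-signal locus recovers the causal variant", {
  ss <- spike_stats(m = 20, idx = 7, z_val = 6)
  tr <- train_config(iters = 600, seed = 1)
  fit <- fit_finemap_vi(ss, tr = tr)
  post <- config_posterior(fit$configs, ss)
  pip <- compute_pips(post, ss$m)
  expect_equal(which.max(pip), 7)
  # exhaustive oracle agrees on the top variant
  oracle <- oracle_posterior(ss, enumerate_configs(20, 2), p0 = 1 / 20)
  expect_equal(which.max(oracle$pip), 7)
  expect_equal(length(fit$loss_trace), 600)
})

test_that("the loss trace trends downward on a strong-signal locus", {
  ss <- spike_stats(m = 20, idx = 7, z_val = 6)
  for (seed in 1:2) {
    fit <- fit_finemap_vi(ss, tr = train_config(seed = seed))
    tr10 <- ceiling(0.1 * length(fit$loss_trace))
    expect_lt(mean(utils::tail(fit$loss_trace, tr10)),
              mean(utils::head(fit$loss_trace, tr10)))
  }
})

test_that("identical seeds reproduce the fit bit for bit", {
  ss <- spike_stats(m = 12, idx = 5, z_val = 5)
  f1 <- fit_finemap_vi(ss, tr = train_config(iters = 150, seed = 8))
  f2 <- fit_finemap_vi(ss, tr = train_config(iters = 150, seed = 8))
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_identical(f1$p_map, f2$p_map)
  expect_identical(f1$configs$configs, f2$configs$configs)
})

test_that("harvested-configuration PIPs track the exhaustive posterior when the signal is strong", {
  set.seed(55)
  study <- simulate_study(sim_config(
    n = 2000, m = 10, d = 1, omega2 = 0.5, causal_var_share = 1,
    ld_block_size = 5, ld_rho = 0.5, seed = 42
  ))
  ss <- study$stats
  expect_gte(max(abs(ss$z)), 6)
  fit <- finemap(ss, tr = train_config(iters = 1000, seed = 4))
  oracle <- oracle_posterior(ss, enumerate_configs(10), p0 = 0.1)
  expect_lt(max(abs(fit$pip - oracle$pip)), 0.05)
})

test_that("every harvested configuration respects the support cap", {
  ss <- spike_stats(m = 30, idx = 11, z_val = 5)
  tr <- train_config(iters = 200, seed = 2, support_cap = 5L)
  fit <- fit_finemap_vi(ss, tr = tr)
  expect_true(all(lengths(fit$configs$configs) <= 5))
})

test_that("raising the prior inclusion probability raises null-data PIPs", {
  ss <- summary_stats(rep(0, 15), diag(15), 5000)
  tr <- train_config(iters = 300, seed = 6)
  fit_lo <- finemap(ss, prior = prior_config(p0 = 1 / 15), tr = tr)
  fit_hi <- finemap(ss, prior = prior_config(p0 = 0.5), tr = tr)
  expect_gte(mean(fit_hi$pip), mean(fit_lo$pip))
})
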