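test_that("configuration posteriors normalize and respect symmetry", {
  ss <- summary_stats(c(2, 2), diag(2), 1000)

  single <- configuration_set(list(1L), m = 2)
  post <- config_posterior(single, ss)
  expect_equal(post$prob, 1, tolerance = 1e-14)

  # two configs with equal likelihood and equal support size split evenly
  pair <- configuration_set(list(1L, 2L), m = 2)
  post2 <- config_posterior(pair, ss)
  expect_equal(post2$prob, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(sum(post2$prob), 1, tolerance = 1e-12)

  expect_error(config_posterior(configuration_set(list(), m = 2), ss), "empty")
})

test_that("posterior over all configurations matches brute-force enumeration", {
  set.seed(61)
  m <- 3
  ld <- random_corr(m)
  ss <- summary_stats(rnorm(m, sd = 2), ld, 2000)
  cfgs <- enumerate_configs(m)
  cs <- configuration_set(cfgs, m = m)
  post <- config_posterior(cs, ss, prior_config(p0 = 1 / m))
  oracle <- oracle_posterior(ss, cfgs, p0 = 1 / m)
  expect_equal(post$prob, oracle$prob, tolerance = 1e-12)
  expect_equal(compute_pips(post, m), oracle$pip, tolerance = 1e-12)
})

test_that("PIPs are the correct per-variant sums over the posterior", {
  post <- tibble::tibble(config = list(1L, c(1L, 2L)), prob = c(0.6, 0.4))
  expect_equal(compute_pips(post, 3), c(1.0, 0.4, 0))

  post1 <- tibble::tibble(config = list(1L), prob = 1)
  expect_equal(compute_pips(post1, 3), c(1, 0, 0))

  # random posterior on m = 8 against independent summation
  set.seed(67)
  cfgs <- replicate(20, sort(sample.int(8, sample(0:3, 1))), simplify = FALSE)
  cfgs <- cfgs[!duplicated(vapply(cfgs, paste, "", collapse = ","))]
  w <- runif(length(cfgs))
  w <- w / sum(w)
  post <- tibble::tibble(config = cfgs, prob = w)
  manual <- vapply(1:8, function(i) {
    sum(w[vapply(cfgs, function(ix) i %in% ix, logical(1))])
  }, numeric(1))
  expect_equal(compute_pips(post, 8), manual, tolerance = 1e-14)
})

test_that("exhaustive-set PIPs are exact at moderate locus size", {
  set.seed(71)
  m <- 12
  ld <- random_corr(m)
  ss <- summary_stats(rnorm(m, sd = 2), ld, 3000)
  cfgs <- enumerate_configs(m, smax = 3)
  post <- config_posterior(configuration_set(cfgs, m = m), ss,
                           prior_config(p0 = 1 / m))
  oracle <- oracle_posterior(ss, cfgs, p0 = 1 / m)
  expect_lt(max(abs(compute_pips(post, m) - oracle$pip)), 1e-12)
})

test_that("credible sets behave on concentrated, split, and two-signal posteriors", {
  ss6 <- summary_stats(c(6, 0, 0, 6, 0, 0), diag(6), 5000)

  # posterior concentrated on a single one-causal config -> one singleton
  post <- tibble::tibble(config = list(1L), prob = 1)
  sets <- credible_sets(post, ss6, coverage = 0.95)
  expect_equal(nrow(sets), 1)
  expect_equal(sets$variants[[1]], 1L)
  expect_gte(sets$attained[1], 0.95)

  # dominant two-causal config on uncorrelated signals -> two singletons
  post2 <- tibble::tibble(
    config = list(c(1L, 4L), 1L, 4L, integer(0)),
    prob = c(0.991, 0.004, 0.004, 0.001)
  )
  sets2 <- credible_sets(post2, ss6, coverage = 0.95)
  expect_equal(nrow(sets2), 2)
  expect_true(all(sets2$size == 1))
  expect_setequal(unlist(sets2$variants), c(1L, 4L))

  # perfectly correlated pair splitting mass 0.5/0.5 -> one set with both
  ld <- diag(2)
  ld[1, 2] <- ld[2, 1] <- 1 - 1e-7
  ss2 <- summary_stats(c(5, 5), ld, 5000)
  post3 <- tibble::tibble(config = list(1L, 2L), prob = c(0.5, 0.5))
  sets3 <- credible_sets(post3, ss2, coverage = 0.95)
  expect_equal(nrow(sets3), 1)
  expect_setequal(sets3$variants[[1]], c(1L, 2L))
  expect_gte(sets3$attained[1], 0.95)

  expect_error(credible_sets(post, ss6, coverage = 1.2), "coverage")
})

test_that("credible sets reach the requested mass or are flagged, and respect max_sets", {
  ss <- summary_stats(c(4, 4, 4, 0), diag(4), 5000)
  # mass spread so no subset conditioned on key 1 reaches 0.99:
  # null config holds 20% of the mass
  post <- tibble::tibble(
    config = list(1L, 2L, integer(0)),
    prob = c(0.5, 0.3, 0.2)
  )
  sets <- credible_sets(post, ss, coverage = 0.95)
  if (nrow(sets)) {
    expect_true(all(sets$attained >= 0.95 | sets$below_coverage))
  }
  # max_sets bounds the number of keys
  post2 <- tibble::tibble(
    config = list(c(1L, 2L, 3L)),
    prob = 1
  )
  sets2 <- credible_sets(post2, ss, coverage = 0.9, max_sets = 2L)
  expect_lte(nrow(sets2), 2)
})

test_that("posterior weights ignore harvest multiplicities", {
  ss <- summary_stats(c(3, 1), diag(2), 1000)
  a <- config_posterior(configuration_set(list(1L, 2L), counts = c(1L, 1L), m = 2), ss)
  b <- config_posterior(configuration_set(list(1L, 2L), counts = c(50L, 1L), m = 2), ss)
  expect_equal(a$prob, b$prob, tolerance = 1e-15)
  expect_error(configuration_set(list(1L, 1L), m = 2), "duplicate")
})
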