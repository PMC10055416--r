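test_that("genotype simulation honors MAF bounds, standardization and the seed", {
  cfg <- sim_config(n = 800, m = 60, d = 2, seed = 10)
  set.seed(cfg$seed)
  g <- simulate_genotypes(cfg)
  expect_true(all(g$maf >= cfg$maf_min & g$maf <= 0.5))
  expect_true(all(g$raw %in% 0:2))
  # columns standardized: mean 0, population variance 1
  expect_lt(max(abs(colMeans(g$std))), 1e-8)
  expect_lt(max(abs(colSums(g$std^2) / cfg$n - 1)), 1e-8)
  # bit-for-bit reproducibility
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$raw, s2$raw)
  expect_identical(s1$stats$z, s2$stats$z)
  expect_identical(s1$causal_indices, s2$causal_indices)
})

test_that("ld_rho = 0 gives near-independent variants", {
  cfg <- sim_config(n = 5000, m = 40, d = 1, ld_rho = 0, seed = 12)
  study <- simulate_study(cfg)
  ld <- study$stats$ld
  off <- abs(ld[upper.tri(ld)])
  expect_lt(mean(off), 0.05)
})

test_that("adjacent-variant LD matches the latent threshold model", {
  cfg <- sim_config(n = 5000, m = 20, d = 1, ld_block_size = 10, ld_rho = 0.9, seed = 14)
  set.seed(cfg$seed)
  g <- simulate_genotypes(cfg)
  emp_ld <- crossprod(g$std) / cfg$n
  # Monte Carlo oracle: correlation of two thresholded latent AR(1) neighbors
  # (genotype = sum of two independent haplotypes) at 1e6 draws
  rho <- cfg$ld_rho
  thr <- qnorm(1 - g$maf)
  set.seed(999)
  for (j in c(1, 5, 11)) {
    l1 <- rnorm(1e6)
    l2 <- rho * l1 + sqrt(1 - rho^2) * rnorm(1e6)
    k1 <- rnorm(1e6)
    k2 <- rho * k1 + sqrt(1 - rho^2) * rnorm(1e6)
    ga <- (l1 > thr[j]) + (k1 > thr[j])
    gb <- (l2 > thr[j + 1]) + (k2 > thr[j + 1])
    expect_lt(abs(emp_ld[j, j + 1] - cor(ga, gb)), 0.1)
  }
})

test_that("the phenotype variance partition is exact by construction", {
  for (omega2 in c(0.2, 0.6)) {
    for (share in c(0.3, 0.9)) {
      cfg <- sim_config(n = 5000, m = 200, d = 1, omega2 = omega2,
                        causal_var_share = share, ld_rho = 0.3, seed = 20)
      set.seed(cfg$seed)
      g <- simulate_genotypes(cfg)
      ph <- simulate_phenotype(g$std, 57L, cfg)
      expect_equal(var(ph$components[, "causal"]), share * omega2, tolerance = 1e-12)
      expect_equal(var(ph$components[, "polygenic"]), (1 - share) * omega2,
                   tolerance = 1e-12)
      expect_equal(var(ph$components[, "noise"]), 1 - omega2, tolerance = 1e-12)
      expect_equal(var(ph$y), 1, tolerance = 0.05)
    }
  }
  # share = 1: the polygenic component is exactly zero
  cfg1 <- sim_config(n = 500, m = 30, d = 2, omega2 = 0.5, causal_var_share = 1, seed = 21)
  set.seed(cfg1$seed)
  g <- simulate_genotypes(cfg1)
  ph <- simulate_phenotype(g$std, c(3L, 17L), cfg1)
  expect_true(all(ph$components[, "polygenic"] == 0))
})

test_that("summary statistics match textbook per-variant OLS", {
  # hand-specified 5-subject toy, lm() as the oracle
  raw <- cbind(c(0, 1, 2, 1, 0), c(2, 2, 1, 0, 0), c(0, 0, 1, 1, 2))
  y <- c(0.3, 1.2, 2.5, 1.1, -0.4)
  ss <- compute_summary_stats(raw, y)
  for (j in 1:3) {
    fit <- lm(y ~ raw[, j])
    z_oracle <- summary(fit)$coefficients[2, "t value"]
    expect_equal(ss$z[j], z_oracle, tolerance = 1e-10)
  }
  expect_equal(diag(ss$ld), rep(1, 3))
  expect_error(compute_summary_stats(cbind(raw, 1), y), "zero-variance")
})

test_that("null phenotypes give centered z-scores", {
  set.seed(31)
  cfg <- sim_config(n = 400, m = 1000, d = 1, ld_rho = 0.2, seed = 31)
  set.seed(cfg$seed)
  g <- simulate_genotypes(cfg)
  y <- rnorm(cfg$n) # independent of genotype
  ss <- compute_summary_stats(g$raw, y)
  expect_lt(abs(mean(ss$z)), 0.1)
})

test_that("z-scores increase with the genotype-phenotype correlation", {
  study <- simulate_study(sim_config(n = 600, m = 40, d = 2, seed = 33))
  r <- drop(cor(study$raw, study$phenotype))
  expect_equal(order(study$stats$z), order(r))
})

test_that("fine-mapping a simulated strong single-causal locus finds the variant", {
  study <- simulate_study(sim_config(
    n = 5000, m = 100, d = 1, omega2 = 0.6, causal_var_share = 0.9,
    ld_rho = 0.3, seed = 3
  ))
  fit <- finemap(study$stats, tr = train_config(iters = 800, seed = 3))
  expect_equal(which.max(fit$pip), study$causal_indices)
})

test_that("PLINK-style export carries the dosages and phenotype", {
  study <- simulate_study(sim_config(n = 30, m = 8, d = 1, seed = 44))
  f <- withr::local_tempfile(fileext = ".raw")
  write_plink_raw(study, f)
  tab <- read.table(f, header = TRUE)
  expect_equal(nrow(tab), 30)
  expect_equal(as.matrix(tab[, -(1:6)]), study$raw,
               ignore_attr = TRUE)
  expect_equal(tab$PHENOTYPE, study$phenotype, tolerance = 1e-9)
})
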