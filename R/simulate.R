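#' Simulation configuration
#'
#' Parameters of the self-contained study generator: block-correlated
#' genotypes for `n` individuals by `m` variants, a mixed-model phenotype
#' with `d` causal fixed effects and a polygenic random effect from the
#' non-causal variants, and the variance partition (`omega2`, the total
#' genotype-explained variance; `causal_var_share`, the proportion of it
#' carried by the causal variants).
#'
#' @param n Number of individuals.
#' @param m Number of variants.
#' @param d Number of causal variants (1 <= d < m).
#' @param omega2 Total genotype-explained phenotypic variance, in (0,1).
#' @param causal_var_share Proportion of the genetic variance attributable
#'   to the causal variants, in (0,1].
#' @param ld_block_size Variants per LD block.
#' @param ld_rho First-order autocorrelation of the latent haplotype field
#'   within a block, in `[0,1)`; adjacent-variant LD decays roughly as
#'   `ld_rho^distance`.
#' @param maf_min Minimum minor-allele frequency (default 0.02); target MAFs
#'   are drawn uniformly on `[maf_min, 0.5]`.
#' @param seed Integer seed; the whole study is reproducible from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n = 5000L, m = 1000L, d = 1L, omega2 = 0.5,
                       causal_var_share = 0.5, ld_block_size = 20L,
                       ld_rho = 0.9, maf_min = 0.02, seed = 1L) {
  if (!(d >= 1 && d < m)) stop_input("need 1 <= d < m")
  if (!(omega2 > 0 && omega2 < 1)) stop_input("omega2 must lie in (0,1)")
  if (!(causal_var_share > 0 && causal_var_share <= 1)) {
    stop_input("causal_var_share must lie in (0,1]")
  }
  if (!(ld_rho >= 0 && ld_rho < 1)) stop_input("ld_rho must lie in [0,1)")
  if (!(maf_min > 0 && maf_min < 0.5)) stop_input("maf_min must lie in (0,0.5)")
  structure(
    list(n = as.integer(n), m = as.integer(m), d = as.integer(d),
         omega2 = omega2, causal_var_share = causal_var_share,
         ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
         maf_min = maf_min, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# latent AR(1) field for one block: rows are haplotypes, columns variants
ar1_block <- function(n_hap, width, rho) {
  L <- matrix(0, n_hap, width)
  L[, 1] <- rnorm(n_hap)
  if (width > 1) {
    sc <- sqrt(1 - rho^2)
    for (j in 2:width) L[, j] <- rho * L[, j - 1] + sc * rnorm(n_hap)
  }
  L
}

#' Simulate block-correlated genotypes
#'
#' Draws two haplotypes per individual from a latent-threshold model: within
#' each block of `ld_block_size` variants the latent field is Gaussian AR(1)
#' with parameter `ld_rho`, and a haplotype carries the minor allele at
#' variant `j` when its latent value exceeds the per-variant threshold
#' chosen so the allele frequency equals the target MAF (uniform on
#' `[maf_min, 0.5]`). Genotypes are the sum of the two haplotypes; columns
#' are then standardized to mean 0 and mean-square 1 (so the empirical LD
#' matrix has unit diagonal).
#'
#' @param cfg A [sim_config()]. The caller is expected to have seeded the
#'   RNG ([simulate_study()] does); call with `set.seed()` first for a
#'   standalone reproducible draw.
#' @return A list with `raw` (n x m integer dosages in 0..2), `std`
#'   (standardized dosage matrix), `maf` (target minor-allele frequencies)
#'   and `blocks` (block id per variant).
#' @export
simulate_genotypes <- function(cfg) {
  n <- cfg$n; m <- cfg$m
  maf <- runif(m, cfg$maf_min, 0.5)
  thresh <- qnorm(1 - maf)
  blocks <- rep(seq_len(ceiling(m / cfg$ld_block_size)), each = cfg$ld_block_size)[seq_len(m)]
  raw <- matrix(0L, n, m)
  for (b in unique(blocks)) {
    cols <- which(blocks == b)
    width <- length(cols)
    h1 <- ar1_block(n, width, cfg$ld_rho)
    h2 <- ar1_block(n, width, cfg$ld_rho)
    g <- (sweep(h1, 2, thresh[cols], ">") + sweep(h2, 2, thresh[cols], ">"))
    raw[, cols] <- g
  }
  # monomorphic columns (possible at small n) are redrawn independently so
  # every column can be standardized
  mono <- which(apply(raw, 2, function(x) min(x) == max(x)))
  tries <- 0
  while (length(mono) && tries < 100) {
    for (j in mono) {
      raw[, j] <- (rnorm(n) > thresh[j]) + (rnorm(n) > thresh[j])
    }
    mono <- which(apply(raw, 2, function(x) min(x) == max(x)))
    tries <- tries + 1
  }
  if (length(mono)) {
    stop_numeric("could not produce polymorphic genotypes (column %d); use a larger n", mono[1])
  }
  std <- standardize_genotypes(raw)
  list(raw = raw, std = std, maf = maf, blocks = blocks)
}

# center and scale each column to mean 0, mean square 1 (population scaling,
# so t(X) %*% X / n has an exactly unit diagonal)
standardize_genotypes <- function(raw) {
  n <- nrow(raw)
  mu <- colMeans(raw)
  Xc <- sweep(raw, 2, mu)
  s <- sqrt(colSums(Xc^2) / n)
  zero <- which(s == 0)
  if (length(zero)) stop_input("zero-variance genotype column %d", zero[1])
  sweep(Xc, 2, s, "/")
}

#' Simulate a mixed-model phenotype
#'
#' Generates `y = g_C + g_NC + noise` where `g_C = X_C beta` with
#' `beta ~ N(0, I_d)` is the causal fixed effect, `g_NC` is a polygenic
#' random effect with covariance `X_NC X_NC' / (m - d)`, and the three
#' components are rescaled by their empirical variances so that they carry
#' exactly `causal_var_share * omega2`, `(1 - causal_var_share) * omega2`
#' and `1 - omega2` of the phenotypic variance. The variance partition is
#' therefore exact by construction and `var(y)` is 1 up to the (small)
#' empirical covariances between components.
#'
#' @param std Standardized genotype matrix (from [simulate_genotypes()]).
#' @param causal_indices Integer vector of `d` causal column indices.
#' @param cfg A [sim_config()].
#' @return A list with `y` (length-n phenotype), `true_beta` (rescaled
#'   causal effects on the standardized scale) and `components` (n x 3
#'   matrix of the scaled causal, polygenic and noise parts).
#' @export
simulate_phenotype <- function(std, causal_indices, cfg) {
  n <- nrow(std); m <- ncol(std); d <- length(causal_indices)
  if (d != cfg$d) stop_input("expected %d causal indices, got %d", cfg$d, d)
  if (any(causal_indices < 1 | causal_indices > m)) stop_input("causal index out of range")
  beta <- rnorm(d)
  g_c <- drop(std[, causal_indices, drop = FALSE] %*% beta)
  v_c <- var(g_c)
  if (v_c <= 0) {
    stop_numeric("degenerate causal component (var(g_C) = 0); re-run with a new seed")
  }
  share <- cfg$causal_var_share
  sc_c <- sqrt(share * cfg$omega2 / v_c)
  g_c <- g_c * sc_c

  if (share < 1) {
    nc <- setdiff(seq_len(m), causal_indices)
    u <- rnorm(length(nc))
    g_nc <- drop(std[, nc, drop = FALSE] %*% u) / sqrt(m - d)
    v_nc <- var(g_nc)
    if (v_nc <= 0) stop_numeric("degenerate polygenic component; re-run with a new seed")
    g_nc <- g_nc * sqrt((1 - share) * cfg$omega2 / v_nc)
  } else {
    g_nc <- numeric(n)
  }

  eps <- rnorm(n)
  eps <- eps * sqrt((1 - cfg$omega2) / var(eps))

  list(
    y = g_c + g_nc + eps,
    true_beta = beta * sc_c,
    components = cbind(causal = g_c, polygenic = g_nc, noise = eps)
  )
}

#' Per-variant GWAS summary statistics from genotypes and phenotype
#'
#' Runs the univariate GWAS that real studies report: a simple ordinary
#' least squares fit (with intercept) of the phenotype on each raw genotype
#' column gives the effect estimate and its standard error, and
#' `z_i = beta_hat_i / se(beta_hat_i)`. For numerical stability `|z|` is
#' clipped at 200. The LD matrix is `X'X / n` on the standardized genotypes.
#'
#' @param raw n x m raw dosage matrix.
#' @param y Length-n phenotype vector.
#' @param variant_ids Optional identifiers (default `v1..vm`).
#' @return A [summary_stats()] object.
#' @export
compute_summary_stats <- function(raw, y, variant_ids = NULL) {
  n <- nrow(raw); m <- ncol(raw)
  if (length(y) != n) stop_input("length(y) = %d but genotypes have %d rows", length(y), n)
  xm <- colMeans(raw)
  Xc <- sweep(raw, 2, xm)
  sxx <- colSums(Xc^2)
  zero <- which(sxx == 0)
  if (length(zero)) stop_input("zero-variance genotype column %d", zero[1])
  yc <- y - mean(y)
  sxy <- drop(crossprod(Xc, yc))
  syy <- sum(yc^2)
  bhat <- sxy / sxx
  s2 <- pmax(syy - bhat * sxy, 0) / (n - 2)
  se <- sqrt(s2 / sxx)
  z <- ifelse(se > 0, bhat / se, Inf)
  z <- clamp(z, -200, 200)
  std <- sweep(Xc, 2, sqrt(sxx / n), "/")
  ld <- crossprod(std) / n
  summary_stats(z, ld, n, variant_ids = variant_ids)
}

#' Simulate a complete GWAS study
#'
#' End-to-end generator: genotypes, causal-variant placement (uniform at
#' random), phenotype, and summary statistics, all reproducible from
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `simulated_study`: a list with `raw`, `std`,
#'   `maf`, `blocks`, `phenotype`, `causal_indices`, `true_beta`,
#'   `components` and `stats` (a [summary_stats()] ready for [finemap()]).
#' @examples
#' study <- simulate_study(sim_config(n = 400, m = 20, d = 1, seed = 7))
#' study$causal_indices
#' @export
simulate_study <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  geno <- simulate_genotypes(cfg)
  causal <- sort(sample.int(cfg$m, cfg$d))
  ph <- simulate_phenotype(geno$std, causal, cfg)
  ids <- sprintf("v%04d", seq_len(cfg$m))
  stats <- compute_summary_stats(geno$raw, ph$y, variant_ids = ids)
  structure(
    list(
      raw = geno$raw, std = geno$std, maf = geno$maf, blocks = geno$blocks,
      phenotype = ph$y, causal_indices = causal, true_beta = ph$true_beta,
      components = ph$components, stats = stats, config = cfg
    ),
    class = "simulated_study"
  )
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(
    "<simulated_study> n = %d, m = %d, causal at {%s}, omega2 = %.2f, share = %.2f\n",
    x$config$n, x$config$m, paste(x$causal_indices, collapse = ", "),
    x$config$omega2, x$config$causal_var_share
  ))
  invisible(x)
}

#' Export a simulated study in PLINK-style .raw text
#'
#' Writes the raw dosages in the additive-coding text layout produced by
#' `plink --recode A` (`FID IID PAT MAT SEX PHENOTYPE` then one dosage
#' column per variant), with the simulated phenotype in the `PHENOTYPE`
#' column, so external fine-mapping tools can be run on identical
#' instances.
#'
#' @param study A [simulate_study()] result.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_plink_raw <- function(study, path) {
  ids <- study$stats$variant_ids
  header <- paste(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE",
                    paste0(ids, "_A")), collapse = " ")
  n <- nrow(study$raw)
  body <- vapply(seq_len(n), function(i) {
    paste(c(sprintf("F%04d", i), sprintf("I%04d", i), "0", "0", "0",
            sprintf("%.10g", study$phenotype[i]), study$raw[i, ]),
          collapse = " ")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
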