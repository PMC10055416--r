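---
title: "Variational fine-mapping from GWAS summary statistics: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variational fine-mapping from GWAS summary statistics: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finemapvi)
```

## The fine-mapping problem

A GWAS reports, for each of $m$ variants in a locus, a z-score
$z_i = \hat\beta_i / \mathrm{se}(\hat\beta_i)$ from a univariate regression
of the trait on that variant. Because nearby variants are correlated
(linkage disequilibrium, LD), a non-causal variant in strong LD with a
causal one can carry a z-score as large as — or larger than — the causal
variant itself. Fine-mapping asks: given the vector $z$, the LD matrix
$\Sigma_X = \tfrac1n X^\top X$ (computed on column-standardized genotypes
$X$), and the sample size $n$, which variants are actually causal? The
answer is posterior: a per-variant posterior inclusion probability (PIP)
and credible sets — groups of variants that contain a causal variant with
stated probability.

## Generative model

Let $c \in [0,1]^m$ encode causal status (1 causal, 0 not, intermediate
values for small residual effects). Under a standardized additive trait
model with a Gaussian effect-size prior of scale $\sigma^2$ on causal
variants, the z-scores are marginally multivariate normal:

$$
z \mid \Sigma_X, c \;\sim\; \mathcal N\!\big(0,\;
\Sigma_X + \Sigma_X (n\sigma^2 \operatorname{diag}(c))\, \Sigma_X\big).
$$

`gwas_log_likelihood()` evaluates this density. Two paths are available
and agree to machine precision: a dense $O(m^3)$ factorization, and a
low-rank path that exploits the sparsity of $c$. Writing
$M = \Sigma_X + \delta I$ (the ridge-stabilized LD matrix) and
$s = \{i : c_i > 0\}$ with $D = n\sigma^2\operatorname{diag}(c_s)$, the
covariance is $M + M_{\cdot s} D M_{s\cdot}$, and because the low-rank
factor consists of columns of $M$ itself, the Woodbury and
matrix-determinant identities collapse to

$$
z^\top \Sigma^{-1} z = z^\top M^{-1} z - z_s^\top (D^{-1}+M_{ss})^{-1} z_s,
\qquad
\log\det\Sigma = \log\det M + \log\det(I + D^{1/2} M_{ss} D^{1/2}),
$$

so that after a one-time Cholesky factorization of $M$ each evaluation
costs $O(k^3)$ in the support size $k$. The same reduction yields the
analytic gradient
$\partial \ell/\partial c_i
 = \tfrac12 n\sigma^2\big[(M\Sigma^{-1}z)_i^2 - (M\Sigma^{-1}M)_{ii}\big]$
used during training.

## The binary concrete proposal

The posterior over causal configurations is approximated by an
element-wise binary concrete (relaxed Bernoulli) distribution
$q(c; p, \lambda)$ with probability map $p \in (0,1)^m$ and temperature
$\lambda$. Draws use the reparameterization

$$
c_i = \operatorname{sigmoid}\!\Big(\tfrac{1}{\lambda}\big[
  \operatorname{logit}(u_i) + \operatorname{logit}(p_i)\big]\Big),
\qquad u_i \sim \mathrm{Uniform}(0,1),
$$

which is differentiable in $p$ and satisfies $P(c_i > \tfrac12) = p_i$ at
every temperature. As $\lambda \to 0$ the distribution approaches a
Bernoulli($p_i$); in that regime the KL divergence between proposal and a
binary concrete prior with scalar inclusion probability $p_0$ is well
approximated by the closed-form Bernoulli KL

$$
\mathrm{KL} \approx \sum_i p_i \log\frac{p_i}{p_0}
  + (1-p_i)\log\frac{1-p_i}{1-p_0},
$$

which acts as the sparsity regularizer. The prior defaults are the
uniform map $p_0 = 1/m$ and prior temperature $\lambda_0 = 0.01$.

## Variational objective and optimization

The probability map is produced by a small inference network,
$p = \mathcal F(z;\phi)$: a fully connected network with two hidden layers
of 256 units (ReLU), and a sigmoid output clamped to
$[10^{-6}, 1-10^{-6}]$, trained per locus from random initialization. The
loss is the Monte Carlo negated evidence lower bound

$$
\mathcal L(\phi) = -\frac1L \sum_{l=1}^{L}
 \log \mathcal N\!\big(z; 0, \Sigma_X + \Sigma_X(n\sigma^2
 \operatorname{diag}(c_l))\Sigma_X\big) + \mathrm{KL}(p(\phi)\,\|\,p_0),
$$

with $L$ relaxed samples $c_l$ drawn by the reparameterization above.
Each sample is support-pruned before the likelihood is evaluated: entries
at or below `support_threshold` (0.01) are zeroed, and at most
`support_cap` (50) entries are kept — the largest values win, with ties
broken by lowest index. Pruned entries carry no gradient. One Adam step
(`step_size` $10^{-3}$) is taken per iteration, for `iters` = 2000
iterations with `mc_samples` $L = 10$.

The temperature is annealed geometrically from $\lambda = 0.5$ to $0.01$
across the run — per iteration, which with a fixed iteration count is the
same fixed-rate decay as per-epoch annealing, just smoother. The final
value keeps the proposal in the Bernoulli-like regime where the KL
approximation is accurate; the high starting value makes early gradients
low-variance so the network can find the signal before sharpening.

### Numerical and initialization choices

* The LD matrix receives a diagonal ridge $\delta = 10^{-4}$ before any
  factorization, identically in every operation. Empirical LD matrices
  from finite samples or reference panels are routinely rank-deficient;
  the ridge guarantees positive definiteness without visibly distorting
  correlations. A non-positive-definite matrix after stabilization is
  reported as an error naming the smallest eigenvalue.
* The output layer of the inference network starts with zero weights and
  bias $\operatorname{logit}(p_0)$, so the initial probability map equals
  the prior exactly for any input. Hidden layers use Glorot-uniform
  initialization. This removes dependence of the early harvest on the
  random initial map.
* Probability maps are clamped to $[10^{-6}, 1-10^{-6}]$ before any
  logit; configuration weights are normalized through a log-sum-exp
  guard; the binary concrete log-density evaluates its denominator in log
  space.
* At very low temperature the reparameterization gradient is heavy-tailed
  (rare, very large kicks). The configuration harvest (below) makes the
  final summaries robust to this: PIPs come from likelihood re-weighting
  of all configurations collected along the run, not from the final map
  alone.
* Input z-scores are clipped at $|z| \le 200$ when read from disk,
  mirroring how infinite values in published GWAS releases are handled.

## From samples to PIPs and credible sets

At every iteration each pruned sample $c_l$ is binarized at
$\gamma = 0.1$ ($b_i = 1$ iff $c_{l,i} > \gamma$, strictly) and added to a
deduplicated configuration set $\mathcal B_R$. Because the samples
concentrate near modes of the posterior as the fit proceeds,
$\mathcal B_R$ is a tractable stand-in for the $2^m$ configuration space.
Each harvested configuration $b$ is then re-scored:

$$
P(b \mid z, \Sigma_X) = \frac{p(z \mid \Sigma_X, b)\, p(b)}
{\sum_{b' \in \mathcal B_R} p(z \mid \Sigma_X, b')\, p(b')},
\qquad
p(b) = \prod_i p_0^{b_i}(1-p_0)^{1-b_i},
$$

and $\mathrm{PIP}_i = \sum_{b : b_i = 1} P(b \mid z, \Sigma_X)$. Harvest
multiplicities are recorded as diagnostics but carry no posterior weight.
On loci small enough to enumerate, PIPs computed this way over the
exhaustive configuration set match brute-force enumeration to $10^{-12}$,
and the harvested set reproduces exhaustive PIPs within 0.05 when the
signal is strong (the test suite checks both).

Credible sets are built in two steps from the configuration posterior:

1. **Key variants.** Starting from an empty conditioning set, repeatedly
   add the variant with the highest conditional probability of being
   causal given that all previously selected keys are causal. Stop when
   that probability falls below 0.5 or when `max_sets` (10) keys exist.
2. **Sets.** For each key, rank all variants (other keys excluded) by
   their conditional inclusion probability given the *other* keys, and
   add variants in decreasing order until the cumulative conditional
   probability reaches the `coverage` level (0.95). If the available mass
   cannot reach it, the set holds every variant with positive conditional
   probability and is flagged `below_coverage`.

Ties anywhere are broken by larger $|z|$, then lower index. The stopping
rule (0.5) and the exclusion of conditioning keys from their own ranking
are this package's design choices for a procedure whose published
description is qualitative; both are configurable, and the procedure
reduces to the intuitive answers in the canonical cases (one strong
signal gives one singleton set; a perfectly correlated pair splitting the
posterior gives one two-variant set; two independent signals give two
singleton sets). No LD "purity" filter is applied to the sets, unlike
some sum-of-single-effects implementations.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `sigma2` | 0.005 | per-causal effect-variance scale; $n\sigma^2 = 25$ at $n = 5000$, the standardized-effect prior scale conventional in summary-statistic fine-mapping |
| `ridge` | $10^{-4}$ | diagonal LD stabilizer |
| `p0` | $1/m$ | prior inclusion probability (uniform) |
| `lam0` | 0.01 | prior temperature |
| `lam_init`, `lam_final` | 0.5, 0.01 | geometric annealing endpoints |
| `iters`, `mc_samples` | 2000, 10 | optimization length and Monte Carlo width |
| `step_size` | $10^{-3}$ | Adam learning rate |
| `support_threshold`, `support_cap` | 0.01, 50 | per-sample pruning |
| `binarize_gamma` | 0.1 | harvest binarization threshold; acts as a lower bound on the relative effect variance $\gamma\sigma^2$ a variant must reach to enter a configuration |
| `coverage` | 0.95 | credible-set level |

Raising `binarize_gamma` shrinks the harvested set (fewer, higher-mass
configurations); lowering it admits weakly supported configurations at
extra cost. Raising `p0` relaxes sparsity; on null data mean PIPs
increase accordingly (a property the tests assert).

## The synthetic study generator

`simulate_study()` replaces reference-panel genotype simulation with a
self-contained parametric model so the full benchmark runs offline:

* **Genotypes.** Haplotypes come from a latent threshold model: within
  blocks of `ld_block_size` variants the latent field is Gaussian AR(1)
  with parameter `ld_rho`, and an allele is carried when the latent value
  exceeds a per-variant threshold set to hit a target minor-allele
  frequency drawn uniformly on `[maf_min, 0.5]` (default floor 0.02, the
  usual GWAS inclusion threshold). Genotypes are sums of two independent
  haplotypes, giving LD that decays roughly geometrically within blocks
  and vanishes between them. Columns are standardized to mean 0 and
  mean-square 1 so the empirical LD matrix has a unit diagonal.
* **Phenotype.** A mixed linear model: $d$ causal variants contribute a
  fixed effect $X_C\beta$ with $\beta \sim \mathcal N(0, I_d)$, the
  remaining variants a polygenic random effect with covariance
  $X_{NC}X_{NC}^\top/(m-d)$, plus Gaussian noise. The three components
  are rescaled by their empirical variances so that they carry exactly
  $p\,\omega^2$, $(1-p)\,\omega^2$ and $1-\omega^2$ of the phenotypic
  variance, where $\omega^2$ is the genotype-explained variance and $p$
  the causal share. Standardizing the noise draw as well as the genetic
  components makes the partition exact for all three terms; the total
  variance is then 1 up to the empirical covariance between components,
  which is small when the locus is large relative to its LD blocks.
* **Summary statistics.** Per-variant OLS with intercept on the *raw*
  dosages gives $\hat\beta_i$ and its standard error, hence
  $z_i = \hat\beta_i/\mathrm{se}(\hat\beta_i)$ (clipped at 200); the LD
  matrix is $X^\top X/n$ on standardized dosages.

What the generator does *not* emulate: recombination-map-accurate LD
decay, realistic allele-frequency spectra (real spectra are skewed toward
rare variants; ours is uniform above the floor), imputation error, and
relatedness. Tests that pass on these simulations therefore demonstrate
correctness of the statistical machinery and qualitative behavior
(recovery, calibration direction, sparsity control), not quantitative
performance on any particular real locus.

## Problem sizes used by the tests

The shipped tests and the acceptance script run desk-scale versions of
the benchmark: loci of $m = 100$ variants with $n = 5000$ individuals for
the recovery study (20 replicates at $d = 1$, $\omega^2 = 0.6$, causal
share 0.9, `ld_rho` 0.3), $m = 200$ for the variance-calibration grid,
$m = 50$ null loci, and $m \le 20$ for oracle comparisons where exhaustive
enumeration over all configurations is feasible. These sizes were chosen
so every quantity can be recomputed from scratch in minutes while keeping
each check statistically meaningful.

## A note on credible-set coverage at small locus size

One benchmark behavior deserves explanation. Under the mixed-model
phenotype, *every* non-causal variant has a real, nonzero effect through
the polygenic component. Its magnitude scales as
$(1-p)\,\omega^2/(m-d)$ per variant: at $m = 1000$ these effects are
individually negligible, but at a scaled-down $m = 100$ with
$\omega^2 = 0.6$, $p = 0.9$, non-causal z-scores have standard deviation
near 2.4, and several variants per locus exceed the posterior inclusion
bar ($|z| \gtrsim 3.6$ under the default prior). The exact posterior —
verified against exhaustive enumeration — assigns such variants PIPs near
1, and each earns a credible set that contains no *designated* causal
variant. Measured coverage against the causal labels therefore drops far
below the nominal level at this locus size, while top-variant recovery,
power, and AUPRC remain high. This is a property of the evaluation at
small $m$, not of the inference: the sets faithfully tag variants with
genuinely nonzero effects. At larger $m$ (weaker per-variant polygenic
effects and a stricter $1/m$ prior) the same pipeline yields
conventionally high coverage.

## Known limitations

* Posterior effect sizes are not estimated; the causal vector models the
  *variance* of effects, so downstream effect-size inference needs a
  separate conditional analysis.
* The variational family is fully factorized; strongly correlated pairs
  are handled through the configuration harvest rather than through
  correlated proposals.
* The Bernoulli-limit KL is an approximation valid for small
  temperatures; it is only used in the regime the annealing schedule
  enforces.
* Inputs must share one variant ordering: the LD matrix is taken in file
  order and never reordered by identifier.
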