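#' GWAS summary statistics for one locus
#'
#' Bundles the inputs every fine-mapping operation consumes: the vector of
#' per-variant z-scores, the matching LD (Pearson correlation) matrix, and
#' the GWAS sample size. Validation enforces the contracts the downstream
#' likelihood relies on: the LD matrix must be symmetric with unit diagonal
#' and must match the length of `z`.
#'
#' @param z Either a numeric vector of z-scores or a data frame with columns
#'   `variant_id` and `z` (the tidy form written by [read_zscores()]).
#' @param ld Square numeric matrix of genotype correlations, in the same
#'   variant order as `z`.
#' @param n Positive integer GWAS sample size.
#' @param variant_ids Optional character vector of variant identifiers;
#'   defaults to `v1..vm` (ignored when `z` is a data frame).
#'
#' @return An object of class `summary_stats`: a list with elements `z`,
#'   `ld`, `n`, `variant_ids`, and `m`.
#' @examples
#' ss <- summary_stats(c(1.2, -0.4), diag(2), n = 5000)
#' ss$m
#' @export
summary_stats <- function(z, ld, n, variant_ids = NULL) {
  if (is.data.frame(z)) {
    if (!all(c("variant_id", "z") %in% names(z))) {
      stop_input("data-frame input to summary_stats() needs columns 'variant_id' and 'z'")
    }
    variant_ids <- as.character(z$variant_id)
    z <- as.numeric(z$z)
  }
  z <- as.numeric(z)
  m <- length(z)
  if (!is.matrix(ld) || nrow(ld) != ncol(ld)) {
    stop_input("ld must be a square matrix")
  }
  if (nrow(ld) != m) {
    stop_input("dimension mismatch: length(z) = %d but ld is %dx%d", m, nrow(ld), ncol(ld))
  }
  if (any(!is.finite(z))) stop_input("z contains non-finite values")
  if (any(!is.finite(ld))) stop_input("ld contains non-finite values")
  asym <- max(abs(ld - t(ld)))
  if (asym > 1e-6) stop_input("ld is not symmetric (max |A - t(A)| = %.3g)", asym)
  ld <- (ld + t(ld)) / 2
  dmax <- max(abs(diag(ld) - 1))
  if (dmax > 1e-6) stop_input("ld diagonal deviates from 1 (max |diag - 1| = %.3g)", dmax)
  diag(ld) <- 1
  if (length(n) != 1 || !is.finite(n) || n < 1) stop_input("n must be a positive integer")
  if (is.null(variant_ids)) {
    variant_ids <- paste0("v", seq_len(m))
  }
  variant_ids <- as.character(variant_ids)
  if (length(variant_ids) != m) {
    stop_input("length(variant_ids) = %d but m = %d", length(variant_ids), m)
  }
  structure(
    list(z = z, ld = unname(ld), n = as.integer(n), variant_ids = variant_ids, m = m),
    class = "summary_stats"
  )
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf(
    "<summary_stats> m = %d variants, n = %d, max |z| = %.2f\n",
    x$m, x$n, max(abs(x$z))
  ))
  invisible(x)
}

#' Effect-size prior for the summary-statistic likelihood
#'
#' The per-causal-variant effect variance scale sigma2 enters the
#' marginal covariance of the z-scores as `n * sigma2 * diag(c)`. The
#' default 0.005 gives `n * sigma2 = 25` at the conventional n = 5000, the
#' standardized-effect scale usual in summary-statistic fine-mapping.
#' `ridge` is added to the diagonal of the LD matrix before any
#' factorization so that rank-deficient empirical LD is handled.
#'
#' @param sigma2 Positive effect-variance scale.
#' @param ridge Non-negative diagonal stabilizer.
#' @return An object of class `effect_prior`.
#' @export
effect_prior <- function(sigma2 = 0.005, ridge = 1e-4) {
  if (sigma2 <= 0) stop_input("sigma2 must be > 0")
  if (ridge < 0) stop_input("ridge must be >= 0")
  structure(list(sigma2 = sigma2, ridge = ridge), class = "effect_prior")
}

#' Binary concrete prior configuration
#'
#' The prior over causal configurations is an element-wise binary concrete
#' distribution with scalar inclusion probability `p0` (default the uniform
#' 1/m, resolved when the locus size is known) and temperature `lam0`.
#'
#' @param p0 Scalar prior inclusion probability in (0,1), or `NULL` for 1/m.
#' @param lam0 Positive prior relaxation temperature.
#' @return An object of class `prior_config`.
#' @export
prior_config <- function(p0 = NULL, lam0 = 0.01) {
  if (!is.null(p0) && (p0 <= 0 || p0 >= 1)) stop_input("p0 must lie in (0,1)")
  if (lam0 <= 0) stop_input("lam0 must be > 0")
  structure(list(p0 = p0, lam0 = lam0), class = "prior_config")
}

resolve_p0 <- function(prior, m) prior$p0 %||% (1 / m)

# One-time factorization of the ridge-stabilized LD matrix M = ld + ridge*I.
# Everything the low-rank likelihood path needs is cached here:
# chol(M), log det M, M^{-1} z, z' M^{-1} z and the null log-density.
ld_cache <- function(stats, prior = effect_prior()) {
  m <- stats$m
  M <- stats$ld
  diag(M) <- diag(M) + prior$ridge
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
    stop_numeric(
      "stabilized LD matrix is not positive definite (smallest eigenvalue %.3g); increase ridge",
      ev
    )
  }
  logdetM <- 2 * sum(log(diag(ch)))
  Minv_z <- backsolve(ch, backsolve(ch, stats$z, transpose = TRUE))
  q0 <- sum(stats$z * Minv_z)
  base_ll <- -0.5 * (m * log(2 * pi) + logdetM + q0)
  list(
    M = M, chol = ch, logdetM = logdetM, Minv_z = Minv_z, q0 = q0,
    base_ll = base_ll, nsigma2 = stats$n * prior$sigma2, m = m, z = stats$z
  )
}
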