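#' Fine-map a locus from GWAS summary statistics
#'
#' The front door of the package. Takes per-variant z-scores (tidy data
#' frame or [summary_stats()] object) plus the matching LD matrix and sample
#' size, fits the variational model with [fit_finemap_vi()], re-weights the
#' harvested causal configurations under the likelihood, and returns
#' posterior inclusion probabilities and credible sets.
#'
#' @param data A data frame with columns `variant_id` and `z`, or a
#'   [summary_stats()] object (then `ld` and `n` are ignored).
#' @param ld m-by-m LD (correlation) matrix in the same variant order.
#' @param n GWAS sample size.
#' @param coverage Credible-set coverage level (default 0.95).
#' @param max_sets Maximum number of credible sets.
#' @param prior A [prior_config()].
#' @param eff An [effect_prior()].
#' @param net_cfg An [inference_net_config()].
#' @param tr A [train_config()]; set `tr = train_config(seed = ...)` for a
#'   reproducible run.
#' @return An object of class `finemap_fit`. Use [tidy()] for the
#'   per-variant PIP table, [glance()] for run-level summaries,
#'   `autoplot()` for a PIP plot; components `credible_sets`,
#'   `config_posterior`, `loss_trace` are also directly accessible.
#' @examples
#' \donttest{
#' study <- simulate_study(sim_config(n = 1000, m = 30, d = 1, seed = 2))
#' fit <- finemap(study$stats, tr = train_config(iters = 300, seed = 2))
#' tidy(fit)
#' }
#' @export
finemap <- function(data, ld = NULL, n = NULL, coverage = 0.95, max_sets = 10L,
                    prior = prior_config(), eff = effect_prior(),
                    net_cfg = NULL, tr = train_config()) {
  stats <- if (inherits(data, "summary_stats")) {
    data
  } else {
    if (is.null(ld) || is.null(n)) {
      stop_input("supply ld and n alongside a data-frame input")
    }
    summary_stats(data, ld, n)
  }
  net_cfg <- net_cfg %||% inference_net_config(seed = tr$seed)
  t0 <- proc.time()[["elapsed"]]
  fit <- fit_finemap_vi(stats, net_cfg = net_cfg, tr = tr, prior = prior, eff = eff)
  posterior <- config_posterior(fit$configs, stats, prior = prior, eff = eff)
  pip <- compute_pips(posterior, stats$m)
  sets <- credible_sets(posterior, stats, coverage = coverage, max_sets = max_sets)
  elapsed <- proc.time()[["elapsed"]] - t0
  structure(
    list(
      stats = stats,
      pip = pip,
      credible_sets = sets,
      config_posterior = posterior,
      p_map = fit$p_map,
      loss_trace = fit$loss_trace,
      lam_trace = fit$lam_trace,
      configs = fit$configs,
      net = fit$net,
      settings = list(
        coverage = coverage, max_sets = max_sets,
        prior = prior, eff = eff, net_cfg = net_cfg, train = tr,
        p0 = resolve_p0(prior, stats$m)
      ),
      elapsed = elapsed
    ),
    class = "finemap_fit"
  )
}

#' @export
print.finemap_fit <- function(x, ...) {
  cat(sprintf(
    "<finemap_fit> m = %d variants, n = %d\n", x$stats$m, x$stats$n
  ))
  top <- order(-x$pip)[seq_len(min(5, x$stats$m))]
  cat("Top PIPs:\n")
  for (i in top) {
    cat(sprintf("  %-12s z = %7.2f  pip = %.3f\n",
                x$stats$variant_ids[i], x$stats$z[i], x$pip[i]))
  }
  cat(sprintf("%d credible set(s) at coverage %.2f\n",
              nrow(x$credible_sets), x$settings$coverage))
  invisible(x)
}

# which credible set (if any) each variant belongs to
cs_membership <- function(fit) {
  cs <- rep(NA_integer_, fit$stats$m)
  sets <- fit$credible_sets
  if (nrow(sets)) {
    for (j in rev(seq_len(nrow(sets)))) cs[sets$variants[[j]]] <- sets$cs[j]
  }
  cs
}

#' Tidy a fine-mapping fit into a per-variant tibble
#'
#' @param x A `finemap_fit`.
#' @param ... Unused.
#' @method tidy finemap_fit
#' @return A tibble with columns `variant_id`, `z`, `pip`, `p_map` (the
#'   variational probability map) and `cs` (credible-set id or `NA`).
#' @export
tidy.finemap_fit <- function(x, ...) {
  tibble::tibble(
    variant_id = x$stats$variant_ids,
    z = x$stats$z,
    pip = x$pip,
    p_map = x$p_map,
    cs = cs_membership(x)
  )
}

#' One-row summary of a fine-mapping fit
#'
#' @param x A `finemap_fit`.
#' @param ... Unused.
#' @method glance finemap_fit
#' @return A one-row tibble: locus size, number of harvested configurations,
#'   number of credible sets, their mean size, max PIP, final loss, elapsed
#'   seconds.
#' @export
glance.finemap_fit <- function(x, ...) {
  tibble::tibble(
    m = x$stats$m,
    n = x$stats$n,
    n_configs = nrow(x$config_posterior),
    n_credible_sets = nrow(x$credible_sets),
    mean_cs_size = if (nrow(x$credible_sets)) mean(x$credible_sets$size) else NA_real_,
    max_pip = max(x$pip),
    final_loss = x$loss_trace[length(x$loss_trace)],
    elapsed = x$elapsed
  )
}

#' Plot posterior inclusion probabilities
#'
#' Lollipop plot of PIPs along the locus; variants in a credible set are
#' colored by set.
#'
#' @param object A `finemap_fit`.
#' @param ... Unused.
#' @method autoplot finemap_fit
#' @return A ggplot object.
#' @export
autoplot.finemap_fit <- function(object, ...) {
  df <- tidy(object)
  df$index <- seq_len(nrow(df))
  df$cs <- factor(df$cs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$pip)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$index, yend = 0), color = "grey70") +
    ggplot2::geom_point(ggplot2::aes(color = .data$cs), size = 2) +
    ggplot2::scale_color_discrete(na.value = "grey40", name = "credible set") +
    ggplot2::labs(x = "variant index", y = "PIP") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
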