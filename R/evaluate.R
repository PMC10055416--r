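#' Area under the precision-recall curve for PIPs
#'
#' Exact step-function integration over all distinct score thresholds, with
#' tied scores grouped into a single threshold step (which avoids the
#' optimistic interpolation a trapezoid rule would give on ties). The
#' result is invariant to strictly monotone transformations of the scores.
#'
#' @param pip Numeric score vector (typically PIPs).
#' @param truth 0/1 vector (or logical) marking the causal variants; at
#'   least one positive is required.
#' @return The AUPRC, a number in `[0,1]`.
#' @examples
#' auprc(c(0.9, 0.1, 0.2), c(1, 0, 0)) # 1
#' @export
auprc <- function(pip, truth) {
  truth <- as.integer(as.logical(truth))
  if (length(pip) != length(truth)) stop_input("pip and truth differ in length")
  P <- sum(truth)
  if (P == 0) stop_input("truth contains no positives")
  thr <- sort(unique(pip), decreasing = TRUE)
  area <- 0
  prev_rec <- 0
  for (t in thr) {
    called <- pip >= t
    tp <- sum(truth[called])
    prec <- tp / sum(called)
    rec <- tp / P
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

#' Power versus FDR curve from PIPs
#'
#' Sweeps every distinct score threshold; at each, FDR is `1 - precision`
#' and power is recall among the variants called at or above the threshold.
#'
#' @inheritParams auprc
#' @return A tibble with columns `threshold`, `fdr`, `power`, ordered from
#'   the highest threshold down.
#' @export
power_fdr_curve <- function(pip, truth) {
  truth <- as.integer(as.logical(truth))
  if (length(pip) != length(truth)) stop_input("pip and truth differ in length")
  P <- sum(truth)
  if (P == 0) stop_input("truth contains no positives")
  thr <- sort(unique(pip), decreasing = TRUE)
  rows <- lapply(thr, function(t) {
    called <- pip >= t
    tp <- sum(truth[called])
    tibble::tibble(threshold = t, fdr = 1 - tp / sum(called), power = tp / P)
  })
  dplyr::bind_rows(rows)
}

#' Coverage, power and mean size of credible sets
#'
#' Coverage is the fraction of reported sets containing at least one causal
#' variant; power is the fraction of causal variants captured by the union
#' of all sets; mean size is the average set cardinality. With no sets,
#' power is 0 and coverage/mean size are `NA` (undefined rather than
#' penalized).
#'
#' @param sets A list of integer vectors, or the credible-set tibble
#'   returned by [credible_sets()] / stored in a `finemap_fit`.
#' @param truth_causal Integer indices of the true causal variants.
#' @return A one-row tibble with `coverage`, `power`, `mean_size`,
#'   `n_sets`.
#' @examples
#' credible_set_metrics(list(c(1, 2), 4), truth_causal = c(2, 4, 9))
#' @export
credible_set_metrics <- function(sets, truth_causal) {
  if (is.data.frame(sets)) sets <- sets$variants
  sets <- lapply(sets, function(s) unique(as.integer(s)))
  k <- length(sets)
  if (k == 0) {
    return(tibble::tibble(coverage = NA_real_, power = 0, mean_size = NA_real_, n_sets = 0L))
  }
  hit <- vapply(sets, function(s) any(truth_causal %in% s), logical(1))
  found <- unique(unlist(sets))
  tibble::tibble(
    coverage = mean(hit),
    power = mean(truth_causal %in% found),
    mean_size = mean(lengths(sets)),
    n_sets = k
  )
}

#' Run a simulation-and-fine-mapping grid
#'
#' Sweeps the noise configurations of the simulation study — number of
#' causal variants `d`, genotype-explained variance `omega2`, and causal
#' variance share — with `replicates` independently seeded studies per
#' cell, fine-mapping each and collecting the evaluation metrics. Every
#' axis is overridable so desk-scale runs are cheap.
#'
#' @param d,omega2,share Vectors of grid values.
#' @param replicates Studies per grid cell.
#' @param base A [sim_config()] providing n, m, LD structure and the base
#'   seed (cell seeds are derived deterministically from it).
#' @param tr A [train_config()] for the fits.
#' @param coverage Credible-set coverage level.
#' @return A tibble with one row per replicate and columns `d`, `omega2`,
#'   `share`, `replicate`, `seed`, `auprc`, `coverage`, `power`,
#'   `mean_size`, `n_sets`, `top_hit` (is the top-PIP variant causal).
#' @export
run_grid <- function(d = c(1, 4, 8, 12),
                     omega2 = c(0.1, 0.2, 0.4, 0.5, 0.7, 0.8),
                     share = c(0.1, 0.3, 0.5, 0.7, 0.9),
                     replicates = 20,
                     base = sim_config(),
                     tr = train_config(),
                     coverage = 0.95) {
  grid <- tidyr::expand_grid(d = d, omega2 = omega2, share = share,
                             replicate = seq_len(replicates))
  rows <- purrr::pmap(grid, function(d, omega2, share, replicate) {
    seed <- (base$seed + 7919L * replicate +
               199L * match(d, sort(unique(d))) +
               31L * round(1000 * omega2) + round(1000 * share)) %% .Machine$integer.max
    cfg <- sim_config(
      n = base$n, m = base$m, d = d, omega2 = omega2, causal_var_share = share,
      ld_block_size = base$ld_block_size, ld_rho = base$ld_rho,
      maf_min = base$maf_min, seed = seed
    )
    study <- simulate_study(cfg)
    tr_rep <- tr
    tr_rep$seed <- seed
    fit <- finemap(study$stats, coverage = coverage, tr = tr_rep)
    truth <- as.integer(seq_len(cfg$m) %in% study$causal_indices)
    met <- credible_set_metrics(fit$credible_sets, study$causal_indices)
    tibble::tibble(
      d = d, omega2 = omega2, share = share, replicate = replicate, seed = seed,
      auprc = auprc(fit$pip, truth),
      coverage = met$coverage, power = met$power,
      mean_size = met$mean_size, n_sets = met$n_sets,
      top_hit = which.max(fit$pip) %in% study$causal_indices
    )
  })
  dplyr::bind_rows(rows)
}

#' Summarize grid metrics along one swept axis
#'
#' Reproduces the reporting scheme of the simulation study: for each value
#' of the chosen axis, the mean of each metric across all other
#' configurations and replicates, with a 95% normal-approximation
#' confidence interval (`mean +/- 1.96 * se`).
#'
#' @param results A tibble from [run_grid()].
#' @param by One of `"d"`, `"omega2"`, `"share"`.
#' @return A tibble with `by`-value, `metric`, `mean`, `lo`, `hi`, `n`.
#' @export
summarize_grid <- function(results, by = c("d", "omega2", "share")) {
  by <- match.arg(by)
  long <- tidyr::pivot_longer(
    results[, c(by, "auprc", "coverage", "power", "mean_size")],
    cols = c("auprc", "coverage", "power", "mean_size"),
    names_to = "metric", values_to = "value"
  )
  long <- dplyr::filter(long, is.finite(.data$value))
  out <- dplyr::summarise(
    dplyr::group_by(long, .data[[by]], .data$metric),
    mean = mean(.data$value),
    se = sd(.data$value) / sqrt(dplyr::n()),
    n = dplyr::n(),
    .groups = "drop"
  )
  dplyr::mutate(out, lo = .data$mean - 1.96 * .data$se, hi = .data$mean + 1.96 * .data$se)
}

#' Plot grid metric summaries
#'
#' Mean-and-95%-CI panels per metric along a swept simulation axis, one
#' panel per metric.
#'
#' @param summary A tibble from [summarize_grid()].
#' @return A ggplot object.
#' @export
plot_grid_summary <- function(summary) {
  axis <- setdiff(names(summary), c("metric", "mean", "se", "n", "lo", "hi"))[1]
  ggplot2::ggplot(summary, ggplot2::aes(x = .data[[axis]], y = .data$mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi)) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = axis, y = "metric (mean, 95% CI)") +
    ggplot2::theme_minimal()
}

#' Plot a power-FDR curve
#'
#' @param curve A tibble from [power_fdr_curve()].
#' @return A ggplot object.
#' @export
plot_power_fdr <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$fdr, y = .data$power)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "FDR (1 - precision)", y = "power (recall)") +
    ggplot2::xlim(0, 1) + ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
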