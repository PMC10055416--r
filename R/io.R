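#' Read a z-score table
#'
#' Expects a whitespace- or tab-delimited file with at least two columns
#' (variant id, z), with an optional header line. Infinite or out-of-range
#' z-scores are clipped to `|z| <= 200` with a warning, mirroring the
#' numerical-stability treatment applied to real GWAS releases where some
#' variants are reported with infinite scores.
#'
#' @param path Path to the file.
#' @return A tibble with columns `variant_id` and `z`, in file order.
#' @export
read_zscores <- function(path) {
  if (!file.exists(path)) stop_input("z-score file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) stop_input("z-score file %s is empty", path)
  parse_line <- function(ln) strsplit(trimws(ln), "[\\s,\\t]+", perl = TRUE)[[1]]
  first <- parse_line(lines[1])
  has_header <- length(first) >= 2 && is.na(suppressWarnings(as.numeric(first[2])))
  body <- if (has_header) lines[-1] else lines
  offset <- if (has_header) 1L else 0L
  ids <- character(length(body))
  z <- numeric(length(body))
  for (i in seq_along(body)) {
    f <- parse_line(body[i])
    if (length(f) < 2) stop_input("line %d of %s has fewer than 2 columns", i + offset, path)
    ids[i] <- f[1]
    val <- suppressWarnings(as.numeric(f[2]))
    if (is.na(val) && !grepl("^-?inf(inity)?$", tolower(f[2]))) {
      stop_input("non-numeric z '%s' at line %d of %s", f[2], i + offset, path)
    }
    if (is.na(val)) val <- if (startsWith(tolower(f[2]), "-")) -Inf else Inf
    z[i] <- val
  }
  dup <- which(duplicated(ids))
  if (length(dup)) {
    stop_input("duplicate variant id '%s' at line %d of %s", ids[dup[1]], dup[1] + offset, path)
  }
  if (any(abs(z) > 200)) {
    warn(sprintf("%d z-score(s) clipped to |z| = 200 in %s", sum(abs(z) > 200), path))
    z <- clamp(z, -200, 200)
  }
  tibble::tibble(variant_id = ids, z = z)
}

#' Read an LD matrix
#'
#' Reads a whitespace- or comma-delimited square numeric matrix (optionally
#' gzip-compressed). Small asymmetries (at most 1e-6) are symmetrized as
#' `(A + t(A)) / 2` and diagonal entries within 1e-6 of 1 are reset to
#' exactly 1; larger deviations are errors, as are entries outside
#' `[-1, 1]` beyond tolerance.
#'
#' @param path Path to the file.
#' @param m Optional expected dimension; checked if given.
#' @return An m-by-m numeric matrix.
#' @export
read_ld <- function(path, m = NULL) {
  if (!file.exists(path)) stop_input("LD file not found: %s", path)
  rows <- utils::read.table(path, header = FALSE, sep = "",
                            comment.char = "#", strip.white = TRUE)
  if (ncol(rows) == 1 && any(grepl(",", rows[[1]], fixed = TRUE))) {
    rows <- utils::read.table(path, header = FALSE, sep = ",", comment.char = "#")
  }
  A <- as.matrix(rows)
  if (!is.numeric(A)) stop_input("LD file %s contains non-numeric entries", path)
  if (nrow(A) != ncol(A)) {
    stop_input("LD matrix in %s is %dx%d, not square", path, nrow(A), ncol(A))
  }
  if (!is.null(m) && nrow(A) != m) {
    stop_input("LD matrix in %s is %dx%d but %d variants expected", path, nrow(A), ncol(A), m)
  }
  asym <- max(abs(A - t(A)))
  if (asym > 1e-6) stop_input("LD matrix in %s asymmetric beyond tolerance (%.3g)", path, asym)
  A <- (A + t(A)) / 2
  if (any(abs(A) > 1 + 1e-6)) {
    stop_input("LD matrix in %s has entries outside [-1, 1]", path)
  }
  dmax <- max(abs(diag(A) - 1))
  if (dmax > 1e-6) stop_input("LD diagonal in %s deviates from 1 by %.3g", path, dmax)
  diag(A) <- 1
  unname(A)
}

#' Write summary statistics to disk
#'
#' Writes the z-score table (`<prefix>_z.tsv`) and the LD matrix
#' (`<prefix>_ld.txt`) in the formats [read_zscores()] and [read_ld()]
#' accept, at 10 significant digits so the round trip is lossless for
#' practical purposes.
#'
#' @param stats A [summary_stats()] object.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_summary_stats <- function(stats, prefix) {
  zfile <- paste0(prefix, "_z.tsv")
  ldfile <- paste0(prefix, "_ld.txt")
  writeLines(
    c("variant_id\tz",
      sprintf("%s\t%.10g", stats$variant_ids, stats$z)),
    zfile
  )
  writeLines(apply(stats$ld, 1, function(r) paste(sprintf("%.10g", r), collapse = " ")), ldfile)
  invisible(c(z = zfile, ld = ldfile))
}

result_header <- function(fit) {
  s <- fit$settings
  c(sprintf("# seed: %d", s$train$seed),
    sprintf("# gamma: %g", s$train$binarize_gamma),
    sprintf("# sigma2: %g", s$eff$sigma2),
    sprintf("# coverage: %g", s$coverage))
}

#' Write the PIP table of a fit
#'
#' Tab-separated `variant_id`, `pip` with a comment header recording seed,
#' binarization threshold, effect-prior scale and coverage level.
#'
#' @param fit A `finemap_fit`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pip_tsv <- function(fit, path) {
  writeLines(
    c(result_header(fit),
      "variant_id\tpip",
      sprintf("%s\t%.10g", fit$stats$variant_ids, fit$pip)),
    path
  )
  invisible(path)
}

#' Write the credible sets of a fit
#'
#' Tab-separated long table: one row per (set, variant) with the variant's
#' PIP and the set's attained coverage.
#'
#' @inheritParams write_pip_tsv
#' @export
write_credible_sets_tsv <- function(fit, path) {
  rows <- character(0)
  sets <- fit$credible_sets
  if (nrow(sets)) {
    for (j in seq_len(nrow(sets))) {
      for (i in sets$variants[[j]]) {
        rows <- c(rows, sprintf("%d\t%s\t%.10g\t%.10g",
                                sets$cs[j], fit$stats$variant_ids[i],
                                fit$pip[i], sets$attained[j]))
      }
    }
  }
  writeLines(
    c(result_header(fit), "set_id\tvariant_id\tpip\tattained_coverage", rows),
    path
  )
  invisible(path)
}

#' Run configuration for an end-to-end fine-mapping run
#'
#' Gathers file paths and every tunable the run needs; fully serializable
#' (the resolved configuration is written next to the outputs as YAML).
#'
#' @param z_file,ld_file Input paths.
#' @param n GWAS sample size.
#' @param out_dir Output directory (created if missing).
#' @param coverage,max_sets,sigma2,ridge,p0,gamma Tunables forwarded to the
#'   fit; `NULL` `p0` means the uniform 1/m prior.
#' @param iters,mc_samples,step_size,seed Training controls.
#' @return An object of class `run_config`.
#' @export
run_config <- function(z_file, ld_file, n, out_dir,
                       coverage = 0.95, max_sets = 10L,
                       sigma2 = 0.005, ridge = 1e-4, p0 = NULL, gamma = 0.1,
                       iters = 2000L, mc_samples = 10L, step_size = 1e-3,
                       seed = 1L) {
  structure(
    list(z_file = z_file, ld_file = ld_file, n = as.integer(n),
         out_dir = out_dir, coverage = coverage, max_sets = as.integer(max_sets),
         sigma2 = sigma2, ridge = ridge, p0 = p0, gamma = gamma,
         iters = as.integer(iters), mc_samples = as.integer(mc_samples),
         step_size = step_size, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' End-to-end fine-mapping run with file outputs
#'
#' Reads the inputs, fits the model, and writes `pips.tsv`,
#' `credible_sets.tsv`, a structured `run_report.yaml` (loss trace summary,
#' temperature schedule endpoints, seed) and the resolved `config.yaml`
#' into the output directory. Output is deterministic given the seed.
#'
#' @param cfg A [run_config()].
#' @return The `finemap_fit`, invisibly; files as a side effect.
#' @export
run_finemap <- function(cfg) {
  ztab <- read_zscores(cfg$z_file)
  ld <- read_ld(cfg$ld_file, m = nrow(ztab))
  stats <- summary_stats(ztab, ld, cfg$n)
  tr <- train_config(iters = cfg$iters, mc_samples = cfg$mc_samples,
                     step_size = cfg$step_size, binarize_gamma = cfg$gamma,
                     seed = cfg$seed)
  fit <- finemap(
    stats, coverage = cfg$coverage, max_sets = cfg$max_sets,
    prior = prior_config(p0 = cfg$p0),
    eff = effect_prior(sigma2 = cfg$sigma2, ridge = cfg$ridge),
    tr = tr
  )
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_pip_tsv(fit, file.path(cfg$out_dir, "pips.tsv"))
  write_credible_sets_tsv(fit, file.path(cfg$out_dir, "credible_sets.tsv"))
  report <- list(
    seed = cfg$seed,
    m = stats$m,
    n = stats$n,
    iterations = cfg$iters,
    mc_samples = cfg$mc_samples,
    lambda = list(init = tr$lam_init, final = tr$lam_final, schedule = "geometric"),
    loss = list(first = fit$loss_trace[1],
                last = fit$loss_trace[length(fit$loss_trace)]),
    n_configs = nrow(fit$config_posterior),
    n_credible_sets = nrow(fit$credible_sets)
  )
  yaml::write_yaml(report, file.path(cfg$out_dir, "run_report.yaml"))
  cfg_out <- unclass(cfg)
  cfg_out$p0 <- cfg_out$p0 %||% "1/m"
  yaml::write_yaml(cfg_out, file.path(cfg$out_dir, "config.yaml"))
  invisible(fit)
}
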