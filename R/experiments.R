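#' Deterministic child seeds
#'
#' Hash-based seed splitter: a small multiplicative hash of the master seed
#' and any further integer keys, reduced modulo 2^31 - 1 so the result is a
#' valid R seed. Distinct (sweep value, replicate) keys give effectively
#' independent streams without coordination.
#'
#' @param master Master seed (integer).
#' @param ... Further integer keys (e.g. sweep index, replicate index).
#' @return A positive integer seed below 2^31.
#' @export
split_seed <- function(master, ...) {
  keys <- c(master, ...)
  h <- 0
  for (k in keys) {
    h <- (h * 69069 + (as.numeric(k) %% 2147483647) + 1) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

#' Wilson score interval for a proportion
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level.
#' @return Named vector `c(estimate, lower, upper)`.
#' @export
wilson_interval <- function(x, n, conf = 0.95) {
  if (n == 0L) return(c(estimate = NA_real_, lower = NA_real_, upper = NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(estimate = p, lower = centre - half, upper = centre + half)
}

boot_mean_ci <- function(x, conf = 0.95, B = 1000L) {
  if (length(x) == 0L) return(c(mean = NA_real_, lower = NA_real_, upper = NA_real_))
  means <- vapply(seq_len(B), function(b) {
    mean(x[sample.int(length(x), replace = TRUE)])
  }, numeric(1))
  qs <- stats::quantile(means, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  c(mean = mean(x), lower = qs[1L], upper = qs[2L])
}

#' Synchronous-scenario sweep over accuracy heterogeneity
#'
#' Runs the synchronous scenario for each algorithm and each heterogeneity
#' level on shared seeds: for a given (sigma_alpha, replicate) pair every
#' algorithm sees the same topology, the same accuracies, and the same
#' initial opinions, so outcome differences are attributable to the update
#' rule alone. Group accuracy is the proportion of runs ending unanimously
#' on the positive (true) state — timeouts count as failures — and consensus
#' times are summarized over converged runs only.
#'
#' @param sigma_alphas Heterogeneity levels to sweep.
#' @param algorithms Algorithms to compare (see [sd_config()]).
#' @param n Group size.
#' @param kappa Target mean degree of the random geometric graph.
#' @param replicates Runs per (level, algorithm).
#' @param master_seed Master seed; children via [split_seed()].
#' @param max_iter Iteration cap per run.
#' @param out_dir Optional directory: per-run rows are written to
#'   `runs_signal_detection.csv` and the summary to
#'   `summary_signal_detection.csv`.
#' @return A list with `runs` (one row per run) and `summary` (one row per
#'   level x algorithm with Wilson and bootstrap 95% intervals).
#' @export
sweep_signal_detection <- function(sigma_alphas = c(0.1, 0.3, 0.5),
                                   algorithms = c("WBC", "BC"),
                                   n = 50L, kappa = 10, replicates = 100L,
                                   master_seed = 1L, max_iter = 1000L,
                                   out_dir = NULL) {
  delta <- radius_for_target_degree(n, kappa,
                                    seed = split_seed(master_seed, 999L))
  rows <- list()
  for (si in seq_along(sigma_alphas)) {
    sa <- sigma_alphas[si]
    for (rep in seq_len(replicates)) {
      seed <- split_seed(master_seed, si, rep)
      tp <- generate_rgg(n, delta, seed = split_seed(seed, 1L),
                         connected = TRUE)
      for (alg in algorithms) {
        cfg <- sd_config(n = n, algorithm = alg, sigma_alpha = sa,
                         max_iter = max_iter)
        res <- run_synchronous(cfg, tp, seed = split_seed(seed, 2L))
        rows[[length(rows) + 1L]] <- data.frame(
          seed = seed, algorithm = alg, sigma_alpha = sa, n = n,
          kappa = kappa, outcome = res$outcome,
          consensus_time = ifelse(is.na(res$consensus_time), NA_integer_,
                                  res$consensus_time)
        )
      }
    }
  }
  runs <- do.call(rbind, rows)
  summary <- aggregate_signal_detection(runs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(runs, file.path(out_dir, "runs_signal_detection.csv"),
                     row.names = FALSE)
    utils::write.csv(summary,
                     file.path(out_dir, "summary_signal_detection.csv"),
                     row.names = FALSE)
  }
  list(runs = runs, summary = summary)
}

#' Aggregate per-run synchronous results
#'
#' Recomputes the summary table from the per-run rows (the written CSV
#' round-trips to the same summary).
#'
#' @param runs Per-run data frame from [sweep_signal_detection()].
#' @return One row per (sigma_alpha, algorithm).
#' @export
aggregate_signal_detection <- function(runs) {
  keys <- unique(runs[, c("sigma_alpha", "algorithm")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- runs[runs$sigma_alpha == keys$sigma_alpha[i] &
                  runs$algorithm == keys$algorithm[i], ]
    wi <- wilson_interval(sum(sub$outcome == "unanimous-correct"), nrow(sub))
    ct <- sub$consensus_time[!is.na(sub$consensus_time)]
    data.frame(
      sigma_alpha = keys$sigma_alpha[i], algorithm = keys$algorithm[i],
      runs = nrow(sub), accuracy = wi[["estimate"]],
      accuracy_lo = wi[["lower"]], accuracy_hi = wi[["upper"]],
      mean_consensus_time = if (length(ct)) mean(ct) else NA_real_,
      converged = length(ct)
    )
  })
  do.call(rbind, out)
}

#' Paired synchronous comparison on shared seeds
#'
#' Convenience wrapper returning, per seed, the consensus-time difference and
#' outcomes of two algorithms run on identical topology, accuracies and
#' initial opinions.
#'
#' @inheritParams sweep_signal_detection
#' @param sigma_alpha Single heterogeneity level.
#' @param algorithms Two or more algorithm names (repeats allowed).
#' @return Data frame, one row per seed, with an `outcome.<k>` and
#'   `consensus_time.<k>` column per algorithm position, plus `time_diff`
#'   (first minus second).
#' @export
paired_comparison <- function(sigma_alpha = 0.3, algorithms = c("WBC", "BC"),
                              n = 50L, kappa = 10, replicates = 100L,
                              master_seed = 1L, max_iter = 1000L) {
  stopifnot(length(algorithms) >= 2L)
  per_alg <- lapply(algorithms, function(alg) {
    sweep_signal_detection(sigma_alpha, alg, n, kappa, replicates,
                           master_seed, max_iter)$runs
  })
  out <- data.frame(seed = per_alg[[1L]]$seed)
  for (k in seq_along(algorithms)) {
    stopifnot(identical(per_alg[[k]]$seed, out$seed))
    out[[sprintf("outcome.%d", k)]] <- per_alg[[k]]$outcome
    out[[sprintf("consensus_time.%d", k)]] <- per_alg[[k]]$consensus_time
  }
  out$time_diff <- out$consensus_time.1 - out$consensus_time.2
  attr(out, "algorithms") <- algorithms
  out
}

#' Asynchronous-scenario experiment
#'
#' Runs replicated asynchronous simulations at each drift-heterogeneity
#' level, on freshly drawn connected random geometric graphs, optionally
#' paired with an asocial baseline (kicks disabled, same seeds). The
#' Bayes-risk-optimal threshold is computed once per level.
#'
#' @param sigma_As Drift-spread levels to sweep.
#' @param n Group size.
#' @param kappa Target mean degree.
#' @param mu_A Mean drift magnitude.
#' @param sigma Diffusion noise.
#' @param cost A [cost_spec()].
#' @param dt Integration step.
#' @param replicates Runs per level.
#' @param master_seed Master seed.
#' @param asocial_baseline Also run the kick-disabled twin of every run.
#' @param out_dir Optional directory for per-run and per-cascade CSV output.
#' @return A list with `runs` (per-run summary rows), `results` (per level:
#'   list of `seq_run_result`), `stats` (per level: [influence_stats()]),
#'   and `z` (per-level thresholds).
#' @export
sweep_sequential <- function(sigma_As = c(0, 0.5), n = 50L, kappa = 10,
                             mu_A = 0.2, sigma = 1, cost = cost_spec(1, 100),
                             dt = 0.01, replicates = 100L, master_seed = 1L,
                             asocial_baseline = FALSE, out_dir = NULL) {
  delta <- radius_for_target_degree(n, kappa,
                                    seed = split_seed(master_seed, 999L))
  rows <- list()
  results <- list()
  stats_by <- list()
  zs <- numeric(length(sigma_As))
  for (si in seq_along(sigma_As)) {
    sA <- sigma_As[si]
    prior <- drift_prior(mu_A, sA)
    cfg <- seq_config(n = n, prior = prior, sigma = sigma, cost = cost,
                      dt = dt)
    zs[si] <- cfg$z
    cfg_aso <- seq_config(n = n, prior = prior, sigma = sigma, cost = cost,
                          dt = dt, z = cfg$z, kicks_enabled = FALSE)
    lvl_runs <- vector("list", replicates)
    for (rep in seq_len(replicates)) {
      seed <- split_seed(master_seed, si, rep)
      tp <- generate_rgg(n, delta, seed = split_seed(seed, 1L),
                         connected = TRUE)
      res <- run_asynchronous(cfg, tp, seed = split_seed(seed, 2L))
      lvl_runs[[rep]] <- res
      rows[[length(rows) + 1L]] <- data.frame(
        sigma_A = sA, replicate = rep, seed = seed, social = TRUE,
        decided = sum(res$decided),
        correct = sum(res$option == res$true_state, na.rm = TRUE),
        mean_cost = bayes_risk_cost(res, cost)
      )
      if (asocial_baseline) {
        res0 <- run_asynchronous(cfg_aso, tp, seed = split_seed(seed, 2L))
        rows[[length(rows) + 1L]] <- data.frame(
          sigma_A = sA, replicate = rep, seed = seed, social = FALSE,
          decided = sum(res0$decided),
          correct = sum(res0$option == res0$true_state, na.rm = TRUE),
          mean_cost = bayes_risk_cost(res0, cost)
        )
      }
    }
    results[[as.character(sA)]] <- lvl_runs
    stats_by[[as.character(sA)]] <- influence_stats(lvl_runs)
  }
  runs <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(runs, file.path(out_dir, "runs_sequential.csv"),
                     row.names = FALSE)
    casc <- do.call(rbind, lapply(names(stats_by), function(k) {
      s <- stats_by[[k]]$sizes
      if (nrow(s) > 0L) cbind(sigma_A = as.numeric(k), s)
    }))
    if (!is.null(casc)) {
      utils::write.csv(casc, file.path(out_dir, "cascades_sequential.csv"),
                       row.names = FALSE)
    }
  }
  list(runs = runs, results = results, stats = stats_by, z = zs)
}
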