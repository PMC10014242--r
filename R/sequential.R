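#' Configuration for an asynchronous collective run
#'
#' @param n Group size.
#' @param prior A [drift_prior()] for the population's drift magnitudes.
#' @param sigma Diffusion noise shared by all agents.
#' @param cost A [cost_spec()]; thresholds are set from it via
#'   [optimal_threshold()] unless `z` is supplied.
#' @param dt Integration time step.
#' @param true_state True world state, +1 or -1.
#' @param z Optional threshold magnitude override.
#' @param max_time Simulation horizon; `NULL` defaults to 10 times the
#'   asocial mean decision time under the drift prior.
#' @param kicks_enabled If `FALSE`, decisions are never broadcast (asocial
#'   baseline on the same seeds).
#' @return A `seq_config` list (with the resolved threshold `z` and horizon).
#' @export
seq_config <- function(n = 50L, prior = drift_prior(0.2, 0.5), sigma = 1,
                       cost = cost_spec(1, 100), dt = 0.01, true_state = 1,
                       z = NULL, max_time = NULL, kicks_enabled = TRUE) {
  stopifnot(n >= 1, inherits(prior, "drift_prior"), sigma > 0,
            inherits(cost, "cost_spec"), dt > 0, abs(true_state) == 1)
  if (is.null(z)) z <- as.numeric(optimal_threshold(cost, prior, sigma))
  if (is.null(max_time)) {
    max_time <- 10 * fold_expect(
      function(a) expected_decision_time(a, z, sigma), prior
    )
  }
  structure(
    list(n = as.integer(n), prior = prior, sigma = sigma, cost = cost,
         dt = dt, true_state = true_state, z = z, max_time = max_time,
         kicks_enabled = isTRUE(kicks_enabled)),
    class = "seq_config"
  )
}

# Memoizing wrapper around kick_size: decision times are multiples of dt, so
# repeated senders at the same step share one quadrature.
make_kick_cache <- function(prior, sigma, z) {
  cache <- new.env(parent = emptyenv())
  function(t) {
    key <- sprintf("%.12g", t)
    if (is.null(cache[[key]])) {
      # log-odds toward the option, without the world-prior term
      cache[[key]] <- kick_size(t, 1, prior, sigma, z, 0.5)
    }
    cache[[key]]
  }
}

#' Run the asynchronous scenario
#'
#' All agents start accumulating evidence at time zero with drifts drawn from
#' the population prior (signed toward the true state). Time advances in
#' steps of `dt`; undecided agents integrate drift and noise, agents whose
#' evidence crosses a threshold decide, broadcast once, and freeze. Each
#' broadcast delivers, one step later, a signed evidence increment of
#' magnitude [kick_size()] (evaluated at the sender's decision time) to every
#' neighbour still undecided at delivery. A decision is attributed to a kick
#' when the agent's pre-kick evidence had not crossed; the causing neighbour
#' is the one whose kick contributed most in the crossing direction (ties:
#' earlier sender decision, then lower index).
#'
#' @param config A [seq_config()].
#' @param tp A connected [topology()] with `config$n` nodes.
#' @param seed Integer seed (drifts, then path noise).
#' @param drifts Optional vector of signed drifts overriding the draw from
#'   the prior (instrumentation and controlled experiments).
#' @return A list of class `seq_run_result`: `events` (data frame with
#'   columns `agent`, `time`, `option`, `cause`, `parent`, ordered by time),
#'   `decided`, `option`, `time` (per agent; NA where undecided), `undecided`
#'   (indices), `drifts`, `z`, `horizon`.
#' @export
run_asynchronous <- function(config, tp, seed = NULL, drifts = NULL) {
  stopifnot(inherits(config, "seq_config"), inherits(tp, "topology"))
  if (tp$n != config$n) stop("topology size does not match config")
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  dt <- config$dt
  sig <- config$sigma
  z <- config$z
  if (is.null(drifts)) {
    drifts <- sample_drifts(config$prior, config$true_state, n)
  } else {
    stopifnot(length(drifts) == n)
  }
  kick_lookup <- make_kick_cache(config$prior, sig, z)
  prior_term <- prior_log_odds(config$cost$p_plus, 1)

  y <- numeric(n)
  decided <- logical(n)
  opt <- rep(NA_real_, n)
  dtime <- rep(NA_real_, n)
  cause <- rep(NA_character_, n)
  parent <- rep(NA_integer_, n)
  # kicks scheduled for delivery at the next step: world-frame amounts
  pending <- list()
  sdt <- sig * sqrt(dt)
  n_steps <- ceiling(config$max_time / dt)

  for (step in seq_len(n_steps)) {
    und <- which(!decided)
    if (length(und) == 0L) break
    t_now <- step * dt
    y_pre <- y[und] + drifts[und] * dt + sdt * stats::rnorm(length(und))
    ksum <- numeric(length(und))
    contrib <- NULL
    if (length(pending) > 0L) {
      deliv <- do.call(rbind, pending)
      deliv <- deliv[!decided[deliv$receiver], , drop = FALSE]
      if (nrow(deliv) > 0L) {
        m <- match(deliv$receiver, und)
        add <- tapply(deliv$amount, m, sum)
        ksum[as.integer(names(add))] <- add
        contrib <- deliv
      }
      pending <- list()
    }
    y_new <- y_pre + ksum
    crossed <- which(y_new >= z | y_new <= -z)
    new_deciders <- integer(0)
    for (ii in crossed) {
      i <- und[ii]
      o <- if (y_new[ii] >= z) 1 else -1
      spont <- (y_pre[ii] >= z) || (y_pre[ii] <= -z)
      decided[i] <- TRUE
      opt[i] <- o
      dtime[i] <- t_now
      if (spont || is.null(contrib)) {
        cause[i] <- "spontaneous"
      } else {
        ci <- contrib[contrib$receiver == i, , drop = FALSE]
        helpful <- ci[sign(ci$amount) == o, , drop = FALSE]
        if (nrow(helpful) == 0L) {
          cause[i] <- "spontaneous"
        } else {
          ord <- order(-abs(helpful$amount), dtime[helpful$sender],
                       helpful$sender)
          cause[i] <- "kick"
          parent[i] <- helpful$sender[ord[1L]]
        }
      }
      new_deciders <- c(new_deciders, i)
    }
    y[und] <- y_new
    if (config$kicks_enabled && length(new_deciders) > 0L) {
      for (i in new_deciders) {
        nb <- which(tp$adjacency[i, ] > 0)
        nb <- nb[!decided[nb]]
        if (length(nb) > 0L) {
          k <- kick_lookup(dtime[i]) + opt[i] * prior_term
          pending[[length(pending) + 1L]] <- data.frame(
            receiver = nb, sender = i, amount = opt[i] * k
          )
        }
      }
    }
  }
  dec <- which(decided)
  ord <- dec[order(dtime[dec], dec)]
  events <- data.frame(
    agent = ord, time = dtime[ord], option = opt[ord], cause = cause[ord],
    parent = parent[ord]
  )
  structure(
    list(events = events, decided = decided, option = opt, time = dtime,
         undecided = which(!decided), drifts = drifts, z = z,
         horizon = n_steps * dt, true_state = config$true_state,
         kicks_enabled = config$kicks_enabled),
    class = "seq_run_result"
  )
}

#' @export
print.seq_run_result <- function(x, ...) {
  cat(sprintf(
    "<seq_run_result> %d/%d decided (%d correct), %d kick-caused\n",
    sum(x$decided), length(x$decided),
    sum(x$option == x$true_state, na.rm = TRUE),
    sum(x$events$cause == "kick")
  ))
  invisible(x)
}

#' Detect decision cascades in an event log
#'
#' Builds the causal forest implied by the event log: every kick-caused
#' decision is a child of its causing neighbour's decision, every spontaneous
#' decision is a root. A cascade is a root together with all of its causal
#' descendants; records of at least `min_size` members (the trigger counts
#' toward the size) are returned.
#'
#' @param events Event log from [run_asynchronous()].
#' @param min_size Minimum member count; the conventional choice is one tenth
#'   of the group size, `ceiling(n / 10)`.
#' @return A list of cascade records, each with `trigger`, `members` (agent
#'   indices in decision-time order, trigger first) and `size`.
#' @export
detect_cascades <- function(events, min_size = 1L) {
  if (nrow(events) == 0L) return(list())
  kicked <- events$cause == "kick"
  bad <- kicked & (is.na(events$parent) |
                     !(events$parent %in% events$agent))
  if (any(bad)) {
    stop("event log has kick-caused decisions with dangling parents")
  }
  children <- split(events$agent[kicked], events$parent[kicked])
  descend <- function(root) {
    members <- integer(0)
    frontier <- root
    while (length(frontier) > 0L) {
      members <- c(members, frontier)
      frontier <- unlist(children[as.character(frontier)], use.names = FALSE)
    }
    members
  }
  roots <- events$agent[!kicked]
  out <- lapply(roots, function(r) {
    m <- descend(r)
    # decision-time order, trigger first
    m <- m[order(match(m, events$agent))]
    list(trigger = r, members = m, size = length(m))
  })
  Filter(function(rec) rec$size >= min_size, out)
}

#' Leader statistics across runs
#'
#' Within each run, agents are ranked by decreasing drift-to-noise ratio
#' (rank 1 = best informed). Per-rank trigger counts tally cascades of at
#' least `min_size` members, while the size distribution covers every causal
#' tree (each spontaneous decision and its descendants, down to singletons),
#' so it resolves the contrast between ranks that spark group-wide cascades
#' and ranks whose decisions go unheeded — the signature of emergent
#' leadership in heterogeneous groups.
#'
#' @param runs List of `seq_run_result` objects.
#' @param min_size Minimum cascade size for the trigger counts (default
#'   `ceiling(n / 10)`).
#' @return A list with `trigger_counts` (per-rank totals over cascades of at
#'   least `min_size`), `sizes` (data frame `rank`, `size`,
#'   `trigger_correct`, one row per cascade of at least `min_size`),
#'   `sizes_all` (same, over all causal trees) and `n`.
#' @export
influence_stats <- function(runs, min_size = NULL) {
  stopifnot(length(runs) > 0L)
  n <- length(runs[[1L]]$decided)
  if (is.null(min_size)) min_size <- ceiling(n / 10)
  counts <- integer(n)
  rows <- list()
  for (run in runs) {
    if (length(run$decided) != n) stop("runs have inconsistent group sizes")
    rank_of <- integer(n)
    rank_of[order(-abs(run$drifts), seq_len(n))] <- seq_len(n)
    for (rec in detect_cascades(run$events, 1L)) {
      rows[[length(rows) + 1L]] <- data.frame(
        rank = rank_of[rec$trigger], size = rec$size,
        trigger_correct = run$option[rec$trigger] == run$true_state
      )
    }
  }
  sizes_all <- if (length(rows) > 0L) {
    do.call(rbind, rows)
  } else {
    data.frame(rank = integer(0), size = integer(0),
               trigger_correct = logical(0))
  }
  sizes <- sizes_all[sizes_all$size >= min_size, , drop = FALSE]
  for (rec in seq_len(nrow(sizes))) {
    counts[sizes$rank[rec]] <- counts[sizes$rank[rec]] + 1L
  }
  list(trigger_counts = counts, sizes = sizes, sizes_all = sizes_all, n = n)
}

#' Realized Bayes-risk cost of a run
#'
#' Per decided agent: `omega_t * decision time` plus `omega_e` if the option
#' disagrees with the true state. Agents undecided at the horizon are charged
#' `omega_t * horizon` when `charge_undecided` (they paid for the time and
#' avoided the error cost); otherwise they are dropped.
#'
#' @param result A `seq_run_result`.
#' @param cost A [cost_spec()].
#' @param true_state True world state (defaults to the run's).
#' @param charge_undecided Include undecided agents at horizon time cost.
#' @return Mean per-agent realized cost.
#' @export
bayes_risk_cost <- function(result, cost, true_state = result$true_state,
                            charge_undecided = TRUE) {
  stopifnot(inherits(result, "seq_run_result"), inherits(cost, "cost_spec"))
  dec <- result$decided
  costs <- cost$omega_t * result$time[dec] +
    cost$omega_e * (result$option[dec] != true_state)
  if (charge_undecided && any(!dec)) {
    costs <- c(costs, rep(cost$omega_t * result$horizon, sum(!dec)))
  }
  mean(costs)
}
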