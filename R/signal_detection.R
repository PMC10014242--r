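#' Log-odds confidence and its inverse
#'
#' An agent with accuracy `alpha` (probability of classifying the binary
#' world state correctly) holds confidence `ln(alpha / (1 - alpha))`, the
#' log-odds of being right. The inverse maps any signed log-odds evidence
#' back to a probability through the logistic function.
#'
#' @param alpha Accuracy in (0, 1).
#' @param c Log-odds confidence (any real value).
#' @return `confidence_from_accuracy()` returns the log-odds;
#'   `accuracy_from_confidence()` the probability in (0, 1).
#' @examples
#' confidence_from_accuracy(0.75)  # log(3)
#' accuracy_from_confidence(log(3))
#' @export
confidence_from_accuracy <- function(alpha) {
  if (any(alpha <= 0 | alpha >= 1)) stop("`alpha` must lie in (0, 1)")
  stats::qlogis(alpha)
}

#' @rdname confidence_from_accuracy
#' @export
accuracy_from_confidence <- function(c) {
  stats::plogis(c)
}

#' Prior log-odds in favour of an opinion
#'
#' @param p_plus Prior probability of the positive world state, in (0, 1).
#' @param opinion +1 or -1.
#' @return `ln(p_plus / (1 - p_plus))` for opinion +1, its negative for -1.
#' @export
prior_log_odds <- function(p_plus, opinion = 1) {
  if (any(p_plus <= 0 | p_plus >= 1)) stop("`p_plus` must lie in (0, 1)")
  if (any(abs(opinion) != 1)) stop("`opinion` must be +1 or -1")
  opinion * stats::qlogis(p_plus)
}

#' Agent population state for the synchronous scenario
#'
#' @param opinions Vector of +1/-1 opinions.
#' @param confidences Vector of non-negative log-odds confidences.
#' @param t Iteration counter.
#' @return An object of class `sd_population` with elements `opinions`,
#'   `confidences`, `t`, and the signed evidence `y = opinions * confidences`.
#' @export
sd_population <- function(opinions, confidences, t = 0L) {
  if (length(opinions) != length(confidences)) stop("length mismatch")
  if (any(abs(opinions) != 1)) stop("opinions must be +1 or -1")
  if (any(confidences < 0) || any(!is.finite(confidences))) {
    stop("confidences must be finite and non-negative")
  }
  structure(
    list(
      opinions = as.numeric(opinions),
      confidences = as.numeric(confidences),
      y = as.numeric(opinions * confidences),
      t = t
    ),
    class = "sd_population"
  )
}

#' @export
print.sd_population <- function(x, ...) {
  cat(sprintf(
    "<sd_population> n=%d, t=%d, +1 votes: %d, mean confidence %.3f\n",
    length(x$opinions), x$t, sum(x$opinions > 0), mean(x$confidences)
  ))
  invisible(x)
}

#' Sample individual accuracies
#'
#' Draws from Normal(`mu_alpha`, `sigma_alpha`), flips draws below 1/2 to
#' `1 - value` (so heterogeneity raises mean accuracy, a folded normal above
#' 1/2), and clamps into `(0.5, 1 - 1e-6)` so the log-odds stay finite.
#'
#' @param mu_alpha Mean of the underlying normal (1/2 in the standard
#'   experiment design, so all skill comes from `sigma_alpha`).
#' @param sigma_alpha Heterogeneity (standard deviation, >= 0).
#' @param n Number of agents.
#' @param seed Integer seed.
#' @return Numeric vector of accuracies in `[0.5, 1)`.
#' @export
sample_accuracies <- function(mu_alpha, sigma_alpha, n, seed = NULL) {
  stopifnot(n >= 1, sigma_alpha >= 0)
  if (!is.null(seed)) set.seed(seed)
  a <- stats::rnorm(n, mu_alpha, sigma_alpha)
  a <- ifelse(a < 0.5, 1 - a, a)
  pmin(pmax(a, 0.5), 1 - 1e-6)
}

resolve_signs <- function(s, previous) {
  out <- sign(s)
  ties <- out == 0
  if (any(ties)) out[ties] <- previous[ties]
  out
}

check_pop_topology <- function(pop, tp) {
  stopifnot(inherits(pop, "sd_population"), inherits(tp, "topology"))
  if (length(pop$opinions) != tp$n) stop("population size does not match topology")
  if (any(!is.finite(pop$y))) stop("non-finite evidence; renormalize before stepping")
}

#' Weighted Bayes Consensus update (one synchronous step)
#'
#' Every agent simultaneously pools its own signed evidence with its
#' neighbours' pre-update signed evidence, `s_i = y_i + sum_{j in M_i} y_j`,
#' adds the prior log-odds, and adopts the sign as its new opinion (ties keep
#' the previous opinion) and the magnitude as its new confidence. The update
#' is the exact naive-Bayes posterior: the new signed evidence equals the
#' posterior log-odds of the positive state given the local votes, so
#' `plogis(y_i')` recovers [direct_bayes_posterior()]. With a flat prior the
#' prior term vanishes and the rule is pure confidence-weighted summation.
#'
#' @param pop An [sd_population()].
#' @param tp A [topology()] of matching size.
#' @param p_plus Prior probability of the positive state.
#' @return The updated [sd_population()].
#' @export
wbc_step <- function(pop, tp, p_plus = 0.5) {
  check_pop_topology(pop, tp)
  s <- drop((diag(tp$n) + tp$adjacency) %*% pop$y)
  lam <- s + prior_log_odds(p_plus, 1)
  x_new <- resolve_signs(lam, pop$opinions)
  sd_population(x_new, abs(lam), pop$t + 1L)
}

#' Exact naive-Bayes posterior over the world state
#'
#' Independent test oracle for the pooling rule: converts each vote's
#' confidence to an accuracy through the logistic, multiplies the per-vote
#' likelihood terms, applies Bayes' rule with the prior and normalizes over
#' the two candidate states. Computed in log space.
#'
#' @param opinions Vector of +1/-1 votes.
#' @param confidences Vector of non-negative confidences (one per vote).
#' @param p_plus Prior probability of the positive state.
#' @param candidate Candidate state, +1 or -1.
#' @return Posterior probability that the world state equals `candidate`.
#' @examples
#' direct_bayes_posterior(c(1, -1), c(2, 2), 0.5, 1)  # symmetric: 0.5
#' @export
direct_bayes_posterior <- function(opinions, confidences, p_plus = 0.5,
                                   candidate = 1) {
  stopifnot(length(opinions) == length(confidences), abs(candidate) == 1)
  if (any(confidences < 0)) stop("confidences must be non-negative")
  alpha <- stats::plogis(confidences)
  loglik <- function(state) {
    sum(ifelse(opinions == state, log(alpha), log1p(-alpha)))
  }
  prior <- c(`1` = p_plus, `-1` = 1 - p_plus)
  lp <- c(loglik(1) + log(prior[["1"]]), loglik(-1) + log(prior[["-1"]]))
  post <- exp(lp - max(lp))
  post <- post / sum(post)
  if (candidate == 1) post[1L] else post[2L]
}

check_epsilon <- function(tp, epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
    stop("`epsilon` must be a positive scalar")
  }
  if (1 - epsilon * max(degrees(tp)) < 0) {
    stop("`epsilon` too large: I - epsilon * L has a negative diagonal")
  }
}

#' Belief Consensus update (distributed averaging, one step)
#'
#' Each agent moves its signed evidence toward its neighbours',
#' `y_i' = y_i + epsilon * sum_{j in M_i} (y_j - y_i)`, i.e.
#' `y' = (I - epsilon L) y`. With `epsilon` at most [safe_epsilon()] the
#' update matrix is doubly stochastic, the total evidence is conserved, and
#' on a connected graph every `y_i` converges to the initial mean.
#'
#' @inheritParams wbc_step
#' @param epsilon Averaging step size; default [safe_epsilon()].
#' @return The updated [sd_population()].
#' @export
belief_consensus_step <- function(pop, tp, epsilon = safe_epsilon(tp)) {
  check_pop_topology(pop, tp)
  check_epsilon(tp, epsilon)
  y_new <- pop$y - epsilon * drop(laplacian(tp) %*% pop$y)
  x_new <- resolve_signs(y_new, pop$opinions)
  sd_population(x_new, abs(y_new), pop$t + 1L)
}

#' Destabilized averaging update
#'
#' Adds a tunable unstable mode to Belief Consensus:
#' `y' = (epsilon_destab * I + F) y` with `F = I - epsilon_avg * L` doubly
#' stochastic. The dominant eigenvalue is `1 + epsilon_destab` with the ones
#' vector as eigenvector, so the growing mode carries the average of the
#' initial evidence and all signs converge to the sign of that average —
#' fast decisions without sacrificing the averaging statistic.
#'
#' @inheritParams wbc_step
#' @param epsilon_destab Instability gain (>= 0; 0 reduces to
#'   [belief_consensus_step()]).
#' @param epsilon_avg Averaging step size; default [safe_epsilon()].
#' @return The updated [sd_population()].
#' @export
destabilized_consensus_step <- function(pop, tp, epsilon_destab,
                                        epsilon_avg = safe_epsilon(tp)) {
  check_pop_topology(pop, tp)
  check_epsilon(tp, epsilon_avg)
  if (epsilon_destab < 0) stop("`epsilon_destab` must be non-negative")
  y_new <- (1 + epsilon_destab) * pop$y -
    epsilon_avg * drop(laplacian(tp) %*% pop$y)
  x_new <- resolve_signs(y_new, pop$opinions)
  sd_population(x_new, abs(y_new), pop$t + 1L)
}

#' Configuration for a synchronous run
#'
#' @param n Population size.
#' @param algorithm One of `"WBC"` (Weighted Bayes Consensus), `"BC"` (Belief
#'   Consensus) or `"BC-destabilized"`.
#' @param p_plus Prior probability of the positive state.
#' @param true_state True world state, +1 or -1.
#' @param mu_alpha,sigma_alpha Accuracy-distribution parameters
#'   (see [sample_accuracies()]).
#' @param max_iter Iteration cap before a run is declared a timeout.
#' @param epsilon Averaging step for the BC variants (`NULL`: safe uniform
#'   step from the topology).
#' @param epsilon_destab Instability gain for `"BC-destabilized"`.
#' @return An `sd_config` list.
#' @export
sd_config <- function(n = 50L, algorithm = c("WBC", "BC", "BC-destabilized"),
                      p_plus = 0.5, true_state = 1, mu_alpha = 0.5,
                      sigma_alpha = 0.3, max_iter = 1000L, epsilon = NULL,
                      epsilon_destab = 0.1) {
  algorithm <- match.arg(algorithm)
  stopifnot(n >= 1, p_plus > 0, p_plus < 1, abs(true_state) == 1,
            max_iter >= 1, sigma_alpha >= 0)
  structure(
    list(n = as.integer(n), algorithm = algorithm, p_plus = p_plus,
         true_state = true_state, mu_alpha = mu_alpha,
         sigma_alpha = sigma_alpha, max_iter = as.integer(max_iter),
         epsilon = epsilon, epsilon_destab = epsilon_destab),
    class = "sd_config"
  )
}

#' Initialize a population from sampled accuracies
#'
#' Each agent independently guesses the true state with probability equal to
#' its accuracy, and sets its confidence to the log-odds of that accuracy.
#'
#' @param accuracies Vector of accuracies in (1/2, 1).
#' @param true_state True world state, +1 or -1.
#' @return An [sd_population()] at `t = 0`.
#' @export
init_sd_population <- function(accuracies, true_state) {
  correct <- stats::runif(length(accuracies)) < accuracies
  opinions <- ifelse(correct, true_state, -true_state)
  sd_population(opinions, confidence_from_accuracy(accuracies), 0L)
}

# Rescale evidence when the unstable summation overflows; the update is
# linear so a uniform positive rescaling never changes any future sign.
WBC_RENORM_CAP <- 1e100

#' Run the synchronous scenario to consensus
#'
#' Draws accuracies and initial opinions, then iterates the configured update
#' rule until all opinions agree or `max_iter` is reached. For the unstable
#' Weighted Bayes Consensus rule the evidence vector is uniformly rescaled
#' whenever its largest magnitude exceeds 1e100; the rescaling preserves the
#' whole sign trajectory and the cumulative factor is recorded.
#'
#' @param config An [sd_config()].
#' @param tp A [topology()] with `config$n` nodes.
#' @param seed Integer seed (accuracies and initial opinions).
#' @return A list of class `sd_run_result`: `outcome` (one of
#'   `"unanimous-correct"`, `"unanimous-wrong"`, `"timeout"`),
#'   `consensus_time`, `plus_counts` (number of +1 opinions per iteration,
#'   starting at t = 0), `final_y` (signed evidence, renormalized scale),
#'   `accuracies`, and `log_scale` (log of the cumulative renormalization).
#' @export
run_synchronous <- function(config, tp, seed = NULL) {
  stopifnot(inherits(config, "sd_config"), inherits(tp, "topology"))
  if (tp$n != config$n) stop("topology size does not match config")
  if (!is.null(seed)) set.seed(seed)
  acc <- sample_accuracies(config$mu_alpha, config$sigma_alpha, config$n)
  pop <- init_sd_population(acc, config$true_state)
  eps <- if (is.null(config$epsilon)) safe_epsilon(tp) else config$epsilon
  step <- switch(config$algorithm,
    "WBC" = function(p) wbc_step(p, tp, config$p_plus),
    "BC" = function(p) belief_consensus_step(p, tp, eps),
    "BC-destabilized" = function(p) {
      destabilized_consensus_step(p, tp, config$epsilon_destab, eps)
    }
  )
  plus_counts <- integer(config$max_iter + 1L)
  plus_counts[1L] <- sum(pop$opinions > 0)
  log_scale <- 0
  outcome <- "timeout"
  consensus_time <- NA_integer_
  if (length(unique(pop$opinions)) == 1L) {
    outcome <- if (pop$opinions[1L] == config$true_state) {
      "unanimous-correct"
    } else {
      "unanimous-wrong"
    }
    consensus_time <- 0L
    plus_counts <- plus_counts[1L]
  } else {
    for (t in seq_len(config$max_iter)) {
      pop <- step(pop)
      m <- max(pop$confidences)
      if (m > WBC_RENORM_CAP) {
        pop <- sd_population(pop$opinions, pop$confidences / m, pop$t)
        log_scale <- log_scale + log(m)
      }
      plus_counts[t + 1L] <- sum(pop$opinions > 0)
      if (length(unique(pop$opinions)) == 1L) {
        outcome <- if (pop$opinions[1L] == config$true_state) {
          "unanimous-correct"
        } else {
          "unanimous-wrong"
        }
        consensus_time <- t
        plus_counts <- plus_counts[seq_len(t + 1L)]
        break
      }
    }
  }
  structure(
    list(outcome = outcome, consensus_time = consensus_time,
         plus_counts = plus_counts, final_y = pop$y, accuracies = acc,
         log_scale = log_scale, algorithm = config$algorithm),
    class = "sd_run_result"
  )
}

#' @export
print.sd_run_result <- function(x, ...) {
  cat(sprintf("<sd_run_result> %s: %s at t=%s\n", x$algorithm, x$outcome,
              ifelse(is.na(x$consensus_time), "-", x$consensus_time)))
  invisible(x)
}
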