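#' Drift-diffusion specification
#'
#' Evidence `y(t)` evolves as a biased Brownian motion `dy = A dt + sigma dW`
#' from `y(0) = 0` until it reaches the upper threshold `z_plus > 0` or the
#' lower threshold `z_minus < 0`; the sign of the crossed threshold is the
#' decision. The analytic first-passage machinery covers the symmetric case
#' `z_minus = -z_plus`; asymmetric thresholds are served by the Monte Carlo
#' simulator only.
#'
#' @param drift Drift rate A (signed; evidence units per time).
#' @param sigma Diffusion noise (> 0; evidence units per sqrt time).
#' @param z_plus Upper threshold (> 0).
#' @param z_minus Lower threshold (< 0; default `-z_plus`).
#' @return An object of class `ddm_spec`.
#' @export
ddm_spec <- function(drift, sigma = 1, z_plus = 1, z_minus = -z_plus) {
  stopifnot(sigma > 0, z_plus > 0, z_minus < 0)
  structure(list(drift = drift, sigma = sigma, z_plus = z_plus,
                 z_minus = z_minus),
            class = "ddm_spec")
}

is_symmetric <- function(spec) {
  isTRUE(all.equal(spec$z_minus, -spec$z_plus))
}

require_symmetric <- function(spec, what) {
  if (!is_symmetric(spec)) {
    stop(sprintf(
      "%s: the analytic expression assumes symmetric thresholds (z- = -z+); use simulate_ddm() for asymmetric thresholds",
      what
    ))
  }
}

#' Population drift prior
#'
#' Drift magnitudes are distributed as the fold |Normal(mu, sigma)| on
#' (0, Inf); the sign of every realized drift equals the true world state
#' (no systematically misinformed agents). Marginals over this prior are
#' computed as expectations over the underlying standard normal, which stays
#' well conditioned down to the point-mass limit `sigma = 0`.
#'
#' @param mu Mean of the underlying normal (drift magnitude scale).
#' @param sigma Spread (>= 0).
#' @return An object of class `drift_prior`.
#' @export
drift_prior <- function(mu, sigma) {
  stopifnot(sigma >= 0)
  structure(list(mu = mu, sigma = sigma), class = "drift_prior")
}

#' Decision cost specification
#'
#' @param omega_t Cost per unit decision time (> 0).
#' @param omega_e Cost of an erroneous decision (> 0).
#' @param p_plus Prior probability of the positive world state.
#' @return An object of class `cost_spec`.
#' @export
cost_spec <- function(omega_t = 1, omega_e = 100, p_plus = 0.5) {
  stopifnot(omega_t > 0, omega_e > 0, p_plus > 0, p_plus < 1)
  structure(list(omega_t = omega_t, omega_e = omega_e, p_plus = p_plus),
            class = "cost_spec")
}

#' Sample signed drifts for a population
#'
#' @param prior A [drift_prior()].
#' @param true_state +1 or -1; every drift carries this sign.
#' @param n Number of agents.
#' @param seed Integer seed.
#' @return Numeric vector of signed drifts.
#' @export
sample_drifts <- function(prior, true_state, n, seed = NULL) {
  stopifnot(inherits(prior, "drift_prior"), abs(true_state) == 1, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  true_state * abs(stats::rnorm(n, prior$mu, prior$sigma))
}

#' Image-sum kernel of the two-boundary first-passage density
#'
#' Evaluates `theta(t, u, v) = sum_k (v - u + 2kv) / sqrt(2 pi t^3) *
#' exp(-(v - u + 2kv)^2 / (2t))`, the method-of-images series for a unit
#' Wiener process started at `u` between absorbing boundaries 0 and `v`.
#' Terms are added outward from `k = 0` (pairing `k` with `-k`) until two
#' consecutive pairs fall below `tol`; the tail decays super-exponentially.
#'
#' @param t Time (> 0); vectorized.
#' @param u Scaled start distance from the lower boundary.
#' @param v Scaled boundary gap (> 0).
#' @param tol Truncation tolerance on individual terms.
#' @return The truncated series value for each `t`.
#' @export
theta_series <- function(t, u, v, tol = 1e-12) {
  if (any(t <= 0)) stop("`t` must be positive")
  stopifnot(v > 0, tol > 0)
  vapply(t, function(tt) {
    pref <- 1 / sqrt(2 * pi * tt^3)
    term <- function(k) {
      d <- v - u + 2 * k * v
      d * pref * exp(-d^2 / (2 * tt))
    }
    s <- term(0)
    below <- 0L
    k <- 1L
    repeat {
      a <- term(k)
      b <- term(-k)
      s <- s + a + b
      if (abs(a) < tol && abs(b) < tol) below <- below + 1L else below <- 0L
      if (below >= 2L || k > 1000L) break
      k <- k + 1L
    }
    s
  }, numeric(1))
}

#' First-passage-time density of the decision time
#'
#' Density over time of the first boundary crossing, conditioned on which
#' boundary is hit first. For symmetric thresholds and an unbiased start the
#' conditional decision-time density is the same at both boundaries (the
#' expression is even in the drift), a classical property of the symmetric
#' drift-diffusion model; the density integrates to one.
#'
#' @param t Time (> 0); vectorized.
#' @param spec A [ddm_spec()] with symmetric thresholds.
#' @param which `"plus"` or `"minus"`: which threshold is hit first.
#' @return Conditional density values.
#' @examples
#' integrate(fpt_density, 0, Inf, spec = ddm_spec(0.2, 1, 2))$value  # ~1
#' @export
fpt_density <- function(t, spec, which = c("plus", "minus")) {
  stopifnot(inherits(spec, "ddm_spec"))
  which <- match.arg(which)
  require_symmetric(spec, "fpt_density")
  if (any(t <= 0)) stop("`t` must be positive")
  A <- if (which == "plus") spec$drift else -spec$drift
  z <- spec$z_plus
  sig <- spec$sigma
  exp(-A^2 * t / (2 * sig^2) - A * z / sig^2) *
    (1 + exp(2 * A * z / sig^2)) *
    theta_series(t, z / sig, 2 * z / sig)
}

#' Probability of deciding at the upper threshold
#'
#' Closed form for symmetric thresholds:
#' `P(hit z+ first) = 1 - 1 / (exp(2 A z+ / sigma^2) + 1)`.
#'
#' @param spec A [ddm_spec()] with symmetric thresholds.
#' @return Probability of reaching `z_plus` before `z_minus`.
#' @export
hit_probability <- function(spec) {
  stopifnot(inherits(spec, "ddm_spec"))
  require_symmetric(spec, "hit_probability")
  1 - 1 / (exp(2 * spec$drift * spec$z_plus / spec$sigma^2) + 1)
}

#' Expected decision time and error probability at a given drift magnitude
#'
#' Standard closed forms for the symmetric drift-diffusion model:
#' `E[T] = (z / A) tanh(A z / sigma^2)` (continuous limit `z^2 / sigma^2` at
#' `A = 0`) and `P(error) = 1 / (1 + exp(2 A z / sigma^2))`. Expected time is
#' decreasing in the drift magnitude: stronger evidence reaches the boundary
#' sooner.
#'
#' @param a_mag Drift magnitude (>= 0); vectorized.
#' @param z Threshold magnitude (> 0).
#' @param sigma Diffusion noise.
#' @return Expected decision time / error probability.
#' @export
expected_decision_time <- function(a_mag, z, sigma = 1) {
  ifelse(a_mag < 1e-10, z^2 / sigma^2,
         (z / a_mag) * tanh(a_mag * z / sigma^2))
}

#' @rdname expected_decision_time
#' @export
error_probability <- function(a_mag, z, sigma = 1) {
  1 / (1 + exp(2 * a_mag * z / sigma^2))
}

# Expectation of g(|A|) over the folded drift prior, as an integral over the
# underlying standard normal; exact point evaluation when sigma = 0.
fold_expect <- function(g, prior, rel.tol = 1e-8) {
  if (prior$sigma == 0) return(g(abs(prior$mu)))
  stats::integrate(
    function(u) {
      vapply(u, function(uu) g(abs(prior$mu + prior$sigma * uu)),
             numeric(1)) * stats::dnorm(u)
    },
    lower = -8, upper = 8, rel.tol = rel.tol
  )$value
}

#' Expected Bayes risk of a symmetric threshold
#'
#' `BR(z) = omega_t * E[T(z)] + omega_e * P(error; z)`, with expected time and
#' error probability marginalized over the folded drift prior by quadrature.
#'
#' @param z Threshold magnitude (> 0); vectorized.
#' @param cost A [cost_spec()].
#' @param prior A [drift_prior()].
#' @param sigma Diffusion noise.
#' @param marginalize If `FALSE`, evaluate at the prior mean magnitude only
#'   instead of integrating over the prior.
#' @return Expected cost for each `z`.
#' @export
bayes_risk <- function(z, cost, prior, sigma = 1, marginalize = TRUE) {
  stopifnot(inherits(cost, "cost_spec"), inherits(prior, "drift_prior"))
  pr <- if (marginalize) prior else drift_prior(prior$mu, 0)
  vapply(z, function(zz) {
    fold_expect(function(a) {
      cost$omega_t * expected_decision_time(a, zz, sigma) +
        cost$omega_e * error_probability(a, zz, sigma)
    }, pr)
  }, numeric(1))
}

#' Bayes-risk-optimal symmetric threshold
#'
#' Minimizes [bayes_risk()] over `z` in `(0, z_max]` by golden-section search
#' seeded from a coarse bracketing grid (the risk is smooth with a single
#' interior minimum for positive costs: vanishing thresholds pay full error
#' cost, huge ones pay unbounded time cost).
#'
#' @inheritParams bayes_risk
#' @param z_max Upper end of the search interval.
#' @param grid_n Bracketing grid resolution.
#' @return The optimal threshold magnitude, with the achieved risk attached
#'   as attribute `"risk"`.
#' @examples
#' optimal_threshold(cost_spec(1, 100), drift_prior(0.2, 0.5))
#' @export
optimal_threshold <- function(cost, prior, sigma = 1, z_max = 20,
                              marginalize = TRUE, grid_n = 60L) {
  zs <- seq(z_max / grid_n, z_max, length.out = grid_n)
  br <- bayes_risk(zs, cost, prior, sigma, marginalize)
  i <- which.min(br)
  if (i == grid_n) {
    stop(paste0(
      "no interior Bayes-risk minimum in (0, z_max]; grid risks: ",
      paste(sprintf("%.3g", br), collapse = " ")
    ))
  }
  lo <- if (i == 1L) 1e-6 else zs[i - 1L]
  hi <- zs[i + 1L]
  opt <- stats::optimize(
    function(z) bayes_risk(z, cost, prior, sigma, marginalize),
    interval = c(lo, hi), tol = 1e-6
  )
  structure(opt$minimum, risk = opt$objective)
}

#' Confidence-calibrated kick size from a neighbour's decision
#'
#' The evidence increment an undecided accumulator assigns to a neighbour's
#' announced decision, given only the decision time `t` and chosen option:
#' the log-odds of the option's state versus its alternative, obtained by
#' marginalizing the first-passage-time density and the threshold-hit
#' probability over the drift prior (the receiver knows the population drift
#' distribution, not the sender's drift), plus the world-prior log-odds.
#' Early decisions indicate a high drift-to-noise ratio and earn large
#' kicks; with a point-mass prior (`sigma = 0` in the prior) the
#' time-dependent term cancels, since the symmetric-threshold decision-time
#' density is the same for correct and error decisions at a known drift.
#'
#' The returned value is the log-odds in favour of the neighbour's option, so
#' the world-frame evidence increment is `option * kick_size(...)`.
#'
#' @param t Decision time of the neighbour (> 0); vectorized.
#' @param option The neighbour's decision, +1 or -1.
#' @param prior A [drift_prior()].
#' @param sigma Diffusion noise.
#' @param z Threshold magnitude shared by the population.
#' @param p_plus Prior probability of the positive world state.
#' @return Signed log-odds evidence increment(s) toward the option.
#' @export
kick_size <- function(t, option, prior, sigma = 1, z, p_plus = 0.5) {
  stopifnot(inherits(prior, "drift_prior"), abs(option) == 1, z > 0)
  if (any(t <= 0)) stop("`t` must be positive")
  dens <- function(tt, a) {
    exp(-a^2 * tt / (2 * sigma^2) - a * z / sigma^2) *
      (1 + exp(2 * a * z / sigma^2)) *
      theta_series(tt, z / sigma, 2 * z / sigma)
  }
  phit <- function(a) 1 - 1 / (exp(2 * a * z / sigma^2) + 1)
  vapply(t, function(tt) {
    num <- fold_expect(function(a) dens(tt, a) * phit(a), prior)
    den <- fold_expect(function(a) dens(tt, a) * phit(-a), prior)
    if (!is.finite(num) || !is.finite(den) || den <= 0 || num <= 0) {
      stop(sprintf(
        "kick quadrature failed at t=%g (numerator %g, denominator %g)",
        tt, num, den
      ))
    }
    log(num / den) + prior_log_odds(p_plus, option)
  }, numeric(1))
}

#' Monte Carlo path simulation of a single accumulator
#'
#' Euler-Maruyama discretization `y <- y + A dt + sigma sqrt(dt) xi` stepped
#' until a threshold is crossed. Crossings are detected at step boundaries
#' and, between boundaries, by the Brownian-bridge crossing probability
#' `exp(-2 (z - y_old)(z - y_new) / (sigma^2 dt))`, which removes the
#' leading-order late bias of purely discrete detection. External evidence
#' kicks can be injected at given times, each applied at the first step
#' boundary at or after its timestamp. This simulator is the oracle for the
#' analytic first-passage machinery and the only route for asymmetric
#' thresholds.
#'
#' @param spec A [ddm_spec()].
#' @param dt Time step (> 0).
#' @param seed Integer seed.
#' @param kicks Optional data frame with columns `time` and `increment`.
#' @param max_time Hard cap on simulated time; exceeding it is an error.
#' @return A list with `decision` (+1/-1) and `time` (a multiple of `dt`).
#' @export
simulate_ddm <- function(spec, dt = 1e-3, seed = NULL, kicks = NULL,
                         max_time = 1e5) {
  stopifnot(inherits(spec, "ddm_spec"), dt > 0)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(kicks)) {
    stopifnot(all(c("time", "increment") %in% names(kicks)))
    kicks <- kicks[order(kicks$time), , drop = FALSE]
    kick_step <- pmax(1L, as.integer(ceiling(kicks$time / dt - 1e-9)))
  }
  y <- 0
  step <- 0L
  chunk <- 1000L
  s2dt <- spec$sigma^2 * dt
  repeat {
    xi <- stats::rnorm(chunk)
    incr <- spec$drift * dt + spec$sigma * sqrt(dt) * xi
    u <- stats::runif(chunk)
    for (j in seq_len(chunk)) {
      step <- step + 1L
      y_old <- y
      y <- y + incr[j]
      kicked <- FALSE
      if (!is.null(kicks)) {
        hit <- which(kick_step == step)
        if (length(hit) > 0L) {
          y <- y + sum(kicks$increment[hit])
          kicked <- TRUE
        }
      }
      if (y >= spec$z_plus) {
        return(list(decision = 1, time = step * dt))
      }
      if (y <= spec$z_minus) {
        return(list(decision = -1, time = step * dt))
      }
      if (!kicked) {
        # bridge correction for crossings between step boundaries
        p_up <- exp(-2 * (spec$z_plus - y_old) * (spec$z_plus - y) / s2dt)
        p_dn <- exp(-2 * (y_old - spec$z_minus) * (y - spec$z_minus) / s2dt)
        if (u[j] < p_up) {
          return(list(decision = 1, time = step * dt))
        }
        if (u[j] < p_up + p_dn) {
          return(list(decision = -1, time = step * dt))
        }
      }
      if (step * dt > max_time) stop("simulate_ddm: max_time exceeded")
    }
  }
}

#' Vectorized Monte Carlo decision sample
#'
#' Runs `n` independent accumulators in lockstep (vectorized over paths),
#' with the same Brownian-bridge crossing correction as [simulate_ddm()],
#' and returns every path's decision and crossing time. Used for
#' distributional cross-checks against [fpt_density()] and
#' [hit_probability()].
#'
#' @param spec A [ddm_spec()].
#' @param n Number of paths.
#' @param dt Time step.
#' @param seed Integer seed.
#' @param max_time Hard cap on simulated time; exceeding it is an error.
#' @return A data frame with columns `decision` and `time`.
#' @export
simulate_ddm_paths <- function(spec, n, dt = 1e-3, seed = NULL,
                               max_time = 1e4) {
  stopifnot(inherits(spec, "ddm_spec"), n >= 1, dt > 0)
  if (!is.null(seed)) set.seed(seed)
  y <- numeric(n)
  active <- seq_len(n)
  decision <- numeric(n)
  time <- numeric(n)
  sdt <- spec$sigma * sqrt(dt)
  s2dt <- spec$sigma^2 * dt
  step <- 0L
  while (length(active) > 0L) {
    step <- step + 1L
    if (step * dt > max_time) stop("simulate_ddm_paths: max_time exceeded")
    y_old <- y[active]
    y_new <- y_old + spec$drift * dt + sdt * stats::rnorm(length(active))
    y[active] <- y_new
    hit_up <- y_new >= spec$z_plus
    hit_dn <- y_new <= spec$z_minus
    open <- !hit_up & !hit_dn
    if (any(open)) {
      # bridge correction for crossings between step boundaries
      p_up <- exp(-2 * (spec$z_plus - y_old[open]) *
                    (spec$z_plus - y_new[open]) / s2dt)
      p_dn <- exp(-2 * (y_old[open] - spec$z_minus) *
                    (y_new[open] - spec$z_minus) / s2dt)
      u <- stats::runif(sum(open))
      hit_up[open] <- u < p_up
      hit_dn[open] <- !hit_up[open] & u < p_up + p_dn
    }
    up <- active[hit_up]
    dn <- active[hit_dn]
    if (length(up) > 0L) {
      decision[up] <- 1
      time[up] <- step * dt
    }
    if (length(dn) > 0L) {
      decision[dn] <- -1
      time[dn] <- step * dt
    }
    if (length(up) + length(dn) > 0L) {
      active <- setdiff(active, c(up, dn))
    }
  }
  data.frame(decision = decision, time = time)
}
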