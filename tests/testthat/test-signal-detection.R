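test_that("confidence and accuracy transforms are exact inverses", {
  expect_equal(confidence_from_accuracy(0.5), 0)
  expect_equal(confidence_from_accuracy(0.75), log(3), tolerance = 1e-12)
  expect_equal(accuracy_from_confidence(0), 0.5)
  expect_equal(accuracy_from_confidence(log(3)), 0.75, tolerance = 1e-12)
  alphas <- seq(0.01, 0.99, by = 0.01)
  expect_equal(accuracy_from_confidence(confidence_from_accuracy(alphas)),
               alphas, tolerance = 1e-12)
  # monotone, saturating
  expect_true(all(diff(confidence_from_accuracy(alphas)) > 0))
  expect_lt(accuracy_from_confidence(30), 1)
  expect_lte(accuracy_from_confidence(1000), 1)  # saturates without overflow
  expect_error(confidence_from_accuracy(1), "0, 1")
  expect_error(confidence_from_accuracy(0), "0, 1")
})

test_that("prior log-odds are antisymmetric in the opinion", {
  expect_equal(prior_log_odds(0.5, 1), 0)
  expect_equal(prior_log_odds(0.5, -1), 0)
  expect_equal(prior_log_odds(0.75, 1), log(3), tolerance = 1e-12)
  for (p in c(0.1, 0.3, 0.8)) {
    expect_equal(prior_log_odds(p, 1), -prior_log_odds(p, -1))
  }
  expect_error(prior_log_odds(0, 1), "0, 1")
  expect_error(prior_log_odds(0.5, 2), "opinion")
})

test_that("wbc_step matches hand computation and leaves isolated agents alone", {
  # star centre x=+1 c=1, neighbours (-1, 2) and (+1, 0.5), flat prior:
  # s = 1 - 2 + 0.5 = -0.5 -> opinion -1, confidence 0.5
  pop <- sd_population(c(1, -1, 1), c(1, 2, 0.5))
  new <- wbc_step(pop, make_star(3), 0.5)
  expect_equal(new$opinions[1], -1)
  expect_equal(new$confidences[1], 0.5)
  # the implied posterior equals the exact naive-Bayes oracle
  expect_equal(accuracy_from_confidence(new$confidences[1]),
               direct_bayes_posterior(pop$opinions, pop$confidences, 0.5, -1),
               tolerance = 1e-12)

  # isolated agent with flat prior: nothing changes
  iso <- wbc_step(sd_population(c(1, -1), c(0.7, 1.2)), make_empty(2), 0.5)
  expect_equal(iso$opinions, c(1, -1))
  expect_equal(iso$confidences, c(0.7, 1.2))

  # star centre with k equally confident agreeing neighbours: linear growth
  confs <- vapply(2:6, function(k) {
    p <- sd_population(rep(1, k + 1), rep(1, k + 1))
    wbc_step(p, make_star(k + 1), 0.5)$confidences[1]
  }, numeric(1))
  expect_equal(confs, 1 + (2:6))

  expect_error(wbc_step(sd_population(1, 1), make_star(3)), "size")
})

test_that("wbc_step ties retain the previous opinion", {
  # two agents with exactly opposing evidence: s = 0 for both
  pop <- sd_population(c(1, -1), c(1, 1))
  new <- wbc_step(pop, make_complete(2), 0.5)
  expect_equal(new$opinions, c(1, -1))
  expect_equal(new$confidences, c(0, 0))
})

test_that("pooled update equals the exact naive-Bayes posterior", {
  set.seed(101)
  for (i in 1:300) {
    k <- sample(1:8, 1)
    opinions <- sample(c(-1, 1), k + 1, replace = TRUE)
    confidences <- runif(k + 1, 0, 5)
    p_plus <- runif(1, 0.05, 0.95)
    pop <- sd_population(opinions, confidences)
    new <- wbc_step(pop, make_star(k + 1), p_plus)
    implied <- accuracy_from_confidence(new$y[1])
    oracle <- direct_bayes_posterior(opinions, confidences, p_plus, 1)
    expect_lt(abs(implied - oracle), 1e-10)
  }
})

test_that("direct_bayes_posterior obeys closed-form special cases", {
  # single vote, flat prior: posterior equals the voter's accuracy
  for (cc in c(0.3, 1, 4)) {
    expect_equal(direct_bayes_posterior(1, cc, 0.5, 1),
                 accuracy_from_confidence(cc), tolerance = 1e-12)
  }
  # opposing equal-confidence votes cancel
  expect_equal(direct_bayes_posterior(c(1, -1), c(2, 2), 0.5, 1), 0.5)
  expect_equal(direct_bayes_posterior(c(1, -1), c(2, 2), 0.5, -1), 0.5)
  # posterior log-odds equal sum of signed confidences plus prior log-odds
  set.seed(7)
  for (i in 1:1000) {
    k <- sample(1:9, 1)
    x <- sample(c(-1, 1), k, replace = TRUE)
    cc <- runif(k, 0, 5)
    p <- runif(1, 0.05, 0.95)
    # recover the log-odds from the two normalized posteriors (avoids the
    # catastrophic cancellation of 1 - post near saturation)
    lo <- log(direct_bayes_posterior(x, cc, p, 1)) -
      log(direct_bayes_posterior(x, cc, p, -1))
    expect_lt(abs(lo - (sum(x * cc) + prior_log_odds(p, 1))), 1e-10)
  }
})

test_that("belief consensus conserves and converges to the initial mean", {
  # two connected agents with opposing evidence shrink symmetrically
  pop <- sd_population(c(1, -1), c(3, 3))
  eps <- 0.25
  new <- belief_consensus_step(pop, make_complete(2), eps)
  expect_equal(new$y, c(3 * (1 - 2 * eps), -3 * (1 - 2 * eps)))

  # sum conservation per step, convergence to the mean
  for (seed in 1:20) {
    tp <- random_connected_rgg(20, seed)
    set.seed(seed)
    pop <- sd_population(sample(c(-1, 1), 20, TRUE), runif(20, 0, 3))
    target <- mean(pop$y)
    for (t in 1:5000) {
      new <- belief_consensus_step(pop, tp)
      expect_lt(abs(sum(new$y) - sum(pop$y)), 1e-9)
      pop <- new
      if (max(abs(pop$y - target)) < 1e-6) break
    }
    expect_lt(max(abs(pop$y - target)), 1e-6)
  }

  # complete graph with eps = 1/N averages in a single step
  n <- 6
  set.seed(3)
  pop <- sd_population(sample(c(-1, 1), n, TRUE), runif(n, 0, 2))
  one <- belief_consensus_step(pop, make_complete(n), 1 / n)
  expect_equal(one$y, rep(mean(pop$y), n), tolerance = 1e-12)

  expect_error(belief_consensus_step(pop, make_complete(n), -0.1), "positive")
  expect_error(belief_consensus_step(pop, make_complete(n), 0.5), "negative diagonal")
})

test_that("destabilized consensus grows along the ones vector", {
  # eps_destab = 0 reduces exactly to belief consensus
  tp <- random_connected_rgg(10, 4)
  set.seed(4)
  pop <- sd_population(sample(c(-1, 1), 10, TRUE), runif(10, 0, 2))
  a <- belief_consensus_step(pop, tp)
  b <- destabilized_consensus_step(pop, tp, 0)
  expect_equal(a$y, b$y, tolerance = 1e-14)

  # positive initial mean: all signs eventually +1, on many random graphs
  for (seed in 1:50) {
    tp <- random_connected_rgg(12, 100 + seed)
    set.seed(seed)
    y0 <- rnorm(12)
    y0 <- y0 - mean(y0) + 0.3  # force positive mean
    pop <- sd_population(sign(y0 + (y0 == 0)), abs(y0))
    for (t in 1:400) {
      pop <- destabilized_consensus_step(pop, tp, 0.2)
      if (all(pop$opinions == 1)) break
      if (max(pop$confidences) > 1e80) {
        pop <- sd_population(pop$opinions, pop$confidences / max(pop$confidences))
      }
    }
    expect_true(all(pop$opinions == 1))
  }
})

test_that("accuracy sampler folds below one half and respects its bounds", {
  expect_equal(sample_accuracies(0.5, 0, 10, seed = 1), rep(0.5, 10))
  a <- sample_accuracies(0.5, 0.3, 5000, seed = 2)
  expect_true(all(a >= 0.5 & a < 1))
  # folded-normal mean at mu = 1/2: 1/2 + sigma * sqrt(2/pi)
  expect_equal(mean(a), 0.5 + 0.3 * sqrt(2 / pi), tolerance = 0.02)
  a2 <- sample_accuracies(0.5, 0.1, 5000, seed = 3)
  expect_lt(mean(a2), mean(a))
})

test_that("run_synchronous handles unanimity, timeouts and renormalization", {
  tp <- make_complete(10)
  # accuracies ~ 1: initial unanimity on the true state at t = 0
  cfg <- sd_config(10, "WBC", mu_alpha = 0.9999999, sigma_alpha = 0)
  res <- run_synchronous(cfg, tp, seed = 1)
  expect_equal(res$outcome, "unanimous-correct")
  expect_equal(res$consensus_time, 0L)

  # no edges, mixed initial opinions: WBC cannot reach consensus
  cfg2 <- sd_config(50, "WBC", mu_alpha = 0.5, sigma_alpha = 0.3,
                    max_iter = 50)
  res2 <- run_synchronous(cfg2, make_empty(50), seed = 2)
  expect_equal(res2$outcome, "timeout")
  expect_true(is.na(res2$consensus_time))

  # long unstable run: evidence stays finite thanks to renormalization
  cfg3 <- sd_config(2, "WBC", mu_alpha = 0.5, sigma_alpha = 0.4,
                    max_iter = 500)
  # two agents disagreeing with equal confidence never converge but the
  # trajectory must remain finite
  res3 <- run_synchronous(cfg3, make_complete(2), seed = 11)
  expect_true(all(is.finite(res3$final_y)))
})

test_that("WBC evidence magnitude is unstable but signs match the linear map", {
  # exact linear-map oracle on a 4-node toy graph: iterate (I+A) y directly
  tp <- make_path(4)
  y0 <- c(0.8, -0.3, 0.55, -1.2)
  pop <- sd_population(sign(y0), abs(y0))
  M <- diag(4) + tp$adjacency
  y_exact <- y0
  for (t in 1:10) {
    y_exact <- drop(M %*% y_exact)
    pop <- wbc_step(pop, tp, 0.5)
    expect_equal(pop$y, y_exact, tolerance = 1e-9)
  }
  # norm grows without bound on any graph with an edge
  expect_gt(sqrt(sum(y_exact^2)), sqrt(sum(y0^2)))
  expect_gt(as.numeric(spectral_radius(M)), 1)
})
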