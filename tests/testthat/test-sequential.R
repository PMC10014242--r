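# Hand-built event log helper.
event_log <- function(agent, time, option, cause, parent) {
  data.frame(agent = agent, time = time, option = option, cause = cause,
             parent = parent)
}

test_that("an isolated agent reproduces single-accumulator statistics", {
  cfg <- seq_config(n = 1, prior = drift_prior(0.5, 0), sigma = 1,
                    z = 1, dt = 0.01, max_time = 500)
  tp <- make_empty(1)
  out <- t(vapply(1:400, function(s) {
    r <- run_asynchronous(cfg, tp, seed = s)
    c(r$option[1], r$time[1])
  }, numeric(2)))
  p_an <- hit_probability(ddm_spec(0.5, 1, 1))
  p_hat <- mean(out[, 1] == 1)
  expect_lt(abs(p_hat - p_an), 3 * sqrt(p_an * (1 - p_an) / nrow(out)))
  m_an <- expected_decision_time(0.5, 1, 1)
  expect_lt(abs(mean(out[, 2]) - m_an), 3 * sd(out[, 2]) / sqrt(nrow(out)))
})

test_that("a fast decider's kick arrives one step later and is attributed", {
  # agent 1 has enormous drift and decides almost immediately; the kick is
  # larger than the full threshold gap, so agent 2 must cross at the very
  # next step, kick-caused, same option, parented to agent 1
  prior <- drift_prior(2, 0.5)
  cfg <- seq_config(n = 2, prior = prior, sigma = 1, z = 0.5, dt = 0.01,
                    max_time = 50)
  # kick magnitude at early times exceeds the 2*z = 1 threshold gap
  expect_gt(kick_size(0.02, 1, prior, 1, 0.5), 1)
  for (seed in 1:20) {
    r <- run_asynchronous(cfg, make_complete(2), seed = seed,
                          drifts = c(50, 0))
    e1 <- r$events[r$events$agent == 1, ]
    e2 <- r$events[r$events$agent == 2, ]
    expect_equal(nrow(e2), 1L)
    expect_equal(e1$cause, "spontaneous")
    expect_equal(e1$option, 1)
    if (e2$cause == "kick") {
      expect_equal(e2$parent, 1L)
      expect_equal(e2$time, e1$time + 0.01, tolerance = 1e-9)
      expect_equal(e2$option, 1)
    }
  }
})

test_that("decisions are final and broadcasts reach only undecided neighbours", {
  cfg <- seq_config(n = 30, prior = drift_prior(0.2, 0.5), dt = 0.02)
  tp <- random_connected_rgg(30, 77)
  for (seed in 1:5) {
    r <- run_asynchronous(cfg, tp, seed = seed)
    # no agent decides twice
    expect_equal(anyDuplicated(r$events$agent), 0L)
    # decided/undecided partition the group
    expect_setequal(c(r$events$agent, r$undecided), 1:30)
    # every kick-caused event's parent decided strictly earlier and is a
    # network neighbour
    kicked <- r$events[r$events$cause == "kick", ]
    for (i in seq_len(nrow(kicked))) {
      pt <- r$events$time[r$events$agent == kicked$parent[i]]
      expect_lt(pt, kicked$time[i])
      expect_equal(tp$adjacency[kicked$agent[i], kicked$parent[i]], 1)
    }
  }
})

test_that("cascade detection builds the causal forest correctly", {
  # only spontaneous decisions: no cascade of size >= 2
  log1 <- event_log(1:4, 1:4, 1, "spontaneous", NA)
  recs <- detect_cascades(log1, 2)
  expect_length(recs, 0)
  expect_length(detect_cascades(log1, 1), 4)

  # chain 1 -> 2 -> 3 -> 4 -> 5, each kicked by the previous
  log2 <- event_log(1:5, 1:5, 1, c("spontaneous", rep("kick", 4)),
                    c(NA, 1:4))
  recs2 <- detect_cascades(log2, 5)
  expect_length(recs2, 1)
  expect_equal(recs2[[1]]$trigger, 1)
  expect_equal(recs2[[1]]$size, 5)
  expect_equal(recs2[[1]]$members, 1:5)

  # two trees: root 1 with children 2,3; root 4 with child 5
  log3 <- event_log(1:5, 1:5, 1,
                    c("spontaneous", "kick", "kick", "spontaneous", "kick"),
                    c(NA, 1, 1, NA, 4))
  recs3 <- detect_cascades(log3, 1)
  expect_equal(vapply(recs3, `[[`, numeric(1), "size"), c(3, 2))
  # member sets partition the decided agents
  expect_setequal(unlist(lapply(recs3, `[[`, "members")), 1:5)

  # dangling parent
  log4 <- event_log(1:2, 1:2, 1, c("spontaneous", "kick"), c(NA, 9))
  expect_error(detect_cascades(log4), "dangling")
})

test_that("cascade members never exceed the decided count in real runs", {
  cfg <- seq_config(n = 40, prior = drift_prior(0.2, 0.5), dt = 0.02)
  tp <- random_connected_rgg(40, 13)
  r <- run_asynchronous(cfg, tp, seed = 3)
  recs <- detect_cascades(r$events, 1)
  expect_equal(sum(vapply(recs, `[[`, numeric(1), "size")),
               nrow(r$events))
  expect_lte(sum(vapply(detect_cascades(r$events, 4), `[[`, numeric(1),
                        "size")), sum(r$decided))
})

test_that("influence statistics attribute cascades to drift ranks", {
  fake_run <- function(drifts, events, option) {
    structure(
      list(decided = rep(TRUE, length(drifts)), option = option,
           time = seq_along(drifts), undecided = integer(0),
           drifts = drifts, events = events, true_state = 1,
           z = 1, horizon = 100, kicks_enabled = TRUE),
      class = "seq_run_result"
    )
  }
  # agent 2 has the largest drift (rank 1) and triggers everyone
  ev <- event_log(c(2, 1, 3), c(1, 2, 3), 1,
                  c("spontaneous", "kick", "kick"), c(NA, 2, 2))
  run <- fake_run(c(0.1, 0.9, 0.5), ev, c(1, 1, 1))
  st <- influence_stats(list(run, run), min_size = 3)
  expect_equal(st$trigger_counts[1], 2L)
  expect_equal(sum(st$trigger_counts), 2L)
  expect_true(all(st$sizes$rank == 1))
  expect_true(all(st$sizes$trigger_correct))
  expect_equal(nrow(st$sizes_all), 2L)
  # permuted drifts move the credit to the new rank of agent 2
  run2 <- fake_run(c(0.9, 0.1, 0.5), ev, c(1, 1, 1))
  st2 <- influence_stats(list(run2), min_size = 3)
  expect_equal(st2$trigger_counts[3], 1L)
})

test_that("realized Bayes-risk cost matches hand computations", {
  mk <- function(option, time, decided = rep(TRUE, length(option)),
                 horizon = 50) {
    structure(
      list(decided = decided, option = option, time = time,
           undecided = which(!decided), drifts = rep(0.2, length(option)),
           events = NULL, true_state = 1, z = 1, horizon = horizon,
           kicks_enabled = TRUE),
      class = "seq_run_result"
    )
  }
  cost <- cost_spec(2, 10)
  # all correct at time 3: cost = omega_t * 3
  expect_equal(bayes_risk_cost(mk(c(1, 1), c(3, 3)), cost), 6)
  # all wrong at time 3: cost = omega_t * 3 + omega_e
  expect_equal(bayes_risk_cost(mk(c(-1, -1), c(3, 3)), cost), 16)
  # one undecided agent charged horizon time when the flag is on
  r <- mk(c(1, NA), c(3, NA), decided = c(TRUE, FALSE), horizon = 50)
  expect_equal(bayes_risk_cost(r, cost), (6 + 100) / 2)
  expect_equal(bayes_risk_cost(r, cost, charge_undecided = FALSE), 6)
})

test_that("disabling kicks reduces to independent accumulators", {
  prior <- drift_prior(0.3, 0)
  cfg <- seq_config(n = 25, prior = prior, z = 1, dt = 0.01,
                    max_time = 400, kicks_enabled = FALSE)
  tp <- random_connected_rgg(25, 5)
  opts <- unlist(lapply(1:20, function(s) {
    r <- run_asynchronous(cfg, tp, seed = s)
    expect_true(all(r$events$cause == "spontaneous"))
    r$option[r$decided]
  }))
  p_an <- hit_probability(ddm_spec(0.3, 1, 1))
  p_hat <- mean(opts == 1)
  expect_lt(abs(p_hat - p_an), 3 * sqrt(p_an * (1 - p_an) / length(opts)))
})
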