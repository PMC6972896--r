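test_that("utility discounts rewarded U-turns only", {
  expect_equal(utility_value(1, TRUE, 0.3), 0.7)
  expect_equal(utility_value(0, TRUE, 0.9), 0)
  expect_equal(utility_value(1, FALSE, 0.9), 1)
  expect_error(utility_value(1, TRUE, 1.5))
})

test_that("value update is the delta rule with its fixed point", {
  expect_equal(update_q(0, 1, 0.1), 0.1)
  expect_equal(update_q(0.5, 1, 0.1), 0.55)
  expect_equal(update_q(0.37, 0.37, 0.8), 0.37)
  expect_error(update_q(0, 1, 0))
})

test_that("softmax probabilities are correct, normalized and shift-invariant", {
  p <- softmax_policy(c(1, 0), tau = 1)$probabilities
  expect_equal(unname(p), c(exp(1) / (1 + exp(1)), 1 / (1 + exp(1))),
               tolerance = 1e-10)
  expect_equal(unname(softmax_policy(c(0.4, 0.4), 0.7)$probabilities),
               c(0.5, 0.5))
  set.seed(1)
  for (i in 1:25) {
    v <- rnorm(2, sd = 3)
    tau <- runif(1, 0.01, 5)
    p1 <- softmax_policy(v, tau)$probabilities
    expect_equal(sum(p1), 1)
    expect_equal(p1, softmax_policy(v + 17.3, tau)$probabilities)
  }
  # cold limit concentrates on the argmax
  expect_gt(softmax_policy(c(1, 0), 1e-3)$probabilities[1], 1 - 1e-12)
  expect_error(softmax_policy(c(1, 0), 0))
  expect_error(softmax_policy(c(1, 0, 2), 1))
})

test_that("state encoding orders slots most-recent-first with sentinel padding", {
  p0 <- agent_params(memory = 0L)
  expect_identical(encode_state(c("A", "B"), p0), "B")
  p2 <- agent_params(memory = 2L)
  expect_identical(encode_state(c("A", "B", "C"), p2), c("C", "B", "A"))
  expect_identical(encode_state("A", p2), c("A", "*", "*"))
})

test_that("ambiguous encoding draws codes uniformly per event", {
  p <- agent_params(memory = 0L, ambiguity = 3L)
  set.seed(7)
  codes <- replicate(3000, encode_state(c("A", "B", "C"), p))
  expect_true(all(codes %in% c("C1", "C2", "C3")))
  freq <- table(codes) / length(codes)
  expect_true(all(abs(freq - 1 / 3) < 0.03))
})

test_that("agent runs are byte-for-byte reproducible under a seed", {
  par <- agent_params(0.1, 0.4, 0.5, 2)
  r1 <- run_agent(par, task_rule("complexity"), n_iterations = 3000, seed = 12)
  r2 <- run_agent(par, task_rule("complexity"), n_iterations = 3000, seed = 12)
  expect_identical(r1, r2)
  r3 <- run_agent(par, task_rule("complexity"), n_iterations = 3000, seed = 13)
  expect_false(identical(r1, r3))
})

test_that("trained agent adopts the circular low-U-turn pattern", {
  rec <- run_agent(agent_params(0.1, 0.15, 0.5, 1), task_rule("training"),
                   n_iterations = 2e4, seed = 3)
  u <- mean(vapply(tail(rec, 10), function(r) uturn_rate(r$locations),
                   numeric(1)))
  expect_lt(u, 0.05)
  expect_true(all(vapply(rec, function(r) all(r$rewarded == 1L), logical(1))))
})

test_that("sequence complexity rises with the randomness parameter", {
  for (m in c(0L, 2L)) {
    C <- vapply(c(0.02, 0.1, 0.5), function(tau) {
      mean(vapply(1:3, function(s) {
        rec <- run_agent(agent_params(0.1, tau, 0.5, m),
                         task_rule("complexity"), n_iterations = 3e4,
                         seed = 100 * s + m)
        session_statistics(rec)$C_hat
      }, numeric(1)))
    }, numeric(1))
    expect_true(all(diff(C) > 0), info = paste("memory", m))
  }
})

test_that("state ambiguity erodes the advantage of memory", {
  S <- function(m, n) {
    rec <- run_agent(agent_params(0.1, 0.2, 0.5, m, ambiguity = n),
                     task_rule("complexity"), n_iterations = 1.5e5, seed = 88)
    session_statistics(rec)$S_hat
  }
  s_mem <- S(4L, 1L)        # enough memory to exploit the tree
  s_mem_amb <- S(4L, 3L)    # same memory, ambiguous codes
  s_none <- S(0L, 1L)
  expect_gt(s_mem, 0.85)
  expect_lt(abs(s_mem_amb - s_none), abs(s_mem - s_none))
})

test_that("baseline policies realize the three task regimes", {
  r <- baseline_policy("random", n_iterations = 2e4,
                       trials_per_session = 2e4, seed = 1)[[1]]
  expect_lt(abs(mean(r$rewarded[-(1:9)]) - 0.75), 0.02)
  rep_ <- baseline_policy("repetitive", n_iterations = 500,
                          trials_per_session = 500, seed = 1)[[1]]
  expect_true(all(rep_$rewarded[-(1:9)] == 0L))
  expect_identical(unclass(rep_$locations)[1:6], c("A", "B", "C", "A", "B", "C"))
  g <- baseline_policy("greedy_oracle", n_iterations = 2000,
                       trials_per_session = 2000, seed = 1)[[1]]
  expect_true(all(g$rewarded[-(1:9)] == 1L))
  expect_error(baseline_policy("optimal"))
})

test_that("win-stay-lose-switch reverses direction exactly after non-reward", {
  w <- baseline_policy("wsls", rule = task_rule("complexity"),
                       n_iterations = 400, trials_per_session = 400,
                       seed = 6)[[1]]
  d <- encode_directions(w$locations)
  for (t in seq_along(d)[-1]) {
    if (w$rewarded[t] == 1L) expect_identical(d[t], d[t - 1])
    else expect_false(d[t] == d[t - 1])
  }
})
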