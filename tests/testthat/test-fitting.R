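test_that("fitness is one minus the mean absolute mismatch", {
  tg <- fit_target(S = 0.5, C = 0.8)
  expect_equal(fitness_score(0.5, 0.8, tg)$fitness, 1)
  f <- fitness_score(0.7, 0.9, tg)
  expect_equal(f$D_session, 0.15)
  expect_equal(f$fitness, 0.85)
  expect_equal(fitness_score(1, 1, fit_target(S = 0, C = 0))$fitness, 0)
  # training mode substitutes the U-turn term
  tu <- fit_target(U = 0.1, C = 0.2)
  expect_equal(fitness_score(0.3, 0.2, tu)$D_session, 0.1)
  expect_error(fitness_score(1.2, 0.5, tg))
  expect_error(fit_target(S = 0.5, U = 0.1, C = 0.5))
})

test_that("fitness is symmetric in its two terms and 1/2-Lipschitz", {
  set.seed(91)
  for (i in 1:30) {
    v <- runif(4)
    f1 <- fitness_score(v[1], v[2], fit_target(S = v[3], C = v[4]))$D_session
    f2 <- fitness_score(v[2], v[1], fit_target(S = v[4], C = v[3]))$D_session
    expect_equal(f1, f2)
    eps <- runif(1, 0, 0.1)
    s2 <- min(1, v[1] + eps)
    f3 <- fitness_score(s2, v[2], fit_target(S = v[3], C = v[4]))$D_session
    expect_lte(abs(f3 - f1), (s2 - v[1]) / 2 + 1e-12)
  }
})

test_that("trailing-session statistics summarize the policy regimes", {
  g <- baseline_policy("greedy_oracle", n_iterations = 2000, seed = 70)
  expect_equal(session_statistics(g)$S_hat, 1)
  r <- baseline_policy("random", n_iterations = 10000, seed = 71)
  sr <- session_statistics(r)
  expect_lt(abs(sr$S_hat - 0.76), 0.03)  # 0.75 plus the warm-up credit
  expect_lt(abs(sr$C_hat - 1), 0.05)
  p <- baseline_policy("repetitive", n_iterations = 2000, seed = 72)
  sp <- session_statistics(p)
  expect_lt(sp$S_hat, 0.06)
  expect_lt(sp$C_hat, 0.2)
  expect_error(session_statistics(g[1:3]))
})

test_that("random search is reproducible and respects its budget", {
  tg <- fit_target(S = 0.75, C = 1)
  b1 <- random_search(tg, budget = 1, n_iterations = 5000, seed = 5)
  expect_identical(nrow(b1), 1L)
  expect_true(all(c("rho", "S_hat", "C_hat", "fitness") %in% names(b1)))
  b2 <- random_search(tg, budget = 12, n_iterations = 5000, top = 5, seed = 6)
  expect_identical(nrow(b2), 5L)
  expect_true(all(diff(b2$fitness) <= 0))
  expect_identical(b2, random_search(tg, budget = 12, n_iterations = 5000,
                                     top = 5, seed = 6))
  expect_error(random_search(tg, budget = 0))
})

test_that("search attributes random behavior to high randomness, small memory", {
  # target = the statistics of a uniform random chooser
  tg <- fit_target(S = 0.76, C = 1)
  b <- random_search(tg, budget = 40, n_iterations = 2e4, seed = 7)
  expect_gt(median(b$rho[1:5]), 1)
  expect_gt(b$fitness[1], 0.9)
  # target = circular training behavior: best fits have low randomness
  tu <- fit_target(U = 0.02, C = 0.15)
  bu <- random_search(tu, budget = 40, n_iterations = 2e4,
                      rule = task_rule("training"), seed = 8)
  expect_lt(median(bu$rho[1:5]), median(b$rho[1:5]))
})

test_that("grid search scores the continuous schedule", {
  targets <- c(list(fit_target(U = 0.02, C = 0.15)),
               lapply(seq(0.5, 0.75, length.out = 10), function(s)
                 fit_target(S = s, C = min(1, s + 0.25))))
  grid <- data.frame(alpha = c(0.1, 0.1), tau = c(0.2, 2), kappa = 0.5,
                     memory = 1L)
  lb <- grid_search(grid, targets, n_runs = 3, n_iterations = 4000, seed = 9)
  expect_identical(nrow(lb), 2L)
  expect_true(all(lb$fitness >= 0 & lb$fitness <= 1))
  expect_true(all(diff(lb$fitness) <= 0))
  # the moderate-temperature agent tracks the rising-variability targets
  # better than the hot one
  expect_equal(lb$tau[1], 0.2)
  expect_identical(lb, grid_search(grid, targets, n_runs = 3,
                                   n_iterations = 4000, seed = 9))
  expect_error(grid_search(grid[0, ], targets))
})

test_that("Bayes factor is the ratio of in-CI fractions", {
  mk <- function(S, C) data.frame(S_hat = S, C_hat = C)
  ci <- list(S = c(0.7, 0.8), C = c(0.9, 1.1))
  ind <- mk(c(rep(0.75, 12), rep(0.2, 3)), rep(1, 15))
  con <- mk(c(rep(0.75, 4), rep(0.2, 11)), rep(1, 15))
  bf <- bayes_factor(ind, con, ci)
  expect_equal(bf$lik_ind, 12 / 15)
  expect_equal(bf$lik_con, 4 / 15)
  expect_equal(bf$bayes_factor, 3)
  expect_false(bf$infinite)
  # equal likelihoods
  expect_equal(bayes_factor(ind, ind, ci)$bayes_factor, 1)
  # zero denominator is flagged infinity, not smoothed
  none <- mk(rep(0.2, 15), rep(0.2, 15))
  bf0 <- bayes_factor(ind, none, ci)
  expect_true(is.infinite(bf0$bayes_factor))
  expect_true(bf0$infinite && bf0$substantial)
  # per-session CIs average the fractions
  bf2 <- bayes_factor(list(ind, ind), list(con, none), list(ci, ci))
  expect_equal(bf2$lik_con, mean(c(4 / 15, 0)))
})

test_that("the 95% CI helper covers the mean", {
  set.seed(33)
  x <- rnorm(27, 0.7, 0.1)
  ci <- ci95(x)
  expect_lt(ci[1], mean(x))
  expect_gt(ci[2], mean(x))
})
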