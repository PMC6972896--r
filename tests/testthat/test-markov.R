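test_that("direction encoding follows the fixed orientation", {
  expect_identical(encode_directions("ABCA"), c("R", "R", "R"))
  expect_identical(encode_directions("ABA"), c("R", "L"))
  expect_identical(encode_directions("ACB"), c("L", "L"))
  expect_error(encode_directions("A"))
  expect_error(encode_directions("AAB"))
})

test_that("direction decoding inverts the encoding", {
  set.seed(40)
  for (rep in 1:20) {
    s <- random_norepeat(sample(5:60, 1), seed = rep)
    expect_identical(unclass(decode_directions(encode_directions(s), s[1])),
                     unclass(s))
  }
})

test_that("a U-turn is exactly a direction change", {
  s <- random_norepeat(500, seed = 41)
  d <- encode_directions(s)
  changes <- d[-1] != d[-length(d)]
  expect_equal(mean(changes), uturn_rate(s))
})

test_that("conditional probabilities are ML estimates with proper rows", {
  tab <- conditional_probabilities(c("R", "L", "R", "L", "R", "L", "R", "L"))
  expect_equal(tab$order0$P_L, 0.5)
  expect_equal(tab$order1$P_L[tab$order1$context == "R"], 1)
  expect_equal(tab$order1$P_R[tab$order1$context == "L"], 1)
  # rows sum to 1 wherever defined
  for (o in tab) {
    ok <- !is.na(o$P_L)
    expect_equal(o$P_L[ok] + o$P_R[ok], rep(1, sum(ok)))
  }
  # unseen contexts are NA, not smoothed
  tab2 <- conditional_probabilities(rep("R", 10))
  expect_true(is.na(tab2$order1$P_L[tab2$order1$context == "L"]))
  expect_identical(tab2$order1$n[tab2$order1$context == "L"], 0L)
  expect_error(conditional_probabilities(c("R", "L"), max_order = 2))
})

test_that("a first-order kernel is recovered and its order identified", {
  s <- make_fixture("first_order_markov", length = 5001, seed = 50,
                    p_stay = 0.7)
  tab <- conditional_probabilities(encode_directions(s))
  pL <- tab$order0$P_L
  pLL <- tab$order1$P_L[tab$order1$context == "L"]
  pLLL <- tab$order2$P_L[tab$order2$context == "LL"]
  expect_lt(abs(pLL - 0.7), 0.03)   # the generating kernel
  expect_gt(abs(pLL - pL), 0.1)     # first order needed
  expect_lt(abs(pLLL - pLL), 0.04)  # second order adds nothing
})

test_that("i.i.d. directions show no conditional structure", {
  s <- random_norepeat(10000, seed = 51)
  tab <- conditional_probabilities(encode_directions(s))
  ests <- c(tab$order0$P_L, tab$order1$P_L, tab$order2$P_L)
  expect_true(all(abs(ests - 0.5) < 0.04))
})

test_that("the analysis is invariant to the global L/R swap", {
  s <- make_fixture("first_order_markov", length = 2001, seed = 52)
  d <- encode_directions(s)
  swapped <- c(L = "R", R = "L")[d]
  t1 <- conditional_probabilities(d)
  t2 <- conditional_probabilities(swapped)
  swap_ctx <- function(x) chartr("LR", "RL", x)
  for (k in 1:3) {
    o1 <- t1[[k]]
    o2 <- t2[[k]]
    m <- match(swap_ctx(o1$context), o2$context)
    expect_equal(o1$P_L, o2$P_R[m])
    expect_identical(o1$n, o2$n[m])
  }
})

test_that("order summary assembles paired vectors across subjects", {
  expect_error(markov_order_summary(list(
    conditional_probabilities(c("R", "L", "R")))), "2 subjects")
  tabs <- lapply(1:6, function(i)
    conditional_probabilities(encode_directions(
      random_norepeat(4000, seed = 600 + i))))
  sm <- markov_order_summary(tabs)
  expect_identical(nrow(sm), 6L * 12L)
  d01 <- sm$higher[sm$order_pair == "0v1"] - sm$lower[sm$order_pair == "0v1"]
  d12 <- sm$higher[sm$order_pair == "1v2"] - sm$lower[sm$order_pair == "1v2"]
  # i.i.d. cohort: both comparisons centered at zero
  expect_lt(abs(mean(d01)), 0.02)
  expect_lt(abs(mean(d12)), 0.02)
  # first-order cohort: the 0-vs-1 comparison shifts, 1-vs-2 does not
  tabs1 <- lapply(1:6, function(i)
    conditional_probabilities(encode_directions(
      make_fixture("first_order_markov", 4000, seed = 700 + i))))
  sm1 <- markov_order_summary(tabs1)
  g01 <- abs(sm1$higher[sm1$order_pair == "0v1"] -
               sm1$lower[sm1$order_pair == "0v1"])
  g12 <- abs(sm1$higher[sm1$order_pair == "1v2"] -
               sm1$lower[sm1$order_pair == "1v2"])
  expect_gt(mean(g01), 0.15)
  expect_lt(mean(g12), 0.04)
})

test_that("reward-conditioned transitions expose win-stay-lose-switch", {
  w <- make_fixture("wsls", length = 400, seed = 60)
  tab <- reward_conditioned_probs(w)
  get <- function(p) tab$value[tab$probability == p]
  expect_equal(get("P(U|unrw)"), 1)
  expect_equal(get("P(U|rw)"), 0)
  # a reward-blind random chooser shows no conditioning
  r <- baseline_policy("random", n_iterations = 20000,
                       trials_per_session = 20000, seed = 61)[[1]]
  tr <- reward_conditioned_probs(r)
  vals <- tr$value[tr$probability %in% c("P(F)", "P(F|rw)", "P(F|unrw)")]
  expect_true(all(abs(vals - 0.5) < 0.03))
  # training sessions have no unrewarded context
  tr2 <- reward_conditioned_probs(session_record(
    random_norepeat(50, seed = 62), rep(1L, 50), condition = "training"))
  expect_true(is.na(tr2$value[tr2$probability == "P(U|unrw)"]))
})

test_that("the validity mask drops flagged trials from the estimates", {
  s <- c("A", "B", "A", "B", "C", "B")
  rw <- c(1L, 1L, 0L, 1L, 1L, 1L)
  full <- reward_conditioned_probs(session_record(s, rw))
  masked <- reward_conditioned_probs(session_record(
    s, rw, valid = c(1L, 1L, 0L, 1L, 1L, 1L)))
  expect_lt(masked$n[masked$probability == "P(U)"],
            full$n[full$probability == "P(U)"])
})
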