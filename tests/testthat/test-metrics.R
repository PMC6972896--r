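test_that("surrogates obey the task constraint with uniform marginals", {
  s <- generate_surrogates(200, 150, seed = 4)
  expect_length(s, 150)
  for (x in s[1:10]) expect_silent(as_choice_sequence(x))
  freq <- table(unlist(s)) / (200 * 150)
  expect_true(all(abs(freq - 1 / 3) < 0.02))
  # the direction encoding of surrogates is i.i.d. uniform
  d <- unlist(lapply(s, encode_directions))
  tab <- table(head(d, -1), tail(d, -1))
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.001)
  expect_lt(abs(mean(d == "L") - 0.5), 0.01)
})

test_that("NLZcomp is near 1 for random choice and far below for repetition", {
  s <- generate_surrogates(150, 100, seed = 8)
  vals <- vapply(s, nlzcomp, numeric(1))
  expect_lt(abs(mean(vals) - 1), 0.02)
  expect_lt(nlzcomp(strrep("ABC", 50)), 0.3)
  expect_error(nlzcomp("A"))
  # normalizer is recomputed per length: different lengths, both calibrated
  s80 <- generate_surrogates(80, 50, seed = 9)
  expect_lt(abs(mean(vapply(s80, nlzcomp, numeric(1))) - 1), 0.04)
})

test_that("diagonal-line entropy matches the hand-built recurrence plot", {
  # period-3 circle, length 30: diagonals of nine distinct lengths 27..3
  expect_equal(rqa_entropy(strrep("ABC", 10)), log(9))
  # all off-diagonal runs of one length: degenerate distribution, entropy 0
  expect_equal(rqa_entropy("ABAB"), 0)
  expect_error(rqa_entropy("AB"))
})

test_that("diagonal-line entropy agrees with the O(T^2) matrix oracle", {
  set.seed(55)
  for (rep in 1:40) {
    len <- sample(5:25, 1)
    s <- sample(c("A", "B", "C"), len, replace = TRUE)
    expect_equal(rqa_entropy(s), rqa_oracle(s), info = paste(s, collapse = ""))
  }
  # structured cases too
  expect_equal(rqa_entropy(strrep("AB", 12)), rqa_oracle(strrep("AB", 12)))
  expect_equal(rqa_entropy(strrep("ABCB", 6)), rqa_oracle(strrep("ABCB", 6)))
})

test_that("entropy is lower for random than for periodic sequences", {
  r <- random_norepeat(150, seed = 10)
  expect_lt(rqa_entropy(r), rqa_entropy(strrep("ABC", 50)))
})

test_that("U-turn rate counts returns over trials 3..T", {
  expect_equal(uturn_rate("ABCABC"), 0)
  expect_equal(uturn_rate("ABABAB"), 1)
  expect_equal(uturn_rate("ABCBA"), 1 / 3)
  expect_error(uturn_rate("AB"))
  # i.i.d. directions return half the time
  r <- random_norepeat(20000, seed = 11)
  expect_lt(abs(uturn_rate(r) - 0.5), 0.01)
})

test_that("surrogate test separates random from structured sequences", {
  # a fresh surrogate is indistinguishable from its ensemble
  s <- generate_surrogates(150, 1, seed = 123)[[1]]
  expect_true(surrogate_test(s)$indistinguishable)
  # periodic sequence sits below every surrogate count
  st <- surrogate_test(strrep("ABC", 50))
  expect_false(st$indistinguishable)
  expect_lt(st$p_value, 0.01)
  # mostly-circular sequence with 10% reversals: still detected as structured
  set.seed(77)
  locs <- c("A", "B", "C")
  noisy <- "A"
  for (i in 2:150) {
    step <- if (runif(1) < 0.9) 1L else 2L
    noisy[i] <- locs[(match(noisy[i - 1], locs) - 1L + step) %% 3L + 1L]
  }
  expect_false(surrogate_test(noisy)$indistinguishable)
})

test_that("pattern histogram pools A-starting windows in tree order", {
  h <- pattern_histogram(as_choice_sequence(strrep("ABC", 10)), k = 10)
  expect_identical(names(h$counts), "ABCABCABCA")
  expect_identical(h$n_windows, 7L)
  expect_identical(sum(h$counts), h$n_windows)
  # pooled random sequences spread mass over many patterns
  rnd <- generate_surrogates(200, 20, seed = 14)
  hr <- pattern_histogram(rnd, k = 10)
  expect_identical(sum(hr$counts), hr$n_windows)
  expect_gt(length(hr$counts), 100)
  # tree order: names sorted so neighbor branches share prefixes
  expect_identical(names(hr$counts), sort(names(hr$counts)))
  # the repetitive input concentrates its cumulative mass far faster
  expect_gt(h$ranked_cumulative[1], hr$ranked_cumulative[1])
})

test_that("metrics report bundles the session statistics", {
  g <- baseline_policy("random", n_iterations = 150,
                       trials_per_session = 150, seed = 20)[[1]]
  rep_ <- metrics_report(g)
  expect_s3_class(rep_, "metrics_report")
  expect_true(rep_$nlzcomp > 0.8 && rep_$nlzcomp < 1.2)
  expect_true(rep_$success_rate >= 0 && rep_$success_rate <= 1)
  expect_true(rep_$uturn_rate >= 0 && rep_$uturn_rate <= 1)
})
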