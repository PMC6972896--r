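#' Task rule configuration
#'
#' Three reward regimes are supported. Under \code{training} every target is
#' rewarded. Under \code{complexity} a choice is rewarded when the window of
#' the nine past choices plus the chosen option has the (weakly) highest LZ
#' complexity of the two legal extensions; the rule is fully deterministic.
#' Under \code{p75} every target is rewarded with probability
#' \code{p_reward} (default 0.75, the uniform-choice success level of the
#' complexity rule), independently of the choice sequence.
#'
#' @param condition one of \code{"complexity"}, \code{"training"},
#'   \code{"p75"}.
#' @param window evaluation window in trials (9 past choices + the next one);
#'   fixed at 10 in all task-faithful configurations.
#' @param warmup policy for trials with fewer than \code{window - 1} past
#'   choices: \code{"reward_all"} rewards them (as in the preceding 100%
#'   training), \code{"skip"} scores the shorter available window.
#' @param p_reward reward probability, used only by \code{p75}.
#' @return list with class \code{"task_rule"}.
#' @export
task_rule <- function(condition = c("complexity", "training", "p75"),
                      window = 10L,
                      warmup = c("reward_all", "skip"),
                      p_reward = 0.75) {
  condition <- match.arg(condition)
  warmup <- match.arg(warmup)
  window <- as.integer(window)
  if (window != 10L) stop("the task is defined for window = 10")
  if (!is.numeric(p_reward) || p_reward < 0 || p_reward > 1)
    stop("p_reward must be in [0, 1]")
  structure(list(condition = condition, window = window, warmup = warmup,
                 p_reward = p_reward), class = "task_rule")
}

condition_code <- function(rule) {
  match(rule$condition, c("training", "complexity", "p75")) - 1L
}
warmup_code <- function(rule) match(rule$warmup, c("reward_all", "skip")) - 1L

#' Deterministic reward map for one decision
#'
#' Given the nine past choices, reports for each of the two legal options
#' whether choosing it is rewarded. Under the complexity rule the option
#' whose 10-symbol extension has the strictly higher LZ complexity is the
#' only rewarded one; on ties both are rewarded. Under training both options
#' are always rewarded. For the probabilistic condition the reward is sampled
#' at step time, not here.
#'
#' @param history choice sequence of length \code{window - 1} (9).
#' @param rule a [task_rule()].
#' @return named logical vector over the two legal options.
#' @examples
#' reward_decision("ABCABCABC", task_rule("complexity"))
#' @export
reward_decision <- function(history, rule = task_rule("complexity")) {
  history <- as_choice_sequence(history)
  if (rule$condition == "p75")
    stop("p75 rewards are sampled at step time, not by the deterministic rule")
  if (rule$condition == "complexity" && length(history) != rule$window - 1L)
    stop("complexity rule needs a history of exactly ", rule$window - 1L,
         " choices (warm-up is the caller's job)")
  last <- history[length(history)]
  opts <- setdiff(LOCATIONS, last)
  if (rule$condition == "training") {
    out <- c(TRUE, TRUE)
  } else {
    counts <- vapply(opts, function(o)
      lz_complexity(c(unclass(history), o)), integer(1))
    out <- counts >= max(counts)
  }
  names(out) <- opts
  out
}

#' Step the task environment
#'
#' Appends one action to the history buffer and returns the reward it earns
#' under the rule. Warm-up trials (fewer than \code{window - 1} past choices)
#' are handled per \code{rule$warmup}.
#'
#' @param state list with element \code{history} (a choice sequence), or
#'   \code{NULL} to start a new session.
#' @param action next location; must differ from the current one.
#' @param rule a [task_rule()].
#' @return list with elements \code{state} (updated) and \code{reward}.
#' @export
step_task <- function(state, action, rule = task_rule("complexity")) {
  if (is.null(state)) state <- list(history = NULL)
  hist <- state$history
  if (!is.null(hist)) hist <- as_choice_sequence(hist)
  if (!action %in% LOCATIONS) stop("unknown location '", action, "'")
  if (!is.null(hist) && action == hist[length(hist)])
    stop("illegal repeat: action equals the current location")
  if (is.null(hist)) {
    reward <- if (rule$condition == "p75") as.integer(runif(1) < rule$p_reward) else 1L
  } else if (rule$condition == "training") {
    reward <- 1L
  } else if (rule$condition == "p75") {
    reward <- as.integer(runif(1) < rule$p_reward)
  } else if (length(hist) < rule$window - 1L && rule$warmup == "reward_all") {
    reward <- 1L
  } else {
    h <- if (length(hist) >= rule$window - 1L)
      tail(unclass(hist), rule$window - 1L) else unclass(hist)
    other <- setdiff(LOCATIONS, c(action, h[length(h)]))
    reward <- as.integer(lz_complexity(c(h, action)) >=
                           lz_complexity(c(h, other)))
  }
  list(state = list(history = as_choice_sequence(c(unclass(hist), action))),
       reward = reward)
}

#' Re-score a choice sequence under the complexity rule
#'
#' Replays an arbitrary no-repeat sequence through the deterministic rule and
#' reports the per-trial reward flags plus the success rate over the
#' post-warm-up trials (those with a full window of nine past choices).
#'
#' @param seq a choice sequence, length greater than the window.
#' @param rule a [task_rule()]; the condition must be \code{"complexity"}.
#' @return list with \code{rewards} (one flag per trial; warm-up trials per
#'   \code{rule$warmup}), \code{success_rate} (post-warm-up trials only), and
#'   \code{n_scored}.
#' @examples
#' evaluate_sequence(strrep("ABC", 20))$success_rate  # 0: periodic
#' @export
evaluate_sequence <- function(seq, rule = task_rule("complexity")) {
  seq <- as_choice_sequence(seq)
  if (rule$condition != "complexity")
    stop("evaluate_sequence re-scores under the complexity rule")
  if (length(seq) <= rule$window)
    stop("sequence must be longer than the window (", rule$window, ")")
  rewards <- rescore_cpp(seq_to_int(seq), warmup_code(rule))
  scored <- seq_along(seq) >= rule$window  # trials with 9 past choices
  list(rewards = rewards,
       success_rate = mean(rewards[scored]),
       n_scored = sum(scored))
}

#' Exhaustive enumeration of the task's decision tree
#'
#' Enumerates every valid 9-choice history (3 x 2^8 = 768 of them) and both
#' legal options, recording the LZ complexity of each 10-symbol extension and
#' whether it is rewarded. Under a uniform random choice each history yields
#' a reward probability of 1 (both options tie) or 0.5 (a single winner);
#' the enumeration reports the per-history probabilities and their mean,
#' which is the expected success rate of a uniform random policy. Because
#' the window chain under uniform choices is doubly stochastic, uniform
#' sampling of histories and the random-walk occupancy agree, and the mean is
#' also the long-run random-policy success rate.
#'
#' @param rule a [task_rule()] with condition \code{"complexity"}.
#' @return list of class \code{"tree_enumeration"}: \code{rows} (data frame
#'   with history, option, lz_count, rewarded), \code{per_history} (data
#'   frame with history and uniform-choice reward probability), and
#'   \code{summary} (n_histories, mean/min/max reward probability, tie
#'   fraction).
#' @export
enumerate_tree <- function(rule = task_rule("complexity")) {
  if (rule$condition != "complexity") stop("enumeration requires the complexity rule")
  w <- rule$window
  # all valid histories: first location free, then binary branching
  n_hist <- as.integer(3 * 2^(w - 2))
  hist_m <- matrix(0L, nrow = w - 1L, ncol = n_hist)
  grid <- expand.grid(rep(list(0:1), w - 2L))       # turn choices
  first <- rep(0:2, each = 2L^(w - 2L))
  hist_m[1, ] <- first
  for (i in 2:(w - 1L)) {
    turn <- rep(grid[[i - 1L]], times = 3L)
    hist_m[i, ] <- (hist_m[i - 1L, ] + 1L + turn) %% 3L
  }
  last <- hist_m[w - 1L, ]
  ext1 <- rbind(hist_m, (last + 1L) %% 3L)
  ext2 <- rbind(hist_m, (last + 2L) %% 3L)
  c1 <- lz_complexity_cols(ext1)
  c2 <- lz_complexity_cols(ext2)
  hist_str <- apply(hist_m, 2, function(col) paste(LOCATIONS[col + 1L], collapse = ""))
  rows <- data.frame(
    history = rep(hist_str, 2L),
    option = LOCATIONS[c((last + 1L) %% 3L, (last + 2L) %% 3L) + 1L],
    lz_count = c(c1, c2),
    rewarded = c(c1 >= c2, c2 >= c1),
    stringsAsFactors = FALSE)
  p_hist <- (as.numeric(c1 >= c2) + as.numeric(c2 >= c1)) / 2
  per_history <- data.frame(history = hist_str, p_reward = p_hist,
                            stringsAsFactors = FALSE)
  structure(list(
    rows = rows[order(rows$history, rows$option), ],
    per_history = per_history,
    summary = list(
      n_histories = n_hist,
      mean_reward_prob = mean(p_hist),
      min_reward_prob = min(p_hist),
      max_reward_prob = max(p_hist),
      tie_fraction = mean(p_hist == 1))),
    class = "tree_enumeration")
}

#' @export
print.tree_enumeration <- function(x, ...) {
  s <- x$summary
  cat("<tree_enumeration> ", s$n_histories, " histories\n",
      "  uniform-choice reward probability: mean ", s$mean_reward_prob,
      ", range [", s$min_reward_prob, ", ", s$max_reward_prob, "]\n",
      "  tie fraction: ", s$tie_fraction, "\n", sep = "")
  invisible(x)
}

#' Export a tree enumeration to TSV + JSON
#'
#' @param tree a [enumerate_tree()] result.
#' @param tsv path for the per-(history, option) table.
#' @param json path for the summary.
#' @return invisibly, the two paths.
#' @export
export_tree_enumeration <- function(tree, tsv, json) {
  stopifnot(inherits(tree, "tree_enumeration"))
  df <- tree$rows
  df$rewarded <- as.integer(df$rewarded)
  write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(tree$summary, json, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, json))
}
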