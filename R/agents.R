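#' Agent parameters
#'
#' Parameters of the memory-augmented Rescorla-Wagner/softmax agent. The
#' state is the vector of the current and up to \code{memory} past locations;
#' \code{kappa} discounts the reward of a U-turn in the utility, and
#' \code{tau} scales choice stochasticity. Their ratio \code{rho = tau/kappa}
#' is the effective randomness of action selection. With \code{ambiguity}
#' n > 1 each location is represented by n interchangeable codes and a code
#' is drawn uniformly at every encoding event, degrading the reliability of
#' the memory. The \code{BasicRL} configuration is \code{memory = 0},
#' \code{kappa = 0}.
#'
#' @param alpha learning rate in (0, 1].
#' @param tau softmax temperature, > 0.
#' @param kappa U-turn cost in \[0, 1\].
#' @param memory integer memory size m, 0..9 (the task window bounds useful
#'   memory).
#' @param ambiguity integer number of codes per location, >= 1.
#' @return list of class \code{"agent_params"}; \code{$rho} is \code{tau /
#'   kappa} (NA when \code{kappa} is 0).
#' @export
agent_params <- function(alpha = 0.1, tau = 0.5, kappa = 0.5,
                         memory = 0L, ambiguity = 1L) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must be in (0, 1]")
  if (!is.numeric(tau) || any(tau <= 0)) stop("tau must be > 0")
  if (!is.numeric(kappa) || any(kappa < 0) || any(kappa > 1))
    stop("kappa must be in [0, 1]")
  memory <- as.integer(memory)
  if (memory < 0L || memory > 9L) stop("memory must be an integer in 0..9")
  ambiguity <- as.integer(ambiguity)
  if (ambiguity < 1L) stop("ambiguity must be >= 1")
  structure(list(alpha = alpha, tau = tau, kappa = kappa, memory = memory,
                 ambiguity = ambiguity,
                 rho = ifelse(kappa > 0, tau / kappa, NA_real_)),
            class = "agent_params")
}

#' Encode the agent's state
#'
#' The state is the tuple of the current and \code{memory} previous
#' locations, most recent first; positions before the start of the session
#' are padded with a start sentinel. With \code{ambiguity} n > 1 each
#' location slot is replaced by one of that location's n codes, drawn
#' uniformly and independently at every encoding event.
#'
#' @param history locations observed so far (most recent last).
#' @param params an [agent_params()].
#' @return character vector of m + 1 slot codes, most recent first
#'   (\code{"*"} is the start sentinel; ambiguous codes are \code{"A1"},
#'   \code{"A2"}, ...).
#' @export
encode_state <- function(history, params) {
  stopifnot(inherits(params, "agent_params"))
  history <- unclass(as_choice_sequence(history))
  m <- params$memory
  n <- params$ambiguity
  key <- character(m + 1L)
  t <- length(history)
  for (j in 0:m) {
    pos <- t - j
    if (pos < 1L) {
      key[j + 1L] <- "*"
    } else if (n == 1L) {
      key[j + 1L] <- history[pos]
    } else {
      key[j + 1L] <- paste0(history[pos], sample.int(n, 1L))
    }
  }
  key
}

#' Utility of an outcome
#'
#' The reward of a U-turn (returning to the location visited two steps
#' earlier) is discounted multiplicatively by the U-turn cost; an unrewarded
#' U-turn has utility 0.
#'
#' @param reward 0 or 1.
#' @param is_uturn logical.
#' @param kappa U-turn cost in \[0, 1\].
#' @return real utility.
#' @examples
#' utility_value(1, TRUE, 0.3)  # 0.7
#' @export
utility_value <- function(reward, is_uturn, kappa) {
  if (kappa < 0 || kappa > 1) stop("kappa must be in [0, 1]")
  ifelse(is_uturn, (1 - kappa) * reward, reward)
}

#' Rescorla-Wagner value update
#'
#' @param q current value.
#' @param u utility of the outcome.
#' @param alpha learning rate in (0, 1].
#' @return updated value \code{q + alpha * (u - q)}.
#' @export
update_q <- function(q, u, alpha) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  q + alpha * (u - q)
}

#' Softmax choice policy over the two legal actions
#'
#' @param values numeric action values, length 2 (the stay action is never
#'   available).
#' @param tau temperature, > 0.
#' @param sample if TRUE also draw an action.
#' @return list with \code{probabilities} (named like \code{values}) and,
#'   when sampled, \code{action} (the index or name drawn).
#' @export
softmax_policy <- function(values, tau, sample = FALSE) {
  if (!is.numeric(tau) || tau <= 0) stop("tau must be > 0")
  if (length(values) != 2L) stop("exactly two legal actions")
  z <- (values - max(values)) / tau
  p <- exp(z) / sum(exp(z))
  names(p) <- names(values)
  out <- list(probabilities = p)
  if (sample) {
    i <- if (runif(1) < p[1]) 1L else 2L
    out$action <- if (!is.null(names(values))) names(values)[i] else i
  }
  out
}

#' Run the learning agent through the task
#'
#' Full learning loop (encode state, softmax choice, environment step,
#' utility, value update), split into simulated sessions of
#' \code{trials_per_session} trials. The value table persists across
#' sessions; the task history buffer resets at each session start (each
#' session begins at a uniformly drawn location and its first move is never
#' a U-turn). Values are initialized at 0: utilities live in \[0, 1\], so
#' structure has to be discovered rather than forced by optimism.
#'
#' @param params an [agent_params()]. \code{tau} and \code{kappa} may be
#'   vectors with one entry per session (a per-session schedule).
#' @param rule a [task_rule()], or a character vector of conditions with one
#'   entry per session for mixed schedules.
#' @param n_iterations total number of trials (ignored when
#'   \code{n_trials_per_session} is given explicitly).
#' @param trials_per_session trials per simulated session (200 mirrors the
#'   upper bound of a real session).
#' @param n_trials_per_session optional explicit vector of session lengths.
#' @param seed optional RNG seed; identical seeds give identical records.
#' @param subject_id label stamped on the records.
#' @return list of [session_record()]s.
#' @export
run_agent <- function(params, rule = task_rule("complexity"),
                      n_iterations = 2e5, trials_per_session = 200L,
                      n_trials_per_session = NULL, seed = NULL,
                      subject_id = "model") {
  stopifnot(inherits(params, "agent_params"))
  if (inherits(rule, "task_rule")) {
    conditions <- rule$condition
    warmup <- rule$warmup
    p_reward <- rule$p_reward
  } else {
    conditions <- rule
    warmup <- "reward_all"
    p_reward <- 0.75
  }
  if (is.null(n_trials_per_session)) {
    if (n_iterations < 1) stop("n_iterations must be >= 1")
    n_sessions <- ceiling(n_iterations / trials_per_session)
    n_trials_per_session <- rep(as.integer(trials_per_session), n_sessions)
    n_trials_per_session[n_sessions] <-
      as.integer(n_iterations - (n_sessions - 1L) * trials_per_session)
  }
  n_sessions <- length(n_trials_per_session)
  conditions <- rep_len(conditions, n_sessions)
  cond_code <- match(conditions, c("training", "complexity", "p75")) - 1L
  if (any(is.na(cond_code))) stop("unknown condition in rule")
  wcode <- match(warmup, c("reward_all", "skip")) - 1L
  sim <- with_seed(seed, agent_simulate_cpp(
    params$alpha, rep_len(params$tau, n_sessions),
    rep_len(params$kappa, n_sessions),
    params$memory, params$ambiguity, cond_code,
    as.integer(n_trials_per_session), p_reward, wcode, 0.0))
  split_simulation(sim, conditions, warmup, subject_id)
}

split_simulation <- function(sim, conditions, warmup, subject_id) {
  idx <- split(seq_along(sim$choices), sim$session)
  lapply(seq_along(idx), function(s) {
    i <- idx[[s]]
    session_record(int_to_seq(sim$choices[i]), sim$rewards[i],
                   condition = conditions[s], subject_id = subject_id,
                   session_index = s, warmup = warmup)
  })
}

#' Reference (non-learning) policies
#'
#' \code{random} draws uniformly over the two legal locations;
#' \code{repetitive} cycles in a fixed direction (A, B, C, A, ...);
#' \code{greedy_oracle} always picks an option of (weakly) maximal LZ
#' extension under the complexity rule, breaking ties uniformly at random, so
#' it is rewarded on every scored trial; \code{wsls} repeats its movement
#' direction after a reward and reverses it otherwise.
#'
#' @param kind one of \code{"random"}, \code{"repetitive"},
#'   \code{"greedy_oracle"}, \code{"wsls"}.
#' @param rule a [task_rule()].
#' @param n_iterations total trials.
#' @param trials_per_session session length used to split the run.
#' @param seed optional RNG seed.
#' @param subject_id label stamped on the records.
#' @return list of [session_record()]s.
#' @export
baseline_policy <- function(kind = c("random", "repetitive", "greedy_oracle",
                                     "wsls"),
                            rule = task_rule("complexity"),
                            n_iterations = 1000, trials_per_session = 200L,
                            seed = NULL, subject_id = kind) {
  kind <- match.arg(kind)
  subject_id <- subject_id[1]
  kcode <- match(kind, c("random", "repetitive", "greedy_oracle", "wsls")) - 1L
  n_sessions <- ceiling(n_iterations / trials_per_session)
  n_trials <- rep(as.integer(trials_per_session), n_sessions)
  n_trials[n_sessions] <-
    as.integer(n_iterations - (n_sessions - 1L) * trials_per_session)
  sim <- with_seed(seed, baseline_simulate_cpp(
    kcode, condition_code(rule), n_trials, rule$p_reward, warmup_code(rule)))
  split_simulation(sim, rep(rule$condition, n_sessions), rule$warmup,
                   subject_id)
}

#' Memory-regime sweep of the randomness effect
#'
#' For each memory size, runs the agent once at a low and once at a high
#' temperature (same U-turn cost, so low and high randomness rho =
#' tau/kappa) and measures the asymptotic success rate over the trailing
#' simulated sessions. Increasing randomness raises success for small
#' memories (it rescues the agent from poorly rewarded stereotyped cycles,
#' toward the 75% of a uniform chooser) but lowers it for large memories
#' (which can exploit the deterministic tree beyond 75%). The sweep reports
#' the boundary: the largest memory size at which the high-randomness run
#' still outperforms the low-randomness one.
#'
#' The default low temperature is 0.2, not lower: near the zero-temperature
#' limit the softmax entrenches whatever cycle the first rewards single
#' out, and even 2-step memories lock into fully rewarded cycles, which
#' masks the memory dependence the sweep is after.
#'
#' @param m_values memory sizes to sweep.
#' @param tau_low,tau_high the two temperatures.
#' @param kappa U-turn cost (fixed across the sweep).
#' @param alpha learning rate.
#' @param n_iterations trials per run.
#' @param window trailing sessions averaged for the asymptotic success.
#' @param seed RNG seed.
#' @return list with \code{table} (data frame: memory, S_low, S_high,
#'   gain) and \code{boundary} (largest memory with positive gain; NA if
#'   none).
#' @export
memory_regime_sweep <- function(m_values = 0:6, tau_low = 0.2,
                                tau_high = 2.5, kappa = 0.5, alpha = 0.1,
                                n_iterations = 2e5, window = 10L,
                                seed = NULL) {
  run1 <- function(m, tau, s) {
    rec <- run_agent(agent_params(alpha, tau, kappa, m),
                     task_rule("complexity"), n_iterations = n_iterations,
                     seed = s)
    session_statistics(rec, window)$S_hat
  }
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                      2L * length(m_values)))
  S_low <- mapply(run1, m_values, tau_low, seeds[seq_along(m_values)])
  S_high <- mapply(run1, m_values, tau_high,
                   seeds[length(m_values) + seq_along(m_values)])
  gain <- S_high - S_low
  tab <- data.frame(memory = m_values, S_low = S_low, S_high = S_high,
                    gain = gain)
  pos <- which(gain > 0)
  list(table = tab,
       boundary = if (length(pos)) m_values[max(pos)] else NA_integer_)
}
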