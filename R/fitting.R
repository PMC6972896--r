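#' Fit target statistics for one session
#'
#' Behavioral statistics the agent is fitted to: mean success rate
#' \code{S} and mean complexity (NLZcomp) \code{C} for complexity sessions,
#' or mean U-turn rate \code{U} and \code{C} for training sessions (success
#' is uninformative when everything is rewarded). Optional 95% confidence
#' intervals across subjects feed the Bayesian model comparison.
#'
#' @param C mean complexity (NLZcomp).
#' @param S mean success rate (complexity sessions).
#' @param U mean U-turn rate (training sessions).
#' @param ci optional list with elements like \code{S = c(lo, hi)},
#'   \code{C = c(lo, hi)}.
#' @return list of class \code{"fit_target"} with a \code{mode} of
#'   \code{"complexity"} or \code{"training"}.
#' @export
fit_target <- function(C, S = NULL, U = NULL, ci = NULL) {
  if (is.null(S) == is.null(U))
    stop("give exactly one of S (complexity mode) or U (training mode)")
  mode <- if (is.null(U)) "complexity" else "training"
  structure(list(S = S, U = U, C = C, ci = ci, mode = mode),
            class = "fit_target")
}

#' Fitness of simulated statistics against a target
#'
#' The distance is the mean absolute mismatch of the two statistics,
#' \code{D = (|S_hat - S_bar| + |C_hat - C_bar|) / 2}, and the fitness is
#' \code{1 - D}. In training mode the success-rate term is replaced by the
#' U-turn-rate term. Complexity values are clamped into \[0, 1\] (a
#' simulated NLZcomp can exceed 1 by sampling noise).
#'
#' @param S_hat simulated success rate (complexity mode) or U-turn rate
#'   (training mode), in \[0, 1\].
#' @param C_hat simulated complexity.
#' @param target a [fit_target()].
#' @return list with \code{D_session} and \code{fitness}, both in \[0, 1\].
#' @examples
#' fitness_score(0.7, 0.9, fit_target(S = 0.5, C = 0.8))  # D = 0.15
#' @export
fitness_score <- function(S_hat, C_hat, target) {
  stopifnot(inherits(target, "fit_target"))
  ref <- if (target$mode == "complexity") target$S else target$U
  if (!is.numeric(S_hat) || S_hat < 0 || S_hat > 1)
    stop("S_hat must be in [0, 1]")
  if (!is.numeric(C_hat) || C_hat < 0 || C_hat > 2)
    stop("C_hat must be a complexity in [0, 2]")
  if (ref < 0 || ref > 1) stop("target statistic must be in [0, 1]")
  C_hat <- min(C_hat, 1)
  C_bar <- min(target$C, 1)
  D <- (abs(S_hat - ref) + abs(C_hat - C_bar)) / 2
  list(D_session = D, fitness = 1 - D)
}

#' Trailing-window statistics of a simulated run
#'
#' Means of success rate, complexity (NLZcomp) and U-turn rate over the last
#' \code{window} simulated sessions, i.e. the post-convergence behavior of a
#' long run.
#'
#' @param records list of [session_record()]s.
#' @param window number of trailing sessions to average (default 10).
#' @return list with \code{S_hat}, \code{C_hat}, \code{U_hat},
#'   \code{n_sessions}.
#' @export
session_statistics <- function(records, window = 10L) {
  if (length(records) < window)
    stop("need at least ", window, " sessions")
  use <- tail(records, window)
  list(S_hat = mean(vapply(use, success_rate, numeric(1))),
       C_hat = mean(vapply(use, function(r) nlzcomp(r$locations), numeric(1))),
       U_hat = mean(vapply(use, function(r) uturn_rate(r$locations),
                           numeric(1))),
       n_sessions = length(use))
}

#' Default hyperparameter search space
#'
#' Log-uniform for the learning rate and temperature, uniform for the
#' U-turn cost, uniform integer for the memory size.
#'
#' @param alpha_range,tau_range,kappa_range,memory_range bounds.
#' @return list of ranges consumed by [random_search()].
#' @export
default_search_space <- function(alpha_range = c(0.01, 1),
                                 tau_range = c(0.01, 10),
                                 kappa_range = c(0.01, 1),
                                 memory_range = c(0L, 9L)) {
  list(alpha = alpha_range, tau = tau_range, kappa = kappa_range,
       memory = memory_range)
}

sample_space <- function(space, budget, fixed_alpha = NULL) {
  loguni <- function(r, n) exp(runif(n, log(r[1]), log(r[2])))
  data.frame(
    alpha = if (is.null(fixed_alpha)) loguni(space$alpha, budget)
            else rep(fixed_alpha, budget),
    tau = loguni(space$tau, budget),
    kappa = runif(budget, space$kappa[1], space$kappa[2]),
    memory = sample(space$memory[1]:space$memory[2], budget, replace = TRUE))
}

# simulate one parameter set to convergence and return trailing statistics
asymptotic_statistics <- function(par, rule, n_iterations,
                                  trials_per_session = 200L, seed = NULL,
                                  window = 10L) {
  rec <- run_agent(agent_params(par$alpha, par$tau, par$kappa, par$memory,
                                if (is.null(par$ambiguity)) 1L else par$ambiguity),
                   rule, n_iterations = n_iterations,
                   trials_per_session = trials_per_session, seed = seed)
  session_statistics(rec, window)
}

score_pool <- function(pool, target, top) {
  ref_hat <- if (target$mode == "complexity") pool$S_hat else pool$U_hat
  sc <- mapply(function(s, c) unlist(fitness_score(s, c, target)),
               ref_hat, pool$C_hat)
  out <- cbind(pool, D_session = sc["D_session", ], fitness = sc["fitness", ])
  out <- out[order(-out$fitness), ]
  rownames(out) <- NULL
  head(out, top)
}

#' Random-search fit of the agent to behavioral statistics
#'
#' Session-by-session mode: samples parameter sets (learning rate fixed at
#' 0.1; temperature log-uniform, U-turn cost uniform, memory uniform
#' integer), runs each to convergence under the rule, summarizes the
#' trailing 10 simulated sessions (200 trials each), and scores against the
#' target(s) with [fitness_score()]. When several session targets are given
#' the same simulated pool is scored against each (the asymptotic model
#' statistics do not depend on the session), giving directly comparable
#' per-session leaderboards.
#'
#' @param target a [fit_target()] or a list of them (one per session).
#' @param space a [default_search_space()].
#' @param budget number of sampled parameter sets, >= 1.
#' @param n_iterations trials per simulated run (default 2e5; raise toward
#'   2e6 for closer convergence).
#' @param rule a [task_rule()]; training targets are fitted under the
#'   training rule.
#' @param top leaderboard size (default 15 retained best fits).
#' @param alpha fixed learning rate of this mode.
#' @param ambiguity state-representation ambiguity of the fitted model.
#' @param seed RNG seed; identical seeds give identical leaderboards.
#' @return a leaderboard data frame (parameters, statistics, fitness),
#'   ranked by fitness; or a list of leaderboards for a list of targets,
#'   with the simulated pool attached as attribute \code{"pool"}.
#' @export
random_search <- function(target, space = default_search_space(),
                          budget = 100L, n_iterations = 2e5,
                          rule = task_rule("complexity"), top = 15L,
                          alpha = 0.1, ambiguity = 1L, seed = NULL) {
  if (budget < 1) stop("budget must be >= 1")
  if (length(space) == 0) stop("empty search space")
  single <- inherits(target, "fit_target")
  targets <- if (single) list(target) else target
  stopifnot(all(vapply(targets, inherits, logical(1), "fit_target")))
  with_seed(seed, {
    pars <- sample_space(space, budget, fixed_alpha = alpha)
    pars$ambiguity <- ambiguity
    pars$rho <- pars$tau / pars$kappa
    stats <- lapply(seq_len(budget), function(i) {
      asymptotic_statistics(pars[i, ], rule, n_iterations)
    })
    pool <- cbind(pars,
                  S_hat = vapply(stats, `[[`, numeric(1), "S_hat"),
                  C_hat = vapply(stats, `[[`, numeric(1), "C_hat"),
                  U_hat = vapply(stats, `[[`, numeric(1), "U_hat"))
    boards <- lapply(targets, score_pool, pool = pool, top = top)
    if (single) boards[[1]] else structure(boards, pool = pool)
  })
}

# simulate the continuous training-to-complexity schedule and score against
# per-session targets; used by both continuous random search and grid search
continuous_fitness <- function(par, targets, n_runs = 20L,
                               n_iterations = 4000L,
                               trials_per_session = 200L,
                               n_training = 10L) {
  n_sessions <- n_iterations / trials_per_session
  conditions <- rep(c("training", "complexity"),
                    c(n_training, n_sessions - n_training))
  scored_idx <- c(n_training, (n_training + 1L):n_sessions)
  fits <- vapply(seq_len(n_runs), function(run) {
    rec <- run_agent(agent_params(par$alpha, par$tau, par$kappa, par$memory,
                                  if (is.null(par$ambiguity)) 1L
                                  else par$ambiguity),
                     conditions, trials_per_session = trials_per_session,
                     n_trials_per_session = rep(trials_per_session,
                                                n_sessions))
    f <- mapply(function(si, tg) {
      r <- rec[[si]]
      s_hat <- if (tg$mode == "training") uturn_rate(r$locations)
               else success_rate(r)
      fitness_score(s_hat, nlzcomp(r$locations), tg)$fitness
    }, scored_idx, targets)
    mean(f)
  }, numeric(1))
  mean(fits)
}

#' Grid-search fit over the continuous schedule
#'
#' Scores every row of an explicit parameter grid on the continuous
#' schedule: each parameter set is run \code{n_runs} times for
#' \code{n_iterations} trials (10 training then complexity sessions of 200
#' trials), and its fitness is the mean over runs of the average fitness of
#' the last training session (U-turn term) and the complexity sessions. An
#' explicit grid keeps parameter values comparable across ambiguity levels.
#'
#' @param grid data frame with columns alpha, tau, kappa, memory, and
#'   optionally ambiguity.
#' @param targets list of [fit_target()]s, one for the last training
#'   session followed by one per complexity session.
#' @param n_runs runs per parameter set.
#' @param n_iterations trials per run.
#' @param top leaderboard size.
#' @param seed RNG seed.
#' @return leaderboard data frame ranked by fitness.
#' @export
grid_search <- function(grid, targets, n_runs = 20L, n_iterations = 4000L,
                        top = 15L, seed = NULL) {
  if (nrow(grid) == 0) stop("empty grid")
  stopifnot(all(vapply(targets, inherits, logical(1), "fit_target")))
  with_seed(seed, {
    fit <- vapply(seq_len(nrow(grid)), function(i)
      continuous_fitness(grid[i, ], targets, n_runs, n_iterations),
      numeric(1))
    out <- cbind(grid, fitness = fit)
    out$rho <- out$tau / out$kappa
    out <- out[order(-out$fitness), ]
    rownames(out) <- NULL
    head(out, top)
  })
}

#' Continuous-mode random search
#'
#' Like [grid_search()] but over sampled parameter sets (learning rate
#' searched log-uniformly instead of fixed).
#'
#' @inheritParams random_search
#' @inheritParams grid_search
#' @return leaderboard data frame ranked by fitness.
#' @export
random_search_continuous <- function(targets, space = default_search_space(),
                                     budget = 50L, n_runs = 20L,
                                     n_iterations = 4000L, top = 15L,
                                     ambiguity = 1L, seed = NULL) {
  if (budget < 1) stop("budget must be >= 1")
  with_seed(seed, {
    pars <- sample_space(space, budget)
    pars$ambiguity <- ambiguity
    grid_search(pars, targets, n_runs, n_iterations, top, seed = NULL)
  })
}

#' Approximate-Bayesian model comparison
#'
#' Likelihood-free evidence for the session-by-session model over the
#' continuous model: each model's likelihood is the fraction of its best
#' fits whose simulated (S, C) pair falls inside the 95% confidence
#' intervals of the behavioral data (averaged over sessions when several
#' are given), and the Bayes factor is their ratio. B > 3 is read as
#' substantial evidence; a zero denominator is reported as +Inf with a
#' flag rather than smoothed.
#'
#' @param fits_ind leaderboard (data frame with S_hat, C_hat) of the
#'   session-wise model, or a list of per-session leaderboards.
#' @param fits_con same for the continuous model.
#' @param ci list with \code{S = c(lo, hi)} and \code{C = c(lo, hi)}, or a
#'   list of such lists (one per session).
#' @return list with \code{lik_ind}, \code{lik_con}, \code{bayes_factor},
#'   \code{substantial}, \code{infinite}.
#' @export
bayes_factor <- function(fits_ind, fits_con, ci) {
  per_session <- !is.null(ci$S) || !is.null(ci[["C"]])
  cis <- if (per_session) list(ci) else ci
  lik <- function(fits) {
    boards <- if (is.data.frame(fits)) list(fits) else fits
    if (length(boards) != length(cis))
      boards <- rep(boards, length.out = length(cis))
    mean(mapply(function(b, ci1) {
      inside <- b$S_hat >= ci1$S[1] & b$S_hat <= ci1$S[2] &
        b$C_hat >= ci1$C[1] & b$C_hat <= ci1$C[2]
      mean(inside)
    }, boards, cis))
  }
  l_ind <- lik(fits_ind)
  l_con <- lik(fits_con)
  inf <- l_con == 0
  B <- if (inf) Inf else l_ind / l_con
  list(lik_ind = l_ind, lik_con = l_con, bayes_factor = B,
       substantial = inf || B > 3, infinite = inf)
}

#' Normal-theory 95% confidence interval across subjects
#'
#' @param x per-subject statistic values.
#' @return numeric \code{c(lo, hi)}.
#' @export
ci95 <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  half <- qt(0.975, length(x) - 1) * sd(x) / sqrt(length(x))
  c(m - half, m + half)
}
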