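#' Specification of a synthetic behavioral cohort
#'
#' Describes a cohort of mouse-like agents run through the task. Behavior is
#' generated by the package's own agent model with a per-session temperature
#' schedule: during training the randomness rho = tau/kappa is low (tight
#' circular trajectories), and across complexity sessions tau rises so that
#' rho increases, reproducing the progressive rise of success rate, NLZcomp
#' and U-turn rate seen in the behaving animals. Group G1 experiences
#' training, then complexity, then the probabilistic (p75) condition; group
#' G2 goes from training straight to p75. In p75 sessions each group keeps
#' the parameters of its preceding condition (the probabilistic reward gives
#' no gradient to move them).
#'
#' @param n_subjects cohort size (default 27).
#' @param n_training,n_complexity,n_p75 sessions per condition.
#' @param group \code{"G1"} (training, complexity, p75) or \code{"G2"}
#'   (training, p75).
#' @param trials_range per-session trial count range, drawn uniformly
#'   (default 100..200, bracketing 50-150 self-stimulations plus warm-up).
#' @param alpha,kappa,memory,ambiguity agent parameters shared by all
#'   sessions. The default memory of 1 is the smallest state that can
#'   represent U-turn aversion at all, which the circular training
#'   trajectories require.
#' @param tau_training temperature of training (and G2 p75) sessions; warm
#'   enough that the forward action is discovered everywhere before the
#'   U-turn value entrenches, cold enough that the converged U-turn rate is
#'   near 0.
#' @param tau_complexity temperature schedule across complexity sessions
#'   (length \code{n_complexity}; default geometric from 0.15 to 0.5, i.e.
#'   rho rising from 0.3 to 1).
#' @param seed master seed; per-subject seeds derive from it.
#' @return list of class \code{"cohort_spec"} with a per-session
#'   \code{schedule} data frame (condition, tau, kappa).
#' @export
cohort_spec <- function(n_subjects = 27L, n_training = 10L,
                        n_complexity = 10L, n_p75 = 0L,
                        group = c("G1", "G2"),
                        trials_range = c(100L, 200L),
                        alpha = 0.1, kappa = 0.5, memory = 1L,
                        ambiguity = 1L, tau_training = 0.15,
                        tau_complexity = NULL, seed = 1L) {
  group <- match.arg(group)
  if (group == "G2") n_complexity <- 0L
  if (is.null(tau_complexity) && n_complexity > 0L)
    tau_complexity <- exp(seq(log(0.15), log(0.5),
                              length.out = n_complexity))
  if (n_complexity > 0L && length(tau_complexity) != n_complexity)
    stop("tau_complexity must have one entry per complexity session")
  tau_p75 <- if (n_complexity > 0L)
    tau_complexity[n_complexity] else tau_training
  schedule <- data.frame(
    condition = rep(c("training", "complexity", "p75"),
                    c(n_training, n_complexity, n_p75)),
    tau = c(rep(tau_training, n_training), tau_complexity,
            rep(tau_p75, n_p75)),
    kappa = kappa, stringsAsFactors = FALSE)
  structure(list(n_subjects = as.integer(n_subjects), group = group,
                 trials_range = as.integer(trials_range), alpha = alpha,
                 kappa = kappa, memory = as.integer(memory),
                 ambiguity = as.integer(ambiguity), schedule = schedule,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Runs one agent per subject through the scheduled conditions (value table
#' carried across sessions, task history reset each session) and returns all
#' session records plus a provenance manifest. Fully reproducible from the
#' spec's master seed. Optionally writes the session CSV files and manifest.
#'
#' @param spec a [cohort_spec()].
#' @param dir optional directory to write session files into.
#' @return list of class \code{"cohort"}: \code{records} (flat list of
#'   [session_record()]s), \code{spec}, \code{manifest}.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  sched <- spec$schedule
  n_sessions <- nrow(sched)
  subject_seeds <- with_seed(spec$seed,
                             sample.int(.Machine$integer.max - 1L,
                                        spec$n_subjects))
  records <- list()
  for (i in seq_len(spec$n_subjects)) {
    sid <- sprintf("%s_m%02d", spec$group, i)
    recs <- with_seed(subject_seeds[i], {
      n_trials <- sample(spec$trials_range[1]:spec$trials_range[2],
                         n_sessions, replace = TRUE)
      run_agent(agent_params(spec$alpha, sched$tau, sched$kappa,
                             spec$memory, spec$ambiguity),
                sched$condition, n_trials_per_session = n_trials,
                subject_id = sid)
    })
    # session_index within condition, as in the behavioral bookkeeping
    for (k in seq_along(recs)) {
      recs[[k]]$session_index <-
        sum(sched$condition[seq_len(k)] == sched$condition[k])
    }
    records <- c(records, recs)
  }
  manifest <- list(group = spec$group, n_subjects = spec$n_subjects,
                   schedule = sched, trials_range = spec$trials_range,
                   alpha = spec$alpha, memory = spec$memory,
                   ambiguity = spec$ambiguity, seed = spec$seed,
                   subject_seeds = subject_seeds)
  out <- structure(list(records = records, spec = spec,
                        manifest = manifest), class = "cohort")
  if (!is.null(dir)) {
    write_sessions(records, dir)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", x$spec$group, ": ", x$spec$n_subjects, " subjects, ",
      length(x$records), " sessions\n", sep = "")
  invisible(x)
}

#' Deterministic fixtures for the analysis pipeline
#'
#' Small canned sequences/sessions with known structure: \code{repetitive}
#' (circular ABC pattern), \code{random} (one constrained surrogate),
#' \code{wsls} and \code{greedy} (runs of the corresponding
#' [baseline_policy()] under the complexity rule, returned as session
#' records), and \code{first_order_markov} (directions drawn from a kernel
#' with P(repeat direction) = \code{p_stay}, decoded to locations).
#'
#' @param kind fixture type.
#' @param length trials.
#' @param seed RNG seed.
#' @param p_stay direction-repeat probability of the Markov fixture.
#' @return a choice sequence, or a [session_record()] for the policy
#'   fixtures.
#' @export
make_fixture <- function(kind = c("repetitive", "random", "wsls",
                                  "first_order_markov", "greedy"),
                         length = 60L, seed = 1L, p_stay = 0.7) {
  kind <- match.arg(kind)
  switch(kind,
    repetitive = as_choice_sequence(
      rep(LOCATIONS, length.out = length)),
    random = generate_surrogates(length, 1L, seed = seed)[[1]],
    first_order_markov = with_seed(seed, {
      dirs <- character(length - 1L)
      dirs[1] <- sample(c("L", "R"), 1)
      for (i in 2:(length - 1L)) {
        stay <- runif(1) < p_stay
        dirs[i] <- if (stay) dirs[i - 1L] else setdiff(c("L", "R"),
                                                       dirs[i - 1L])
      }
      decode_directions(dirs, start = "A")
    }),
    wsls = baseline_policy("wsls", task_rule("complexity"),
                           n_iterations = length, seed = seed)[[1]],
    greedy = baseline_policy("greedy_oracle", task_rule("complexity"),
                             n_iterations = length, seed = seed)[[1]])
}
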