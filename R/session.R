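#' Construct a behavioral session record
#'
#' One session = one uninterrupted run of choices by one subject under one
#' reward condition, with per-trial reward flags and an optional validity
#' mask (trials whose reward attribution is uncertain can be masked out of
#' reward-conditioned analyses).
#'
#' @param locations choice sequence of visited targets.
#' @param rewarded integer 0/1 flags, one per trial.
#' @param condition \code{"training"}, \code{"complexity"} or \code{"p75"}.
#' @param subject_id subject identifier.
#' @param session_index 1-based session number within the condition.
#' @param valid optional 0/1 validity mask (default all valid).
#' @param warmup warm-up convention the rewards were produced under.
#' @return list of class \code{"session_record"}.
#' @export
session_record <- function(locations, rewarded,
                           condition = c("complexity", "training", "p75"),
                           subject_id = "S1", session_index = 1L,
                           valid = NULL,
                           warmup = c("reward_all", "skip")) {
  condition <- match.arg(condition)
  warmup <- match.arg(warmup)
  locations <- as_choice_sequence(locations)
  rewarded <- as.integer(rewarded)
  if (length(rewarded) != length(locations))
    stop("rewarded must have one flag per trial")
  if (any(!rewarded %in% c(0L, 1L))) stop("rewarded flags must be 0/1")
  if (condition == "training" && any(rewarded == 0L))
    stop("training sessions reward every trial")
  if (is.null(valid)) valid <- rep(1L, length(locations))
  valid <- as.integer(valid)
  if (length(valid) != length(locations) || any(!valid %in% c(0L, 1L)))
    stop("valid must be a 0/1 mask, one per trial")
  structure(list(subject_id = as.character(subject_id),
                 condition = condition,
                 session_index = as.integer(session_index),
                 locations = locations, rewarded = rewarded, valid = valid,
                 warmup = warmup),
            class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat("<session_record> ", x$subject_id, " ", x$condition, x$session_index,
      ": ", length(x$locations), " trials, success ",
      round(success_rate(x), 3), "\n", sep = "")
  invisible(x)
}

#' Session success rate
#'
#' Fraction of rewarded trials over the whole session.
#'
#' @param session a [session_record()].
#' @return fraction in \[0, 1\].
#' @export
success_rate <- function(session) {
  stopifnot(inherits(session, "session_record"))
  mean(session$rewarded)
}
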