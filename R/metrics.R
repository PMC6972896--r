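# surrogate-ensemble cache (mean LZ by length / n / seed), so NLZcomp across
# equal-length sessions shares one normalizer and stays comparable
.metric_cache <- new.env(parent = emptyenv())

# default seed of the normalizer stream; one fixed stream makes NLZcomp a
# deterministic function of the sequence
SURROGATE_SEED <- 20200121L

#' Constrained random surrogate sequences
#'
#' Surrogates emulate a memoryless chooser under the apparatus constraint:
#' first location uniform over the three targets, every next location
#' uniform over the two legal ones. They are the normalizer and the null
#' distribution of the variability statistics.
#'
#' @param length trials per surrogate, >= 1.
#' @param count number of surrogates.
#' @param seed optional RNG seed.
#' @return list of [as_choice_sequence()] objects.
#' @export
generate_surrogates <- function(length, count = 1000L, seed = NULL) {
  if (length < 1) stop("length must be >= 1")
  m <- with_seed(seed, surrogates_cpp(as.integer(length), as.integer(count)))
  lapply(seq_len(ncol(m)), function(j) int_to_seq(m[, j]))
}

# mean LZ of `count` surrogates of this length, cached
surrogate_mean_lz <- function(length, count = 1000L, seed = SURROGATE_SEED) {
  key <- sprintf("L%d_n%d_s%d", length, count, seed)
  hit <- .metric_cache[[key]]
  if (!is.null(hit)) return(hit)
  m <- with_seed(seed, surrogates_cpp(as.integer(length), as.integer(count)))
  val <- mean(lz_complexity_cols(m))
  assign(key, val, envir = .metric_cache)
  val
}

# raw surrogate LZ counts (for the significance test), cached
surrogate_lz_counts <- function(length, count = 1000L, seed = SURROGATE_SEED) {
  key <- sprintf("C%d_n%d_s%d", length, count, seed)
  hit <- .metric_cache[[key]]
  if (!is.null(hit)) return(hit)
  m <- with_seed(seed, surrogates_cpp(as.integer(length), as.integer(count)))
  val <- lz_complexity_cols(m)
  assign(key, val, envir = .metric_cache)
  val
}

#' Normalized LZ complexity (NLZcomp)
#'
#' LZ complexity of the sequence divided by the mean LZ complexity of
#' \code{n_surrogates} constrained random sequences of the same length.
#' Close to 1 for uncorrelated random choice, far below 1 for repetitive
#' sequences. The surrogate ensemble is drawn from its own fixed-seed stream
#' and cached by (length, count, seed), so sessions of equal length share a
#' normalizer.
#'
#' @param seq a choice sequence, length >= 2.
#' @param n_surrogates surrogates in the normalizer.
#' @param seed seed of the surrogate stream.
#' @return positive real.
#' @export
nlzcomp <- function(seq, n_surrogates = 1000L, seed = SURROGATE_SEED) {
  seq <- as_choice_sequence(seq)
  if (length(seq) < 2L) stop("nlzcomp needs length >= 2")
  lz_complexity(seq) / surrogate_mean_lz(length(seq), n_surrogates, seed)
}

#' Diagonal-line entropy from recurrence quantification (RQA ENT)
#'
#' Builds the symbolic recurrence plot (recurrent where two trials share a
#' location), excludes the line of identity, collects the maximal diagonal
#' runs of length >= \code{l_min} in the upper triangle, and returns the
#' Shannon entropy (natural log) of the empirical distribution of run
#' lengths. Diagonal lines mark recurring choice patterns, so the entropy is
#' high for structured, repetitive sequences and low for uncorrelated ones;
#' it is 0 when at most one distinct run length occurs.
#'
#' @param seq a symbolic sequence (any single-character alphabet; the
#'   no-repeat constraint is not required), length > \code{l_min}.
#' @param l_min minimal diagonal length counted (default 2).
#' @return entropy in nats.
#' @examples
#' rqa_entropy(strrep("ABC", 10))  # log(9): nine distinct diagonal lengths
#' @export
rqa_entropy <- function(seq, l_min = 2L) {
  s <- if (is.character(seq) && length(seq) == 1L && nchar(seq) > 1L)
    strsplit(seq, "")[[1]] else unclass(seq)
  if (!length(s) || any(is.na(s))) stop("invalid sequence")
  n <- length(s)
  if (n <= l_min) stop("sequence too short for RQA (need length > l_min)")
  lengths <- integer(0)
  for (k in 1:(n - 1L)) {           # upper-triangle diagonals, offset k
    d <- s[1:(n - k)] == s[(1 + k):n]
    r <- rle(d)
    runs <- r$lengths[r$values]
    lengths <- c(lengths, runs[runs >= l_min])
  }
  if (length(lengths) == 0L) return(0)
  p <- table(lengths) / length(lengths)
  if (length(p) <= 1L) return(0)
  -sum(p * log(p))
}

#' U-turn rate of a choice sequence
#'
#' A U-turn at trial t is a return to the location visited two trials
#' earlier (A, B, A). The first two trials have no defined U-turn, so the
#' rate is taken over trials 3..T.
#'
#' @param seq a choice sequence, length >= 3.
#' @return fraction in \[0, 1\].
#' @export
uturn_rate <- function(seq) {
  seq <- unclass(as_choice_sequence(seq))
  n <- length(seq)
  if (n < 3L) stop("uturn_rate needs length >= 3")
  mean(seq[3:n] == seq[1:(n - 2L)])
}

#' Surrogate randomness test of a choice sequence
#'
#' Ranks the observed raw LZ complexity within the LZ distribution of
#' \code{n_surrogates} constrained random sequences of the same length and
#' returns the two-sided empirical p-value with the (r + 1)/(B + 1)
#' correction. A sequence with p > alpha is flagged indistinguishable from
#' the random surrogates.
#'
#' @param seq a choice sequence, length >= 10.
#' @param n_surrogates ensemble size.
#' @param alpha significance level of the flag.
#' @param seed seed of the surrogate stream.
#' @return list with \code{p_value}, \code{indistinguishable},
#'   \code{lz_observed}.
#' @export
surrogate_test <- function(seq, n_surrogates = 1000L, alpha = 0.05,
                           seed = SURROGATE_SEED) {
  seq <- as_choice_sequence(seq)
  if (length(seq) < 10L) stop("surrogate_test needs length >= 10")
  obs <- lz_complexity(seq)
  null_counts <- surrogate_lz_counts(length(seq), n_surrogates, seed)
  B <- length(null_counts)
  p_lo <- (sum(null_counts <= obs) + 1) / (B + 1)
  p_hi <- (sum(null_counts >= obs) + 1) / (B + 1)
  p <- min(1, 2 * min(p_lo, p_hi))
  list(p_value = p, indistinguishable = p > alpha, lz_observed = obs)
}

#' Histogram of length-k choice patterns
#'
#' Slides a window of \code{k} trials over each sequence, keeps the windows
#' starting at location A (every pattern appears, relabeled, starting from
#' each location, so one start anchors the bookkeeping), and counts
#' occurrences. Patterns are ordered by the decision-tree prefix order
#' (lexicographic), so neighboring branches share prefixes; the ranked
#' cumulative distribution summarizes how concentrated the behavior is on
#' few patterns.
#'
#' @param seqs one choice sequence or a list of them.
#' @param k pattern length (default 10, the task window).
#' @return list of class \code{"pattern_histogram"}: \code{counts} (named,
#'   tree-ordered), \code{n_windows}, \code{ranked_cumulative} (descending
#'   counts, cumulative fractions).
#' @export
pattern_histogram <- function(seqs, k = 10L) {
  if (!is.list(seqs)) seqs <- list(seqs)
  pats <- unlist(lapply(seqs, function(s) {
    s <- unclass(as_choice_sequence(s))
    if (length(s) < k) stop("each sequence must be at least k trials long")
    starts <- which(s == "A")
    starts <- starts[starts <= length(s) - k + 1L]
    vapply(starts, function(i) paste(s[i:(i + k - 1L)], collapse = ""),
           character(1))
  }))
  counts <- table(factor(pats))
  counts <- counts[order(names(counts))]          # tree prefix order
  ranked <- sort(as.integer(counts), decreasing = TRUE)
  structure(list(counts = counts,
                 n_windows = length(pats),
                 ranked_cumulative = cumsum(ranked) / sum(ranked)),
            class = "pattern_histogram")
}

#' Variability report for one session
#'
#' Bundles the session-level statistics used throughout the analyses:
#' success rate, NLZcomp, RQA diagonal entropy, U-turn rate and the
#' surrogate randomness test.
#'
#' @param session a [session_record()].
#' @param n_surrogates ensemble size for NLZcomp and the test.
#' @param seed surrogate stream seed.
#' @return list of class \code{"metrics_report"}.
#' @export
metrics_report <- function(session, n_surrogates = 1000L,
                           seed = SURROGATE_SEED) {
  stopifnot(inherits(session, "session_record"))
  st <- surrogate_test(session$locations, n_surrogates, seed = seed)
  structure(list(subject_id = session$subject_id,
                 condition = session$condition,
                 session_index = session$session_index,
                 n_trials = length(session$locations),
                 success_rate = success_rate(session),
                 nlzcomp = nlzcomp(session$locations, n_surrogates, seed),
                 rqa_ent = rqa_entropy(session$locations),
                 uturn_rate = uturn_rate(session$locations),
                 surrogate_p = st$p_value,
                 indistinguishable = st$indistinguishable),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> ", x$subject_id, " ", x$condition, x$session_index,
      ": S=", round(x$success_rate, 3), " C=", round(x$nlzcomp, 3),
      " ENT=", round(x$rqa_ent, 3), " U=", round(x$uturn_rate, 3),
      " p_surr=", signif(x$surrogate_p, 3), "\n", sep = "")
  invisible(x)
}
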