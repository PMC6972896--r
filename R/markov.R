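#' Encode a choice sequence as movement directions
#'
#' Each transition between targets is a movement to the right (R: A to B,
#' B to C, C to A) or to the left (L: the reverses). Pooling the three
#' targets into two directions triples the data per symbol and makes a
#' U-turn exactly a direction change.
#'
#' @param seq a choice sequence, length >= 2.
#' @return character vector over \{L, R\} of length \code{length(seq) - 1}.
#' @examples
#' encode_directions("ABCA")  # "R" "R" "R"
#' @export
encode_directions <- function(seq) {
  s <- seq_to_int(seq)
  if (length(s) < 2L) stop("need at least 2 locations to encode a direction")
  d <- (s[-1] - s[-length(s)]) %% 3
  c("R", "L")[d]          # +1 mod 3 = R, +2 mod 3 = L
}

#' Rebuild a choice sequence from directions and a start location
#'
#' Inverse of [encode_directions()].
#'
#' @param dirs character vector over \{L, R\}.
#' @param start starting location.
#' @return choice sequence of length \code{length(dirs) + 1}.
#' @export
decode_directions <- function(dirs, start = "A") {
  step <- ifelse(dirs == "R", 1L, 2L)
  if (any(!dirs %in% c("L", "R"))) stop("directions must be L or R")
  int_to_seq(cumsum(c(match(start, LOCATIONS) - 1L, step)) %% 3L)
}

#' Conditional direction probabilities up to a Markov order
#'
#' Maximum-likelihood estimates of P(X), P(X | Y), P(X | YZ) for directions
#' X, Y, Z in \{L, R\} from transition counts. Context strings are written
#' oldest first, so \code{"LR"} conditions on L two steps back and R
#' immediately before. Contexts never observed are reported as NA (no
#' smoothing).
#'
#' @param dirseq direction sequence from [encode_directions()].
#' @param max_order highest conditioning order (default 2).
#' @return list of class \code{"conditional_table"}: one data frame per
#'   order with columns context, P_L, P_R, n.
#' @export
conditional_probabilities <- function(dirseq, max_order = 2L) {
  if (any(!dirseq %in% c("L", "R"))) stop("directions must be L or R")
  n <- length(dirseq)
  if (n < max_order + 1L)
    stop("need at least max_order + 1 directions")
  orders <- lapply(0:max_order, function(k) {
    ctxs <- if (k == 0L) "" else
      apply(expand.grid(rep(list(c("L", "R")), k))[, k:1, drop = FALSE], 1,
            paste, collapse = "")
    ctxs <- sort(unique(ctxs))
    rows <- lapply(ctxs, function(ctx) {
      if (k == 0L) {
        nxt <- dirseq
      } else {
        pos <- seq_len(n - k)
        ctx_at <- vapply(pos, function(i)
          paste(dirseq[i:(i + k - 1L)], collapse = ""), character(1))
        nxt <- dirseq[pos[ctx_at == ctx] + k]
      }
      m <- length(nxt)
      data.frame(context = ctx,
                 P_L = if (m > 0) mean(nxt == "L") else NA_real_,
                 P_R = if (m > 0) mean(nxt == "R") else NA_real_,
                 n = m, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  names(orders) <- paste0("order", 0:max_order)
  structure(orders, class = "conditional_table")
}

#' Paired per-subject comparisons across Markov orders
#'
#' Assembles, for a cohort of subjects, the paired vectors that a paired
#' test consumes: each unconditional probability against the conditionals
#' one order deeper (P(X) vs P(X | Y), and P(X | Y) vs P(X | YZ)). A
#' first-order process shows a shift in the first comparison and none in
#' the second.
#'
#' @param tables list of [conditional_probabilities()] results, one per
#'   subject (>= 2 subjects).
#' @return data frame with columns subject, comparison (e.g.
#'   \code{"P(L) vs P(L|R)"}), order_pair (\code{"0v1"} or \code{"1v2"}),
#'   lower (the shallower estimate), higher (the deeper one).
#' @export
markov_order_summary <- function(tables) {
  if (length(tables) < 2L) stop("pairing requires at least 2 subjects")
  one <- function(tab, subject) {
    stopifnot(inherits(tab, "conditional_table"))
    rows <- list()
    for (X in c("L", "R")) {
      pX <- tab$order0[[paste0("P_", X)]][1]
      for (Y in c("L", "R")) {
        pXY <- tab$order1[[paste0("P_", X)]][tab$order1$context == Y]
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subject,
          comparison = sprintf("P(%s) vs P(%s|%s)", X, X, Y),
          order_pair = "0v1", lower = pX, higher = pXY,
          stringsAsFactors = FALSE)
        for (Z in c("L", "R")) {
          ctx2 <- paste0(Z, Y)     # Z two back, Y immediately before
          pXYZ <- tab$order2[[paste0("P_", X)]][tab$order2$context == ctx2]
          rows[[length(rows) + 1L]] <- data.frame(
            subject = subject,
            comparison = sprintf("P(%s|%s) vs P(%s|%s)", X, Y, X, ctx2),
            order_pair = "1v2", lower = pXY, higher = pXYZ,
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  }
  ids <- if (!is.null(names(tables))) names(tables) else
    paste0("S", seq_along(tables))
  do.call(rbind, Map(one, tables, ids))
}

#' Forward / U-turn probabilities conditioned on the previous reward
#'
#' Going forward (F) repeats the previous movement direction; a U-turn (U)
#' reverses it. A win-stay-lose-switch chooser ties these to the previous
#' trial's outcome, so comparing P(F) and P(U) with their reward-conditioned
#' versions tests whether the outcome steers the next transition. Trials
#' masked invalid (or following an invalid trial) are excluded. Contexts
#' with no observations (e.g. unrewarded trials in a training session) are
#' NA.
#'
#' @param session a [session_record()] with length >= 3.
#' @return data frame with columns probability (\code{"P(F)"},
#'   \code{"P(U)"}, \code{"P(F|rw)"}, \code{"P(F|unrw)"}, \code{"P(U|rw)"},
#'   \code{"P(U|unrw)"}), value, n.
#' @export
reward_conditioned_probs <- function(session) {
  stopifnot(inherits(session, "session_record"))
  s <- unclass(session$locations)
  n <- length(s)
  if (n < 3L) stop("need at least 3 trials")
  t <- 3:n
  uturn <- s[t] == s[t - 2L]
  prev_rw <- session$rewarded[t - 1L] == 1L
  ok <- session$valid[t] == 1L & session$valid[t - 1L] == 1L
  est <- function(x) if (length(x)) mean(x) else NA_real_
  rows <- list(
    c("P(F)", est(!uturn[ok]), sum(ok)),
    c("P(U)", est(uturn[ok]), sum(ok)),
    c("P(F|rw)", est(!uturn[ok & prev_rw]), sum(ok & prev_rw)),
    c("P(F|unrw)", est(!uturn[ok & !prev_rw]), sum(ok & !prev_rw)),
    c("P(U|rw)", est(uturn[ok & prev_rw]), sum(ok & prev_rw)),
    c("P(U|unrw)", est(uturn[ok & !prev_rw]), sum(ok & !prev_rw)))
  data.frame(probability = vapply(rows, `[`, character(1), 1),
             value = as.numeric(vapply(rows, `[`, character(1), 2)),
             n = as.integer(vapply(rows, `[`, character(1), 3)),
             stringsAsFactors = FALSE)
}
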