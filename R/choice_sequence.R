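#' @useDynLib complexitask, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif sd qt quantile cor
#' @importFrom utils head tail write.csv read.csv
NULL

# location alphabet; integer codes 0, 1, 2 on the C++ side
LOCATIONS <- c("A", "B", "C")

#' Validate and normalize a choice sequence
#'
#' A choice sequence is an ordered run of target locations from
#' \code{{A, B, C}} in which no two consecutive locations are equal (the
#' apparatus never rewards the same location twice in a row, so a repeat is
#' not a legal trial). Input may be a character vector of single letters or a
#' single collapsed string such as \code{"ABCAB"}.
#'
#' @param x character vector of locations, or one collapsed string.
#' @return character vector of single locations with class
#'   \code{"choice_sequence"}.
#' @examples
#' as_choice_sequence("ABCAB")
#' @export
as_choice_sequence <- function(x) {
  if (inherits(x, "choice_sequence")) return(x)
  if (is.numeric(x)) x <- LOCATIONS[x + 1L]
  if (!is.character(x)) stop("choice sequence must be character")
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "")[[1]]
  if (length(x) < 1L) stop("choice sequence must have length >= 1")
  bad <- which(!x %in% LOCATIONS)
  if (length(bad)) {
    stop("invalid location '", x[bad[1]], "' at position ", bad[1])
  }
  rep_at <- which(x[-1] == x[-length(x)])
  if (length(rep_at)) {
    stop("consecutive repeat of location '", x[rep_at[1] + 1L],
         "' at position ", rep_at[1] + 1L)
  }
  structure(x, class = "choice_sequence")
}

# integer codes 0..2 for the C++ kernels
seq_to_int <- function(x) {
  match(unclass(as_choice_sequence(x)), LOCATIONS) - 1L
}

int_to_seq <- function(i) as_choice_sequence(LOCATIONS[i + 1L])

#' @export
print.choice_sequence <- function(x, ...) {
  cat("<choice_sequence> length ", length(x), ": ",
      paste(head(unclass(x), 40), collapse = ""),
      if (length(x) > 40) "..." else "", "\n", sep = "")
  invisible(x)
}

# Evaluate an expression under a temporary RNG state; the caller's stream is
# untouched. Used wherever a function takes its own seed.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
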