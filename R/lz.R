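#' Lempel-Ziv (LZ76) complexity of a symbolic sequence
#'
#' Parses the sequence into its exhaustive production history and counts the
#' components that terminate in an innovation (a symbol that could not be
#' copied from the already-produced prefix, overlap-copying allowed). A
#' terminal component that is fully reproducible from its prefix does not add
#' to the count. The count is a proxy for the compressibility, hence the
#' randomness, of the sequence.
#'
#' Any finite single-character alphabet is accepted; the no-repeat constraint
#' of the behavioral task is not required at this level.
#'
#' @param x a sequence: character vector of single symbols, or one collapsed
#'   string (e.g. \code{"ABCABCABCA"}).
#' @return non-negative integer complexity count.
#' @examples
#' lz_complexity("A")            # 1
#' lz_complexity("ABCABCABCA")   # 3: A.B.C + reproducible tail
#' lz_complexity("ABCABCABCB")   # 4: the tail ends with an innovation
#' @export
lz_complexity <- function(x) {
  if (is.character(x) && length(x) == 1L) x <- strsplit(x, "")[[1]]
  if (length(x) < 1L || any(is.na(x)) ||
      (is.character(x) && any(!nzchar(x)))) {
    stop("lz_complexity requires a non-empty sequence of symbols")
  }
  codes <- if (is.numeric(x)) as.integer(x) else {
    as.integer(factor(x)) - 1L
  }
  lz76_int_cpp(codes)
}

# LZ counts for many equal-length sequences given as columns of an integer
# matrix of location codes (0..2); used by enumeration and surrogate scoring.
lz_complexity_cols <- function(m) lz76_cols_cpp(m)
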