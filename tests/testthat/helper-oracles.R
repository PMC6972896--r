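# Independent reference implementations used to cross-check the package.
# Both are deliberately naive and share no code with the implementation.

# LZ76 by direct definition: at each position take the longest extension that
# re-occurs starting earlier in the string (overlap allowed), plus one
# innovation symbol; a fully reproducible tail ends no component.
lz_oracle <- function(s) {
  if (is.character(s) && length(s) == 1L && nchar(s) > 1L)
    s <- strsplit(s, "")[[1]]
  str <- paste(s, collapse = "")
  n <- length(s)
  stopifnot(n >= 1L)
  count <- 0L
  i <- 1L
  while (i <= n) {
    l <- 0L
    repeat {
      if (i + l > n) break
      pat <- substr(str, i, i + l)
      starts <- gregexpr(pat, str, fixed = TRUE)[[1]]
      if (any(starts != -1L & starts < i)) l <- l + 1L else break
    }
    if (i + l <= n) {
      count <- count + 1L
      i <- i + l + 1L
    } else {
      i <- n + 1L
    }
  }
  count
}

# Diagonal-line entropy from an explicitly constructed recurrence matrix.
rqa_oracle <- function(s, l_min = 2L) {
  if (is.character(s) && length(s) == 1L && nchar(s) > 1L)
    s <- strsplit(s, "")[[1]]
  n <- length(s)
  R <- outer(s, s, "==")
  lens <- integer(0)
  for (k in 1:(n - 1L)) {       # upper-triangle diagonals
    run <- 0L
    for (i in 1:(n - k)) {
      if (R[i, i + k]) {
        run <- run + 1L
      } else {
        if (run >= l_min) lens <- c(lens, run)
        run <- 0L
      }
    }
    if (run >= l_min) lens <- c(lens, run)
  }
  if (length(lens) == 0L) return(0)
  p <- as.numeric(table(lens)) / length(lens)
  if (length(p) <= 1L) return(0)
  -sum(p * log(p))
}

# all strings of a given length over an alphabet, as a character vector
all_strings <- function(len, alphabet = c("A", "B", "C")) {
  g <- do.call(expand.grid, rep(list(alphabet), len))
  apply(g, 1, paste, collapse = "")
}

# random no-repeat sequence via the package's surrogate generator
random_norepeat <- function(len, seed) {
  generate_surrogates(len, 1L, seed = seed)[[1]]
}
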