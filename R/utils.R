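# internal helpers shared across modules

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
# stream; seed = NULL runs under the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialize .Random.seed
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed from a base seed and a stream label,
# kept within the 32-bit integer range.
derive_seed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h * 131 + index) %% 2147483563) + 1L
}

is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == trunc(x)
}

# Nearest even integer, ties (odd integers, exact midpoints) rounded upward.
round_even <- function(x) {
  lo <- 2 * floor(x / 2)
  hi <- lo + 2
  ifelse(x - lo < hi - x, lo, hi)
}
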