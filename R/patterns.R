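#' Binary population activity pattern with an exact active-cell count
#'
#' A `binary_pattern` represents the spiking state of a population of `length`
#' cells within one gamma window as a binary vector, stored sparsely as the
#' sorted set of active cell indices. Patterns always have an exact number of
#' active cells `k` — they are samples from the fixed-count ensemble, not
#' independent Bernoulli draws — matching the convention that every input
#' pattern activates the same number of presynaptic cells.
#'
#' Indices are 1-based in R; the plain-text pattern file format
#' (see [write_patterns()]) uses 0-based indices.
#'
#' @param length Positive integer, the number of cells N in the population.
#' @param active Integer vector of active cell indices in `1:length`, without
#'   duplicates (any order; stored sorted).
#' @return An object of class `binary_pattern` with fields `length`, `active`
#'   (sorted integer vector) and `k = length(active)`.
#' @examples
#' p <- binary_pattern(10, c(2, 5, 9))
#' p$k
#' as.integer(p) # dense 0/1 vector
#' @seealso [random_pattern()], [hamming()], [pair_with_hd()]
#' @export
binary_pattern <- function(length, active = integer(0)) {
  stopifnot(is_count(length, min = 0))
  length <- as.integer(length)
  active <- as.integer(active)
  if (anyNA(active)) stop("active indices must not contain NA")
  if (anyDuplicated(active)) stop("active indices must be distinct")
  if (any(active < 1L) || any(active > length)) {
    stop("active indices must lie in 1..length")
  }
  structure(
    list(length = length, active = sort(active), k = base::length(active)),
    class = "binary_pattern"
  )
}

#' @export
print.binary_pattern <- function(x, ...) {
  cat(sprintf("<binary_pattern> N = %d, k = %d active (%.2f%%)\n",
              x$length, x$k, 100 * x$k / max(1L, x$length)))
  invisible(x)
}

#' @export
as.integer.binary_pattern <- function(x, ...) {
  v <- integer(x$length)
  v[x$active] <- 1L
  v
}

#' @export
`==.binary_pattern` <- function(e1, e2) {
  e1$length == e2$length && identical(e1$active, e2$active)
}

is_binary_pattern <- function(x) inherits(x, "binary_pattern")

#' Hamming distance between two binary patterns
#'
#' The Hamming distance between two equal-length binary vectors is the number
#' of components at which they differ; for sparse patterns this is the size of
#' the symmetric difference of their active sets. It is the metric used for
#' both network inputs (CA3/EC spiking patterns) and network outputs (CA1
#' spiking patterns).
#'
#' For two patterns with the same active count k the distance is always even:
#' every cell active only in `a` is matched by one active only in `b`.
#'
#' @param a,b `binary_pattern` objects with equal `length`.
#' @return Non-negative integer Hamming distance.
#' @examples
#' v0 <- binary_pattern(5, integer(0))
#' v1 <- binary_pattern(5, c(2, 4, 5))
#' v2 <- binary_pattern(5, c(2, 3, 4))
#' hamming(v0, v1) # 3
#' hamming(v1, v2) # 2
#' @export
hamming <- function(a, b) {
  stopifnot(is_binary_pattern(a), is_binary_pattern(b))
  if (a$length != b$length) {
    stop(sprintf("pattern dimensions differ (%d vs %d)", a$length, b$length))
  }
  shared <- sum(a$active %in% b$active)
  (a$k - shared) + (b$k - shared)
}

#' Maximal Hamming distance between equal-count patterns
#'
#' For two binary vectors of length `length` that each have exactly `k` ones,
#' the largest achievable Hamming distance is `min(2k, 2(length - k))`:
#' disjoint active sets when they fit, otherwise limited by the number of
#' zero components available.
#'
#' @param length Population size N.
#' @param k Active-cell count, `0 <= k <= length`.
#' @return Even integer, the maximal Hamming distance.
#' @examples
#' max_hd(28009, 1540) # 3080
#' max_hd(45073, 3086) # 6172
#' @export
max_hd <- function(length, k) {
  stopifnot(is_count(length, min = 0), is_count(k))
  if (k > length) stop("k must satisfy 0 <= k <= length")
  as.integer(2 * min(k, length - k))
}

#' Draw a uniform random pattern with exactly k active cells
#'
#' Samples `k` distinct cell indices uniformly without replacement, i.e. a
#' uniform draw from the fixed-count ensemble of patterns.
#'
#' @inheritParams max_hd
#' @param seed Optional integer seed; when given the draw is reproducible and
#'   the caller's RNG stream is left untouched.
#' @return A [binary_pattern()].
#' @export
random_pattern <- function(length, k, seed = NULL) {
  stopifnot(is_count(length, min = 0), is_count(k))
  if (k > length) stop("k must satisfy 0 <= k <= length")
  with_seed(seed, {
    binary_pattern(length, sample.int(length, k))
  })
}

#' Target Hamming distance for "similar" pattern pairs
#'
#' Similar pairs are defined by a small fraction (default 2%) of the maximal
#' achievable Hamming distance for the given population size and active count.
#' Because equal-count patterns are always an even distance apart, the product
#' `fraction * max_hd` is rounded to the nearest even integer, ties upward
#' (e.g. 0.02 x 3080 = 61.6 becomes 62).
#'
#' @inheritParams max_hd
#' @param fraction Proportion of the maximal Hamming distance, in (0, 1].
#' @return Even integer target Hamming distance.
#' @examples
#' similar_hd(28009, 1540) # 62
#' similar_hd(45073, 3086) # 124
#' @export
similar_hd <- function(length, k, fraction = 0.02) {
  stopifnot(is.numeric(fraction), length(fraction) == 1L,
            fraction > 0, fraction <= 1)
  as.integer(round_even(fraction * max_hd(length, k)))
}

#' Target Hamming distance for "distinct" pattern pairs
#'
#' Distinct pairs sit at the chance level: their Hamming distance equals the
#' mean of the binomial null distribution of distances between independent
#' random patterns with per-cell activity `p = k/length`
#' (see [binomial_hd_stats()]), rounded to the nearest even integer. At this
#' distance the two patterns share exactly the chance-expected number
#' `k^2/length` of active cells.
#'
#' @inheritParams max_hd
#' @return Even integer target Hamming distance.
#' @examples
#' distinct_hd(28009, 1540) # 2910
#' distinct_hd(45073, 3086) # 5750
#' @export
distinct_hd <- function(length, k) {
  stopifnot(is_count(length, min = 1), is_count(k, min = 1))
  if (k >= length) stop("distinct_hd needs 0 < k < length")
  m <- binomial_hd_stats(length, k / length)$mean_hd
  as.integer(round_even(m))
}

#' A pair of equal-count patterns at an exactly controlled Hamming distance
#'
#' Constructs a pattern pair by the shared-core scheme: pattern `a` is drawn
#' uniformly at random; `b` keeps a uniformly chosen subset of `k - d/2` of
#' `a`'s active cells and activates `d/2` cells drawn uniformly from `a`'s
#' inactive cells. Conditional on `a`, `b` is uniform over all equal-count
#' patterns at Hamming distance exactly `d`. The realized distance is
#' recomputed and verified for every generated pair.
#'
#' @inheritParams max_hd
#' @param d Even non-negative target Hamming distance, feasible for
#'   `(length, k)`: `d <= max_hd(length, k)`.
#' @param seed Optional integer seed.
#' @param condition Label stored on the pair; one of `"similar"`,
#'   `"distinct"`, `"custom"`.
#' @param a Optional pre-drawn first pattern (a `binary_pattern` of matching
#'   `length` and `k`); drawn at random when `NULL`.
#' @return An object of class `pattern_pair`: fields `a`, `b`, `target_hd`,
#'   `condition`.
#' @examples
#' pr <- pair_with_hd(100, 10, 4, seed = 1)
#' hamming(pr$a, pr$b) # 4
#' @export
pair_with_hd <- function(length, k, d, seed = NULL,
                         condition = c("custom", "similar", "distinct"),
                         a = NULL) {
  condition <- match.arg(condition)
  stopifnot(is_count(length, min = 0), is_count(k), is_count(d))
  if (k > length) stop("k must satisfy 0 <= k <= length")
  if (d %% 2 != 0) {
    stop("d must be even: equal-count patterns are always an even Hamming distance apart")
  }
  if (d > max_hd(length, k)) {
    stop(sprintf("d = %d infeasible: max_hd(%d, %d) = %d",
                 d, length, k, max_hd(length, k)))
  }
  h <- as.integer(d / 2)
  with_seed(seed, {
    if (is.null(a)) {
      a <- binary_pattern(length, sample.int(length, k))
    } else {
      stopifnot(is_binary_pattern(a))
      if (a$length != length || a$k != k) {
        stop("supplied pattern a does not match (length, k)")
      }
    }
    # index-based sampling: sample(x, ...) on a length-1 vector would
    # misread x as a population size
    keep <- a$active[sample.int(k, k - h)]
    pool <- setdiff(seq_len(length), a$active)
    add <- pool[sample.int(base::length(pool), h)]
    b <- binary_pattern(length, c(keep, add))
    out <- structure(
      list(a = a, b = b, target_hd = as.integer(d), condition = condition),
      class = "pattern_pair"
    )
    realized <- hamming(a, b)
    if (realized != d) { # defensive: construction guarantees this
      stop(sprintf("internal error: realized HD %d != target %d", realized, d))
    }
    out
  })
}

#' @export
print.pattern_pair <- function(x, ...) {
  cat(sprintf("<pattern_pair> N = %d, k = %d, HD = %d (%s)\n",
              x$a$length, x$a$k, x$target_hd, x$condition))
  invisible(x)
}

# ---- plain-text pattern file format ------------------------------------

#' Read and write pattern files
#'
#' Patterns are stored in a diffable plain-text format: a header line
#' `#length=N`, then one pattern per line as space-separated **0-based**
#' active cell indices in ascending order (an empty line is an all-zero
#' pattern). Serialization is deterministic, and a write/read round trip is
#' lossless.
#'
#' @param patterns A list of [binary_pattern()] objects with a common length
#'   (a single pattern is accepted).
#' @param path File path.
#' @return `write_patterns()` returns `path` invisibly; `read_patterns()`
#'   returns a list of `binary_pattern` objects.
#' @export
write_patterns <- function(patterns, path) {
  if (is_binary_pattern(patterns)) patterns <- list(patterns)
  stopifnot(length(patterns) >= 1, all(vapply(patterns, is_binary_pattern, TRUE)))
  n <- unique(vapply(patterns, function(p) p$length, integer(1)))
  if (length(n) != 1) stop("all patterns in one file must share a length")
  lines <- vapply(patterns, function(p) paste(p$active - 1L, collapse = " "),
                  character(1))
  writeLines(c(sprintf("#length=%d", n), lines), path)
  invisible(path)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1 || !grepl("^#length=\\d+$", lines[1])) {
    stop("pattern file must start with a '#length=N' header")
  }
  n <- as.integer(sub("^#length=", "", lines[1]))
  body <- lines[-1]
  lapply(body, function(ln) {
    idx <- if (nzchar(trimws(ln))) {
      as.integer(strsplit(trimws(ln), "\\s+")[[1]]) + 1L
    } else {
      integer(0)
    }
    binary_pattern(n, idx)
  })
}

#' Write a pair manifest
#'
#' Records a set of generated pattern pairs as a CSV manifest with columns
#' `pair_id`, `condition`, `file_a`, `file_b`, `target_hd`, `realized_hd`,
#' `seed`. The realized Hamming distance is recomputed from the patterns at
#' write time.
#'
#' @param pairs List of `pattern_pair` objects.
#' @param files_a,files_b Character vectors of pattern file names, recycled
#'   to the number of pairs.
#' @param seeds Integer vector of per-pair seeds (NA allowed), recycled.
#' @param path Output CSV path.
#' @return The manifest as a data.frame, invisibly.
#' @export
write_pair_manifest <- function(pairs, files_a, files_b, seeds, path) {
  stopifnot(length(pairs) >= 1)
  m <- data.frame(
    pair_id = seq_along(pairs),
    condition = vapply(pairs, function(p) p$condition, character(1)),
    file_a = rep_len(files_a, length(pairs)),
    file_b = rep_len(files_b, length(pairs)),
    target_hd = vapply(pairs, function(p) p$target_hd, integer(1)),
    realized_hd = vapply(pairs, function(p) hamming(p$a, p$b), integer(1)),
    seed = rep_len(as.integer(seeds), length(pairs))
  )
  utils::write.csv(m, path, row.names = FALSE, quote = FALSE)
  invisible(m)
}
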