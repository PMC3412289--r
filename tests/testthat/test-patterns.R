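test_that("hamming reproduces the worked example and rejects dimension mismatch", {
  v0 <- binary_pattern(5, integer(0))
  v1 <- binary_pattern(5, c(2, 4, 5))
  v2 <- binary_pattern(5, c(2, 3, 4))
  expect_identical(hamming(v0, v1), 3L)
  expect_identical(hamming(v1, v2), 2L)
  expect_identical(hamming(v1, v0), 3L) # symmetric
  expect_identical(hamming(v1, v1), 0L)
  expect_error(hamming(v1, binary_pattern(6, 1)), "dimensions differ")
})

test_that("hamming is a metric on random triples", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    x <- random_pattern(n, sample(0:n, 1))
    y <- random_pattern(n, sample(0:n, 1))
    z <- random_pattern(n, sample(0:n, 1))
    expect_identical(hamming(x, y), hamming(y, x))
    expect_identical(hamming(x, x), 0L)
    if (hamming(x, y) == 0L) expect_true(x == y)
    expect_lte(hamming(x, z), hamming(x, y) + hamming(y, z))
  }
})

test_that("hamming between equal-count patterns is always even", {
  set.seed(202)
  for (i in 1:50) {
    n <- sample(4:60, 1)
    k <- sample(0:n, 1)
    expect_identical(hamming(random_pattern(n, k), random_pattern(n, k)) %% 2L, 0L)
  }
})

test_that("max_hd matches the no-overlap bound", {
  expect_identical(max_hd(28009, 1540), 3080L)
  expect_identical(max_hd(45073, 3086), 6172L)
  expect_identical(max_hd(3, 2), 2L) # limited by the single zero component
  expect_identical(max_hd(10, 0), 0L)
  expect_error(max_hd(10, 11), "k must satisfy")
})

test_that("binary_pattern validates its invariants", {
  expect_error(binary_pattern(5, c(1, 1)), "distinct")
  expect_error(binary_pattern(5, 6), "1..length")
  expect_error(binary_pattern(5, 0), "1..length")
  p <- binary_pattern(10, c(9, 2, 5))
  expect_identical(p$active, c(2L, 5L, 9L)) # stored sorted
  expect_identical(p$k, 3L)
  expect_identical(as.integer(p), as.integer(c(0,1,0,0,1,0,0,0,1,0)))
})

test_that("random_pattern draws exact counts, reproducibly and uniformly", {
  expect_identical(random_pattern(10, 0)$k, 0L)
  expect_identical(random_pattern(10, 10)$active, 1:10)
  expect_true(random_pattern(50, 7, seed = 3) == random_pattern(50, 7, seed = 3))
  expect_false(random_pattern(50, 7, seed = 3) == random_pattern(50, 7, seed = 4))
  # per-index inclusion frequency over many draws is k/n within 4 binomial SDs
  n <- 40; k <- 6; m <- 4000
  set.seed(55)
  freq <- rowMeans(vapply(seq_len(m),
                          function(i) as.integer(random_pattern(n, k)),
                          integer(n)))
  p <- k / n
  expect_true(all(abs(freq - p) < 4 * sqrt(p * (1 - p) / m)))
})

test_that("pair_with_hd realizes the target distance exactly", {
  pr <- pair_with_hd(28009, 1540, 62, seed = 9, condition = "similar")
  expect_identical(hamming(pr$a, pr$b), 62L)
  expect_identical(pr$a$k, 1540L)
  expect_identical(pr$b$k, 1540L)
  # d = 0 gives identical patterns
  pr0 <- pair_with_hd(30, 5, 0, seed = 1)
  expect_true(pr0$a == pr0$b)
  # property: random feasible (length, k, d)
  set.seed(77)
  for (i in 1:60) {
    n <- sample(6:80, 1)
    k <- sample(1:(n - 1), 1)
    d <- 2 * sample(0:(max_hd(n, k) / 2), 1)
    pr <- pair_with_hd(n, k, d)
    expect_identical(hamming(pr$a, pr$b), as.integer(d))
    expect_identical(pr$b$k, as.integer(k))
  }
})

test_that("pair_with_hd rejects odd and infeasible distances", {
  expect_error(pair_with_hd(20, 5, 3), "even")
  expect_error(pair_with_hd(20, 5, 12), "infeasible")
  expect_error(pair_with_hd(20, 19, 4), "infeasible") # max_hd = 2
})

test_that("similar_hd rounds to the nearest even integer, ties up", {
  expect_identical(similar_hd(28009, 1540), 62L)  # 61.6 -> 62
  expect_identical(similar_hd(45073, 3086), 124L) # 123.44 -> 124
  expect_identical(similar_hd(100, 50, 1.0), max_hd(100, 50))
  expect_identical(similar_hd(1000, 500, 0.003), 4L) # 3.0 tie -> up
})

test_that("distinct_hd matches the brute-force mean at small n and the printed values", {
  expect_identical(distinct_hd(28009, 1540), 2910L)
  expect_identical(distinct_hd(45073, 3086), 5750L)
  # exhaustive oracle at (6, 3): mean HD over all equal-count partners
  d <- enumerate_hd_distribution(6, 3)
  brute_mean <- sum(d$hd * d$prob)
  expect_lte(abs(distinct_hd(6, 3) - brute_mean), 1)
})

test_that("pattern files round-trip losslessly with 0-based indices on disk", {
  pats <- list(binary_pattern(25, c(1, 7, 25)),
               binary_pattern(25, integer(0)),
               random_pattern(25, 10, seed = 2))
  f <- withr::local_tempfile(fileext = ".txt")
  write_patterns(pats, f)
  lines <- readLines(f)
  expect_identical(lines[1], "#length=25")
  expect_identical(lines[2], "0 6 24") # 0-based on disk
  back <- read_patterns(f)
  expect_true(all(mapply(function(a, b) a == b, pats, back)))
})

test_that("pair manifests record exact realized distances", {
  pairs <- lapply(1:4, function(j) pair_with_hd(60, 8, 6, seed = j,
                                                condition = "custom"))
  f <- withr::local_tempfile(fileext = ".csv")
  m <- write_pair_manifest(pairs, "a.txt", "b.txt", 1:4, f)
  expect_identical(m$realized_hd, rep(6L, 4))
  expect_identical(m$target_hd, rep(6L, 4))
  back <- read.csv(f)
  expect_identical(nrow(back), 4L)
  expect_true(all(back$realized_hd == back$target_hd))
})
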