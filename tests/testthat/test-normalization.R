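longRecords <- function(vals) {
  # vals: named list feature -> named list sample -> numeric vector
  do.call(rbind, lapply(names(vals), function(f)
    do.call(rbind, lapply(names(vals[[f]]), function(s)
      data.frame(feature = f, sample = s, value = vals[[f]][[s]])))))
}

test_that("observation sampling is exhaustive, flagged and deterministic", {
  recs <- longRecords(list(
    area = list(m1 = rnorm(50, 10), m2 = rnorm(500, 12))))
  # group of exactly nObs values -> a permutation of the group
  t1 <- sampleObservations(
    longRecords(list(a = list(s = 1:100))), nObs = 100L, seed = 2L)
  expect_equal(sort(t1@values[1, 1, ]), as.numeric(1:100))
  expect_false(t1@withReplacement[1, 1])
  # smaller group: sampled with replacement, support stays inside
  t2 <- sampleObservations(recs, nObs = 100L, seed = 2L)
  expect_true(t2@withReplacement["area", "m1"])
  expect_false(t2@withReplacement["area", "m2"])
  expect_true(all(t2@values[1, 1, ] %in%
                  recs$value[recs$sample == "m1"]))
  # determinism under the seed
  t3 <- sampleObservations(recs, nObs = 100L, seed = 2L)
  expect_identical(t2@values, t3@values)
  expect_error(sampleObservations(recs[0, ], 10L, 1L), "empty")
  # a (feature, sample) combination with no observations is an error
  holey <- data.frame(feature = rep(c("a", "a", "b"), each = 5L),
                      sample = rep(c("s1", "s2", "s1"), each = 5L),
                      value = rnorm(15L))
  expect_error(sampleObservations(holey, 5L, 1L), "empty")
})

test_that("3D quantile normalization matches the worked example and fixes identical samples", {
  # one feature, two samples, z-vectors (1,2,3) and (4,5,6): both
  # become the rank means (2.5, 3.5, 4.5)
  tens <- array(NA_real_, c(1, 2, 3))
  tens[1, 1, ] <- c(3, 1, 2)
  tens[1, 2, ] <- c(6, 5, 4)
  q <- quantileNormalize3D(tens)
  expect_equal(q[1, 1, ], c(2.5, 3.5, 4.5))
  expect_equal(q[1, 2, ], c(2.5, 3.5, 4.5))
  # all samples identical -> output equals the sorted input
  t2 <- array(rep(c(5, 2, 9), each = 4), c(2, 2, 3))
  q2 <- quantileNormalize3D(t2)
  expect_equal(q2[1, 1, ], c(2, 5, 9))
  expect_equal(q2, aperm(apply(t2, c(1, 2), sort), c(2, 3, 1)))
  expect_error(quantileNormalize3D(array(c(1, NA), c(1, 1, 2))),
               "finite")
})

test_that("frame-wise normalization equalizes sample multisets and matches a brute-force oracle", {
  # oracle: independent counting-based quantile normalization per frame
  oracleFrame <- function(M) {
    ref <- rowMeans(apply(M, 2L, sort))
    out <- M
    for (j in seq_len(ncol(M))) for (i in seq_len(nrow(M))) {
      r <- sum(M[, j] < M[i, j]) + (sum(M[, j] == M[i, j]) + 1) / 2
      lo <- floor(r); hi <- ceiling(r)
      out[i, j] <- (ref[lo] + ref[hi]) / 2
    }
    out
  }
  oracle3d <- function(a) {
    a <- aperm(apply(a, c(1, 2), sort), c(2, 3, 1))
    for (k in seq_len(dim(a)[3]))
      a[, , k] <- oracleFrame(matrix(a[, , k], dim(a)[1]))
    a
  }
  set.seed(13)
  for (rep in 1:30) {
    a <- array(sample(1:6, 12, replace = TRUE), c(2, 2, 3))
    expect_equal(quantileNormalize3D(a), oracle3d(a), tolerance = 1e-12)
  }
  for (rep in 1:10) {
    a <- array(rnorm(3 * 2 * 5), c(3, 2, 5))
    q <- quantileNormalize3D(a)
    expect_equal(q, oracle3d(a), tolerance = 1e-12)
    # after normalization every frame's samples share one multiset
    for (k in 1:5)
      expect_equal(sort(q[, 1, k]), sort(q[, 2, k]), tolerance = 1e-12)
  }
})

test_that("normalization is idempotent and mean-equalizing when feature scales are separated", {
  # separated feature scales (the cell-type situation): ranks are
  # stable along z, the regime the method is designed for
  set.seed(14)
  for (rep in 1:5) {
    a <- array(NA_real_, c(4, 3, 40))
    for (f in 1:4) for (s in 1:3)
      a[f, s, ] <- rnorm(40, mean = 10 * f, sd = 1)
    q <- quantileNormalize3D(a)
    expect_equal(quantileNormalize3D(q), q, tolerance = 1e-9)
    # z-vectors remain sorted
    expect_true(all(apply(q, c(1, 2), function(z) !is.unsorted(z))))
    # per-feature means agree across samples to machine precision
    mns <- apply(q, c(1, 2), mean)
    expect_lt(max(apply(mns, 1, function(v) diff(range(v)))), 1e-9)
  }
})

test_that("normalization agrees with limma's 2D method frame by frame", {
  set.seed(15)
  a <- array(rnorm(5 * 4 * 8), c(5, 4, 8))
  q <- quantileNormalize3D(a)
  srt <- aperm(apply(a, c(1, 2), sort), c(2, 3, 1))
  for (k in 1:8) {
    ref <- limma::normalizeQuantiles(matrix(srt[, , k], 5, 4))
    expect_equal(matrix(q[, , k], 5, 4), ref, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("two-group comparisons behave under identity, separation and the null", {
  set.seed(16)
  # identical vectors: Mann-Whitney reports no separation
  v <- rnorm(50)
  a <- array(NA_real_, c(1, 2, 50))
  a[1, 1, ] <- v; a[1, 2, ] <- v
  p <- compareFeatures(a, 1, 2, "mann_whitney")$p
  expect_gte(p, 0.99)
  # five-sigma shift is overwhelmingly significant
  b <- array(NA_real_, c(1, 2, 100))
  b[1, 1, ] <- rnorm(100, 0, 1)
  b[1, 2, ] <- rnorm(100, 5, 1)
  expect_lt(compareFeatures(b, 1, 2, "mann_whitney")$p, 1e-6)
  expect_lt(compareFeatures(b, 1, 2, "paired_t")$p, 1e-6)
  # paired t on aligned draws differing only by tiny noise is
  # calibrated: p-values are uniform over seeded replicates
  ps <- vapply(1:200, function(i) {
    set.seed(i)
    x <- sort(rnorm(100))
    y <- x + rnorm(100, 0, 1e-3)
    arr <- array(NA_real_, c(1, 2, 100))
    arr[1, 1, ] <- x; arr[1, 2, ] <- sort(y)
    compareFeatures(arr, 1, 2, "paired_t")$p
  }, numeric(1L))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_error(compareFeatures(array(1, c(1, 2, 1)), 1, 2), "at least 2")
  expect_error(compareFeatures(b, 1, 5), "unknown sample")
  # Bonferroni never decreases p-values
  p2 <- compareFeatures(b, 1, 2, "paired_t", bonferroni = TRUE)$p
  expect_gte(p2, compareFeatures(b, 1, 2, "paired_t")$p)
})

test_that("significance labels follow the 0.01 boundary and tier scheme", {
  out <- significanceLabel(c(0.02, 1e-6, 0.01, 0.5, 5e-4))
  expect_equal(out$label,
               c("not_significant", "significant", "significant",
                 "not_significant", "significant"))
  expect_equal(out$tier, c("ns", "p<=1e-5", "p<=0.01", "ns", "p<=1e-3"))
  expect_error(significanceLabel(1.2), "\\[0, 1\\]")
  expect_error(significanceLabel(-0.1), "\\[0, 1\\]")
})

test_that("observation tensors survive the CSV + JSON round-trip", {
  recs <- data.frame(feature = rep(c("a", "b"), each = 40),
                     sample = rep(c("s1", "s2"), times = 40),
                     value = rnorm(80))
  tens <- sampleObservations(recs, nObs = 25L, seed = 4L)
  f <- tempfile(fileext = ".csv")
  writeObservationTensor(tens, f)
  back <- readObservationTensor(f)
  expect_equal(back@values, tens@values, tolerance = 1e-12)
  expect_identical(back@featureNames, tens@featureNames)
  expect_identical(back@sampleIds, tens@sampleIds)
  expect_equal(back@withReplacement[, 1], tens@withReplacement[, 1])
})
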