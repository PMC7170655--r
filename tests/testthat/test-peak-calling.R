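test_that("a single enriched fragment never forms a peak", {
  fm <- uniform_fragments(11)
  v <- rep(0, 11); v[6] <- 3
  pk <- call_candidate_peaks(fragment_track(fm, v), 0, 2L)
  expect_equal(length(pk), 0L)
})

test_that("runs of consecutive enriched fragments form candidate peaks", {
  fm <- uniform_fragments(6)
  v <- c(0, 0.5, 0.7, 0, 0, 0)
  pk <- call_candidate_peaks(fragment_track(fm, v), 0, 2L)
  expect_equal(length(pk), 1L)
  expect_equal(mcols(pk)$n_fragments, 2L)
  expect_equal(mcols(pk)$mean_occupancy, 0.6)
  expect_equal(start(pk), start(fm)[2L])
  expect_equal(end(pk), end(fm)[3L])

  # missing fragments break runs
  v2 <- c(1, 1, NA, 1, 1, 1)
  pk2 <- call_candidate_peaks(fragment_track(fm, v2), 0, 3L)
  expect_equal(length(pk2), 1L)
  expect_equal(mcols(pk2)$n_fragments, 3L)
})

test_that("candidate detection matches a brute-force run scan on random tracks", {
  set.seed(23)
  for (rep in 1:5) {
    n <- 2000L
    v <- rnorm(n, 0, 1)
    v[sample.int(n, 100)] <- NA
    fm <- uniform_fragments(n)
    pk <- call_candidate_peaks(fragment_track(fm, v), 0.2, 2L)
    expected <- oracle_runs(v, 0.2, 2L)
    if (is.null(expected)) {
      expect_equal(length(pk), 0L)
    } else {
      expect_equal(length(pk), nrow(expected))
      expect_equal(mcols(pk)$n_fragments, as.integer(expected[, 1L]))
      expect_equal(mcols(pk)$mean_occupancy, expected[, 2L])
      expect_equal(start(pk), start(fm)[expected[, 3L]])
      expect_equal(end(pk), end(fm)[expected[, 4L]])
    }
  }
})

test_that("runs never cross chromosome boundaries", {
  fm <- GRanges(rep(c("c1", "c2"), each = 3),
                IRanges(rep(c(1L, 201L, 401L), 2), width = 200L))
  seqlengths(fm) <- c(c1 = 600L, c2 = 600L)
  v <- rep(1, 6)
  pk <- call_candidate_peaks(fragment_track(fm, v), 0, 2L)
  expect_equal(length(pk), 2L)
  expect_equal(as.character(seqnames(pk)), c("c1", "c2"))
})

test_that("shuffle-null FDR matches an independent implementation and flags planted signal", {
  set.seed(31)
  n <- 5000L
  v <- rnorm(n, 0, 0.3)
  v[2001:2005] <- 3.0
  fm <- uniform_fragments(n)
  tr <- fragment_track(fm, v)
  cand <- call_candidate_peaks(tr, 0, 2L)
  cand <- estimate_fdr(cand, tr, n_shuffles = 50L, seed = 99L)
  expected <- oracle_fdr(v, 0, 2L, 50L, 99L)
  expect_equal(mcols(cand)$fdr, expected)
  planted <- which(start(cand) <= start(fm)[2001L] & end(cand) >= end(fm)[2005L])
  expect_equal(length(planted), 1L)
  expect_lt(mcols(cand)$fdr[planted], 1e-4)
})

test_that("FDR handles degenerate inputs", {
  fm <- uniform_fragments(10)
  flat <- fragment_track(fm, rep(0, 10))
  cand <- call_candidate_peaks(flat, 0, 2L)
  expect_equal(length(cand), 0L)
  expect_equal(length(estimate_fdr(cand, flat, 10L, seed = 1L)), 0L)
  tr <- fragment_track(fm, rnorm(10))
  cand2 <- call_candidate_peaks(tr, -10, 2L)
  expect_error(estimate_fdr(cand2, tr, n_shuffles = 0L, seed = 1L), "n_shuffles")
})

test_that("joint tail counts are monotone in run length and mean occupancy", {
  # the >=/>= tail definition forces: a peak dominating another in both
  # statistics has tail counts no larger than the dominated peak's
  set.seed(37)
  obs_n <- sample(2:8, 150, replace = TRUE)
  obs_m <- rnorm(150, 1, 0.5)
  ref_n <- sample(2:8, 400, replace = TRUE)
  ref_m <- rnorm(400, 1, 0.5)
  counts <- tadakit:::.tail_counts(obs_n, obs_m, ref_n, ref_m)
  # correctness against direct counting
  direct <- vapply(seq_along(obs_n), function(i)
    sum(ref_n >= obs_n[i] & ref_m >= obs_m[i]), numeric(1))
  expect_equal(counts, direct)
  dominates <- outer(obs_n, obs_n, `>=`) & outer(obs_m, obs_m, `>=`)
  count_le <- outer(counts, counts, `<=`)
  expect_equal(sum(dominates & !count_le), 0L)
})

test_that("significance uses a strict threshold and merges book-ended peaks", {
  fm <- uniform_fragments(20)
  pk <- GRanges("chrSim", IRanges(c(1, 401, 1001), c(400, 800, 1400)))
  mcols(pk)$n_fragments <- c(2L, 2L, 2L)
  mcols(pk)$mean_occupancy <- c(1, 2, 3)
  mcols(pk)$fdr <- c(0.00005, 0.0001, 0.5)
  sig <- filter_significant(pk, 1e-4)
  expect_equal(length(sig), 1L)                 # exactly-at-threshold excluded
  expect_equal(start(sig), 1L)

  # book-ended significant peaks sharing a fragment boundary merge
  mcols(pk)$fdr <- c(0, 0, 0)
  sig2 <- filter_significant(pk, 1e-4)
  expect_equal(length(sig2), 2L)
  expect_equal(start(sig2), c(1L, 1001L))
  expect_equal(end(sig2), c(800L, 1400L))
  expect_equal(mcols(sig2)$n_fragments, c(4, 2))
  expect_equal(mcols(sig2)$mean_occupancy, c(1.5, 3))

  expect_equal(length(filter_significant(pk[0], 1e-4)), 0L)
  mcols(pk)$fdr <- c(0, NA, 0)
  expect_error(filter_significant(pk, 1e-4), "fdr")
})

test_that("replicate intersection emits union spans of cross-replicate components", {
  mk <- function(s, e) {
    g <- GRanges("c1", IRanges(s, e))
    mcols(g)$n_fragments <- rep(2L, length(s))
    mcols(g)$mean_occupancy <- rep(1, length(s))
    mcols(g)$fdr <- rep(0, length(s))
    g
  }
  r1 <- mk(100, 500); r2 <- mk(400, 900)
  fin <- intersect_replicates(r1, r2)
  expect_equal(start(fin), 100L)
  expect_equal(end(fin), 900L)

  # identical sets reproduce their intervals
  same <- mk(c(10, 1000), c(200, 1200))
  fin2 <- intersect_replicates(same, same)
  expect_equal(start(fin2), c(10L, 1000L))
  expect_equal(end(fin2), c(200L, 1200L))

  # book-ended only (no shared bp) does not connect
  expect_equal(length(intersect_replicates(mk(1, 100), mk(101, 200))), 0L)
  expect_equal(length(intersect_replicates(mk(1, 100), mk(500, 600))), 0L)
})

test_that("replicate intersection matches a brute-force component computation", {
  set.seed(43)
  for (rep in 1:3) {
    mkdf <- function(n, src) {
      s <- sort(sample.int(50000, n))
      data.frame(start = s, end = s + sample(50:800, n, replace = TRUE), src = src)
    }
    d1 <- mkdf(200, 1L); d2 <- mkdf(200, 2L)
    as_gr <- function(d) {
      g <- GRanges("c1", IRanges(d$start, d$end))
      mcols(g)$n_fragments <- rep(2L, nrow(d))
      mcols(g)$mean_occupancy <- rep(1, nrow(d))
      mcols(g)$fdr <- rep(0, nrow(d))
      g
    }
    fin <- intersect_replicates(as_gr(d1), as_gr(d2))
    expected <- oracle_intersect(d1, d2)
    expect_equal(length(fin), nrow(expected))
    expect_equal(start(fin), as.integer(expected[, 1L]))
    expect_equal(end(fin), as.integer(expected[, 2L]))
    # containment: every final peak overlaps at least one peak of each replicate
    expect_true(all(countOverlaps(fin, as_gr(d1)) >= 1))
    expect_true(all(countOverlaps(fin, as_gr(d2)) >= 1))
    expect_lte(length(fin), min(200L, 200L))
  }
})
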