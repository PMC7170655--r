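test_that("accessible regions are runs above the genome-wide quantile", {
  fm <- uniform_fragments(100)
  v <- rep(0, 100); v[48:50] <- 50   # 3 % of fragments: above the 95 % quantile
  tr <- fragment_track(fm, v, units = "rpm")
  got <- call_accessible_regions(tr, 0.95, 2L)
  expect_equal(length(got), 1L)
  expect_equal(start(got), start(fm)[48L])
  expect_equal(end(got), end(fm)[50L])

  # an isolated elevated fragment is not a region
  v2 <- rep(0, 100); v2[70] <- 50
  expect_equal(length(call_accessible_regions(fragment_track(fm, v2, units = "rpm"),
                                              0.95, 2L)), 0L)

  expect_error(call_accessible_regions(fragment_track(fm, rep(3, 100), units = "rpm")),
               "quantile")
})

test_that("accessible-region calling matches a brute-force scan at the computed threshold", {
  set.seed(67)
  fm <- uniform_fragments(3000)
  v <- rexp(3000, 1 / 20)
  tr <- fragment_track(fm, v, units = "rpm")
  got <- call_accessible_regions(tr, 0.9, 2L)
  thr <- unname(quantile(v, 0.9))
  expected <- oracle_runs(v, thr, 2L)
  expect_equal(length(got), nrow(expected))
  expect_equal(start(got), start(fm)[expected[, 3L]])
  expect_equal(end(got), end(fm)[expected[, 4L]])
})

test_that("metaprofile bins are length-weighted means around region centres", {
  fm <- uniform_fragments(100, width = 100L)   # chromosome of 10 kb
  const <- fragment_track(fm, rep(2.5, 100))
  regions <- GRanges("chrSim", IRanges(4001, 5000))
  mp <- metaprofile(const, regions, flank = 2000L, bin_width = 200L)
  expect_equal(dim(mp$matrix), c(1L, 20L))
  expect_true(all(mp$matrix == 2.5))
  expect_true(all(mp$mean_profile == 2.5))

  # track symmetric about the region centre gives a palindromic row
  centre0 <- floor((4000 + 5000) / 2)          # 0-based centre
  sym_vals <- abs(seq(50, 9950, by = 100) - centre0)
  mp_sym <- metaprofile(fragment_track(fm, sym_vals), regions,
                        flank = 1000L, bin_width = 100L)
  expect_equal(mp_sym$matrix[1, ], rev(mp_sym$matrix[1, ]))

  # hand-computed length-weighted bin: fragments of 100 bp, bin of 250 bp
  fm2 <- uniform_fragments(40, width = 100L)
  vals <- seq_len(40)
  tr2 <- fragment_track(fm2, vals)
  reg2 <- GRanges("chrSim", IRanges(1751, 2250))  # centre0 = 2000
  mp2 <- metaprofile(tr2, reg2, flank = 250L, bin_width = 250L)
  # first bin covers 0-based [1750, 2000): fragments 18 (50 bp), 19, 20
  expect_equal(mp2$matrix[1, 1], (18 * 50 + 19 * 100 + 20 * 100) / 250)
  # second bin covers [2000, 2250): fragments 21, 22, 23 (50 bp)
  expect_equal(mp2$matrix[1, 2], (21 * 100 + 22 * 100 + 23 * 50) / 250)

  expect_error(metaprofile(const, GRanges(), 2000L, 200L), "empty")
  expect_error(metaprofile(const, regions, 2000L, 300L), "multiple")
})

test_that("metaprofile is translation-equivariant and handles chromosome edges", {
  set.seed(71)
  fm <- uniform_fragments(200, width = 100L)
  v <- rnorm(200)
  tr <- fragment_track(fm, v)
  r1 <- GRanges("chrSim", IRanges(5001, 5400))
  r2 <- GRanges("chrSim", IRanges(5001 + 3000, 5400 + 3000))
  v_shift <- c(rep(NA, 30), v[1:170])          # shift values by 30 fragments
  tr_shift <- fragment_track(fm, v_shift)
  m1 <- metaprofile(tr, r1, flank = 1000L, bin_width = 100L)
  m2 <- metaprofile(tr_shift, r2, flank = 1000L, bin_width = 100L)
  expect_equal(m1$matrix, m2$matrix)

  # off-chromosome bins are missing
  edge <- metaprofile(tr, GRanges("chrSim", IRanges(101, 200)),
                      flank = 1000L, bin_width = 100L)
  expect_true(all(is.na(edge$matrix[1, 1:8])))   # window starts 850 bp before base 0
  expect_false(anyNA(edge$matrix[1, 11:20]))
})

test_that("state enrichment equals brute-force overlap-weighted means", {
  fm <- uniform_fragments(50, width = 100L)
  v <- rep(0, 50); v[11:20] <- 1
  tr <- fragment_track(fm, v)
  states <- GRanges("chrSim", IRanges(c(1001, 2001), c(2000, 3000)))
  mcols(states)$label <- c("bound", "rest")
  got <- state_enrichment(tr, states)
  expect_equal(got$mean_signal[got$state == "bound"], 1)
  expect_equal(got$mean_signal[got$state == "rest"], 0)

  # constant track: zero enrichment everywhere
  flat <- state_enrichment(fragment_track(fm, rep(1.5, 50)), states)
  expect_equal(flat$enrichment, c(0, 0))

  # random states and values against a brute-force computation
  set.seed(73)
  vr <- rnorm(50)
  trr <- fragment_track(fm, vr)
  cuts <- sort(sample(seq(200, 4800, by = 100), 6))
  bounds <- c(1, cuts + 1)
  ends <- c(cuts, 5000)
  sr <- GRanges("chrSim", IRanges(bounds, ends))
  mcols(sr)$label <- sample(c("s1", "s2", "s3"), 7, replace = TRUE)
  gotr <- state_enrichment(trr, sr)
  for (st in unique(mcols(sr)$label)) {
    num <- den <- 0
    for (k in which(mcols(sr)$label == st)) for (f in seq_along(fm)) {
      ov <- min(end(sr)[k], end(fm)[f]) - max(start(sr)[k], start(fm)[f]) + 1
      if (ov > 0) { num <- num + ov * vr[f]; den <- den + ov }
    }
    expect_equal(gotr$mean_signal[gotr$state == st], num / den)
  }
  # partition property: union of all states covers the genome exactly
  gw <- sum(vr * width(fm)) / sum(width(fm))
  total <- sum(vapply(unique(mcols(sr)$label), function(st) {
    w_st <- sum(width(sr)[mcols(sr)$label == st])
    gotr$mean_signal[gotr$state == st] * w_st
  }, numeric(1))) / sum(width(sr))
  expect_equal(total, gw)

  overlapping <- GRanges("chrSim", IRanges(c(1, 50), c(100, 200)))
  mcols(overlapping)$label <- c("a", "b")
  expect_error(state_enrichment(trr, overlapping), "overlap")
})

test_that("binding planted in low-accessibility fragments yields a negative correlation", {
  cfg <- sim_config(chromosome_length = 1000000L, low_access_bias = 1)
  gen <- simulate_genome(cfg, 79)
  truth <- simulate_truth(cfg, gen$fragments, 79)
  reps <- simulate_damid(truth, gen$fragments)
  binding <- occupancy_ratio(reps[[1L]]$fusion, reps[[1L]]$control)
  access <- rpm_normalize(reps[[1L]]$control)
  expect_lt(binding_accessibility_correlation(binding, access), 0)
})
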