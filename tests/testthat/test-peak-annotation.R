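mk_peaks <- function(starts, ends, chrom = "c1") {
  g <- GRanges(chrom, IRanges(starts, ends))
  mcols(g)$n_fragments <- rep(2L, length(g))
  g
}

mk_genes <- function(df) {
  gene_models(df$chrom, df$start, df$end, df$strand, df$gene_id)
}

test_that("genes overlapping or within 5 kb of a peak are assigned", {
  # overlap: distance 0 (1-based spans for 0-based [1000,2000) and [1500,3000))
  genes <- mk_genes(data.frame(chrom = "c1", start = 1501, end = 3000,
                               strand = "+", gene_id = "gA"))
  got <- assign_genes(mk_peaks(1001, 2000), genes)
  expect_equal(got$gene_id, "gA")
  expect_equal(got$distance, 0)

  # gap of 6,001 bp: never assigned under the printed 5 kb rule
  far <- mk_genes(data.frame(chrom = "c1", start = 8002, end = 9000,
                             strand = "+", gene_id = "gFar"))
  expect_equal(nrow(assign_genes(mk_peaks(1001, 2000), far)), 0L)

  # a gene lying entirely in the gap blocks the farther gene
  pair <- mk_genes(data.frame(chrom = "c1", start = c(2501, 4001),
                              end = c(2800, 6000), strand = c("+", "-"),
                              gene_id = c("gNear", "gBlocked")))
  got2 <- assign_genes(mk_peaks(1001, 2000), pair)
  expect_equal(got2$gene_id, "gNear")

  # a partially overlapping bystander does not block
  pair2 <- mk_genes(data.frame(chrom = "c1", start = c(1500, 4001),
                               end = c(2800, 6000), strand = c("+", "-"),
                               gene_id = c("gOverlap", "gB")))
  got3 <- assign_genes(mk_peaks(1001, 2000), pair2)
  expect_setequal(got3$gene_id, c("gOverlap", "gB"))

  expect_error(assign_genes(mk_peaks(1, 10), genes, max_distance = -1), "max_distance")
})

test_that("gene assignment matches the brute-force intervening-gene oracle", {
  set.seed(53)
  for (rep in 1:3) {
    ng <- 120L
    gs <- sort(sample.int(200000, ng))
    genes_df <- data.frame(chrom = "c1", start = gs,
                           end = gs + sample(200:3000, ng, replace = TRUE),
                           strand = sample(c("+", "-"), ng, replace = TRUE),
                           gene_id = sprintf("g%03d", seq_len(ng)))
    ps <- sort(sample.int(200000, 40))
    peaks_df <- data.frame(chrom = "c1", start = ps,
                           end = ps + sample(100:1500, 40, replace = TRUE))
    got <- assign_genes(mk_peaks(peaks_df$start, peaks_df$end), mk_genes(genes_df))
    expected <- oracle_assign(peaks_df, genes_df, 5000)
    if (is.null(expected)) {
      expect_equal(nrow(got), 0L)
    } else {
      rownames(got) <- rownames(expected) <- NULL
      expect_equal(got$peak_id, expected$peak_id)
      expect_equal(got$gene_id, expected$gene_id)
      expect_equal(got$distance, as.numeric(expected$distance))
    }
    # monotonicity: larger max_distance never removes an assignment
    wider <- assign_genes(mk_peaks(peaks_df$start, peaks_df$end),
                          mk_genes(genes_df), max_distance = 10000)
    key <- function(d) paste(d$peak_id, d$gene_id)
    expect_true(all(key(got) %in% key(wider)))
  }
})

test_that("feature classification follows the promoter > TTS > exon > intron priority", {
  genes <- gene_models("c1", 5000, 9000, "+", "gA",
                       exons = list(cbind(c(5000, 7000), c(5500, 7400))))
  # midpoint 500 bp upstream of the + strand TSS
  got <- classify_features(mk_peaks(4401, 4600), genes)
  expect_equal(as.character(got$categories), "promoter-TSS")
  # midpoint inside an intron (between exons, away from windows)
  got2 <- classify_features(mk_peaks(6201, 6400), genes)
  expect_equal(as.character(got2$categories), "intron")
  # midpoint inside the second exon
  got3 <- classify_features(mk_peaks(7101, 7300), genes)
  expect_equal(as.character(got3$categories), "exon")
  # near the 3' end: TTS window
  got4 <- classify_features(mk_peaks(8901, 9100), genes)
  expect_equal(as.character(got4$categories), "TTS")
  # far away: intergenic
  got5 <- classify_features(mk_peaks(20001, 20200), genes)
  expect_equal(as.character(got5$categories), "intergenic")
})

test_that("feature classification matches the exhaustive oracle on random annotations", {
  set.seed(59)
  ng <- 60L
  gs <- sort(sample.int(150000, ng))
  genes_df <- data.frame(chrom = "c1", start = gs,
                         end = gs + sample(500:4000, ng, replace = TRUE),
                         strand = sample(c("+", "-"), ng, replace = TRUE),
                         gene_id = sprintf("g%03d", seq_len(ng)))
  exons <- lapply(seq_len(ng), function(i) {
    if (runif(1) < 0.4) return(cbind(genes_df$start[i], genes_df$end[i]))
    mid <- floor((genes_df$start[i] + genes_df$end[i]) / 2)
    cbind(c(genes_df$start[i], mid + 50), c(mid - 50, genes_df$end[i]))
  })
  genes <- gene_models(genes_df$chrom, genes_df$start, genes_df$end,
                       genes_df$strand, genes_df$gene_id, exons = exons)
  ps <- sample.int(150000, 500)
  peaks_df <- data.frame(chrom = "c1", start = ps,
                         end = ps + sample(50:900, 500, replace = TRUE))
  got <- classify_features(mk_peaks(peaks_df$start, peaks_df$end), genes)
  expected <- oracle_classify(peaks_df, genes_df, exons)
  expect_equal(as.character(got$categories), expected)
  expect_equal(sum(got$counts), 500L)
  expect_equal(sum(got$fractions), 1, tolerance = 1e-9)
  # invariant under reordering
  perm <- sample.int(500)
  got_perm <- classify_features(mk_peaks(peaks_df$start[perm], peaks_df$end[perm]),
                                genes)
  expect_equal(got_perm$counts, got$counts)
})

test_that("venn_counts enumerates every membership pattern", {
  got <- venn_counts(list(A = c("a", "b"), B = c("b", "c")))
  expect_equal(unname(got[c("A", "B", "A&B")]), c(1L, 1L, 1L))
  expect_equal(sum(got), 3L)   # size of the union

  same <- venn_counts(list(X = letters[1:5], Y = letters[1:5]))
  expect_equal(unname(same["X&Y"]), 5L)
  expect_equal(unname(same["X"]), 0L)

  set.seed(61)
  sets <- list(A = sample(sprintf("g%04d", 1:3000), 1000),
               B = sample(sprintf("g%04d", 1:3000), 1000),
               C = sample(sprintf("g%04d", 1:3000), 1000))
  got3 <- venn_counts(sets)
  universe <- unique(unlist(sets))
  # enumeration oracle: classify each element by its membership pattern
  pat <- vapply(universe, function(e)
    paste(names(sets)[vapply(sets, function(s) e %in% s, logical(1))],
          collapse = "&"), character(1))
  tab <- table(pat)
  for (nm in names(tab)) expect_equal(unname(got3[nm]), unname(as.integer(tab[nm])))
  expect_equal(sum(got3), length(universe))

  expect_error(venn_counts(list(A = "a")), "at least 2")
  expect_error(venn_counts(stats::setNames(replicate(7, "a", simplify = FALSE),
                                           letters[1:7])), "6")
})
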